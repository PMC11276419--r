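# Pairs (case) bootstrap of the AIC selection process.
#
# The naive bootstrap AIC, -2*loglik(theta*_hat | y*) + 2k, is optimistic:
# the bootstrap-fitted likelihood is evaluated on the very resample used to
# fit it, and the resample carries duplicated rows, so fewer independent
# pieces of information than the original sample. Restoring approximate
# unbiasedness for the expected Kullback-Leibler discrepancy requires a
# total penalty of 3k; the adjusted bootstrap AIC adds the extra k.

# Per-replicate substream seeds derived from one master seed, so replicate b
# is reproducible on its own and adjusted/unadjusted runs with the same seed
# see identical resamples.
substream_seeds <- function(seed, B) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, B)
}

# Precomputed candidate-set geometry shared by the selection loops.
candidate_geometry <- function(data, specs) {
  p1 <- length(data$names)
  Zfull <- cbind(rep(1, data$n), data$X)
  cols <- lapply(specs, function(s) c(1L, 1L + which(s$mask)))
  list(
    Zfull = Zfull,
    cols = cols,
    ks = vapply(specs, function(s) sum(s$mask) + 2L, integer(1)),
    labels = vapply(specs, function(s) s$label, character(1)),
    masks = {
      mk <- do.call(rbind, lapply(specs, function(s) as.integer(s$mask)))
      colnames(mk) <- data$names
      mk
    })
}

# Goodness-of-fit terms -2*loglik for every candidate model on (Z, y).
# Returns the vector, or NULL if any candidate fit is singular/degenerate
# (the offending label is left in `offender` in the enclosing frame).
all_model_gof <- function(geom, Z, y) {
  m <- length(geom$cols)
  gof <- numeric(m)
  n <- length(y)
  for (j in seq_len(m)) {
    cj <- geom$cols[[j]]
    f <- stats::.lm.fit(Z[, cj, drop = FALSE], y)
    rss <- sum(f$residuals^2)
    if (f$rank < length(cj) || degenerate_rss(rss, y)) {
      attr(gof, "offender") <- geom$labels[j]
      attr(gof, "bad") <- TRUE
      return(gof)
    }
    gof[j] <- n * (log2pi + log(rss / n) + 1)
  }
  gof
}

#' Draw one pairs-bootstrap resample
#'
#' Draws `n` row indices i.i.d. uniformly with replacement and records, for
#' every original row, its multiplicity in the resample. Rows of the outcome
#' and the covariate matrix are resampled jointly (case resampling), and the
#' multiplicities are defined by row index identity, not by matching outcome
#' values, so tied outcome values are unambiguous.
#'
#' @param data A [bmf_data] object.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   on its own, otherwise the current RNG state is used.
#'
#' @return An object of class `"bootstrap_replicate"` with elements
#'   `indices` (length `n`) and `counts` (length `n`, summing to `n`).
#' @examples
#' d <- bmf_data(rnorm(5))
#' r <- resample_cases(d, seed = 1)
#' sum(r$counts)  # 5
#' @export
resample_cases <- function(data, seed = NULL) {
  stopifnot(inherits(data, "bmf_data"))
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(data$n, data$n, replace = TRUE)
  structure(list(indices = idx, counts = tabulate(idx, data$n)),
            class = "bootstrap_replicate")
}

# Materialize the resampled dataset for a replicate skeleton.
resampled_data <- function(data, replicate) {
  bmf_data(data$y[replicate$indices],
           data$X[replicate$indices, , drop = FALSE],
           data$names)
}

#' Bootstrap AIC of a fit on a resample
#'
#' Given a model fitted to a bootstrap sample, returns the bootstrap AIC:
#' unadjusted it is `-2*loglik + 2k`, exactly the AIC formula evaluated on
#' the resample; adjusted it adds a further `k`, for a total penalty of
#' `3k`, compensating the optimism of evaluating a bootstrap-fitted
#' likelihood on its own fitting resample.
#'
#' @param fit_star A `"gaussian_fit"` obtained on the bootstrap sample.
#' @param adjusted Logical; apply the extra-`k` bias adjustment (default
#'   `TRUE`).
#'
#' @return The criterion value (a scalar).
#' @export
bootstrap_aic <- function(fit_star, adjusted = TRUE) {
  stopifnot(inherits(fit_star, "gaussian_fit"))
  fit_star$aic + if (adjusted) fit_star$k else 0
}

#' Plug-in discrepancy of a bootstrap fit against the original sample
#'
#' Evaluates `-2 * loglik(beta*, sigma2* | y)`: the Gaussian log-likelihood
#' of the ORIGINAL observations under the parameters fitted on a bootstrap
#' resample. This is the plug-in estimate of the Kullback-Leibler
#' discrepancy of the bootstrap-fitted model, the quantity whose expected
#' optimism gaps (penalties k, 2k, 3k) motivate the BMF bias adjustment.
#'
#' @param fit_star A `"gaussian_fit"`, typically fitted on a resample of
#'   `data`.
#' @param data The original [bmf_data] object.
#'
#' @return The scalar `-2 * loglik` value.
#' @export
plugin_discrepancy <- function(fit_star, data) {
  stopifnot(inherits(fit_star, "gaussian_fit"), inherits(data, "bmf_data"))
  Z <- design_matrix(data, fit_star$spec)
  resid <- data$y - drop(Z %*% fit_star$beta_hat)
  data$n * (log2pi + log(fit_star$sigma2_hat)) +
    sum(resid^2) / fit_star$sigma2_hat
}

#' Bootstrap estimate of the extended information criterion (EIC)
#'
#' The EIC replaces the fixed `2k` AIC penalty by a bootstrap estimate of
#' the optimism of the fitted log-likelihood:
#' `EIC = -2*loglik(theta_hat | y) + 2 * E*[loglik(theta*_hat | y*) -
#' loglik(theta*_hat | y)]`, where the expectation runs over resamples. For
#' a correctly specified model both EIC and AIC are asymptotically unbiased
#' for the expected Kullback-Leibler discrepancy of the fitted model, which
#' is what the package's penalty-ladder checks verify empirically.
#'
#' @param data A [bmf_data] object.
#' @param spec The candidate `"model_spec"` to assess.
#' @param B Number of bootstrap replicates (`>= 1`).
#' @param seed Optional integer master seed.
#'
#' @return A list with `eic` (the estimate), `optimism` (the bootstrap mean
#'   of `2*(loglik(theta*|y*) - loglik(theta*|y))`), `mc_se` (Monte Carlo
#'   standard error of `optimism`; 0 when `B = 1`), `B` and `redraws` (count
#'   of degenerate replicates that were redrawn).
#' @export
eic <- function(data, spec, B, seed = NULL) {
  stopifnot(inherits(data, "bmf_data"), inherits(spec, "model_spec"), B >= 1)
  fit0 <- fit_gaussian_ml(data, spec)
  geom <- candidate_geometry(data, list(spec))
  cj <- geom$cols[[1L]]
  n <- data$n
  seeds <- substream_seeds(seed, B)
  opt <- numeric(B)
  redraws <- 0L
  budget <- 100L * B
  draws <- 0L
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    repeat {
      draws <- draws + 1L
      if (draws > budget)
        stop("exceeded ", budget, " bootstrap draws redrawing degenerate ",
             "replicates for model '", spec$label, "'")
      idx <- sample.int(n, n, replace = TRUE)
      yb <- data$y[idx]
      Zb <- geom$Zfull[idx, cj, drop = FALSE]
      f <- stats::.lm.fit(Zb, yb)
      rss <- sum(f$residuals^2)
      if (f$rank < length(cj) || degenerate_rss(rss, yb)) {
        redraws <- redraws + 1L
        next
      }
      beta <- numeric(length(cj)); beta[f$pivot] <- f$coefficients
      sigma2 <- rss / n
      ll_star_star <- loglik_from_rss(rss, n)
      resid0 <- data$y - drop(geom$Zfull[, cj, drop = FALSE] %*% beta)
      ll_star_orig <- -0.5 * (n * (log2pi + log(sigma2)) +
                                sum(resid0^2) / sigma2)
      opt[b] <- 2 * (ll_star_star - ll_star_orig)
      break
    }
  }
  list(eic = -2 * fit0$loglik + mean(opt),
       optimism = mean(opt),
       mc_se = if (B > 1) stats::sd(opt) / sqrt(B) else 0,
       B = B, redraws = redraws)
}

#' Bootstrap model frequencies (BMFs)
#'
#' Approximates model selection probabilities for an all-subsets candidate
#' set by repeating the AIC selection on pairs-bootstrap resamples. For each
#' of `B` replicates, every candidate model is fitted to the SAME resample,
#' the (adjusted or unadjusted) bootstrap AICs are computed, and the
#' minimizer is recorded (ties broken as in [select_min_aic()]). The BMF of
#' a model is its selection fraction over the `B` replicates.
#'
#' Replicates in which any candidate fit is singular or interpolates the
#' resample exactly are discarded and redrawn, up to a total budget of
#' `100 * B` draws; the number of redraws is reported in the result.
#'
#' @param data A [bmf_data] object.
#' @param specs Candidate list from [enumerate_models()] (defaults to the
#'   full all-subsets set over `data$names`).
#' @param B Number of bootstrap replicates (`>= 1`).
#' @param adjusted Logical; use the bias-adjusted bootstrap AIC with total
#'   penalty `3k` (default `TRUE`). With the same `seed`, adjusted and
#'   unadjusted runs see identical resamples, enabling paired comparisons.
#' @param seed Optional integer master seed; replicate `b` runs on a
#'   deterministically derived substream.
#' @param keep_replicates Logical; retain per-replicate detail (counts,
#'   bootstrap AICs, selected model, zero-filled coefficient vector) needed
#'   for bootstrap smoothing (default `TRUE`). Disable for long Monte Carlo
#'   runs that only need the frequency table.
#'
#' @return An object of class `"bmf_result"`: a list with `table` (data
#'   frame: `model`, `count`, `frequency`), `masks` (0/1 matrix, one row per
#'   model), `replicates` (list of `"bootstrap_replicate"` or `NULL`), `B`,
#'   `adjusted`, `n`, `redraws` and `seed`. Frequencies sum to 1 and counts
#'   sum to `B`.
#' @examples
#' d <- bmf_data(rnorm(30), matrix(rnorm(30), 30, 1), "x1")
#' r <- bmf(d, B = 50, seed = 7)
#' r$table
#' @export
bmf <- function(data, specs = enumerate_models(data$names), B,
                adjusted = TRUE, seed = NULL, keep_replicates = TRUE) {
  stopifnot(inherits(data, "bmf_data"), length(specs) >= 1, B >= 1)
  geom <- candidate_geometry(data, specs)
  m <- length(specs)
  n <- data$n
  p <- length(data$names) + 1L
  seeds <- substream_seeds(seed, B)
  sel_counts <- integer(m)
  reps <- if (keep_replicates) vector("list", B) else NULL
  redraws <- 0L
  budget <- 100L * B
  draws <- 0L
  extra <- if (adjusted) geom$ks else 0
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    repeat {
      draws <- draws + 1L
      if (draws > budget)
        stop("exceeded ", budget, " bootstrap draws redrawing degenerate ",
             "replicates (last offending model: '", attr(gof, "offender"), "')")
      idx <- sample.int(n, n, replace = TRUE)
      yb <- data$y[idx]
      Zb <- geom$Zfull[idx, , drop = FALSE]
      gof <- all_model_gof(geom, Zb, yb)
      if (isTRUE(attr(gof, "bad"))) {
        redraws <- redraws + 1L
        next
      }
      break
    }
    aics_star <- gof + 2 * geom$ks + extra
    sel <- select_min_aic(aics_star, geom$ks)
    sel_counts[sel] <- sel_counts[sel] + 1L
    if (keep_replicates) {
      cj <- geom$cols[[sel]]
      f <- ols_solve(Zb[, cj, drop = FALSE], yb)
      beta_star <- numeric(p)
      beta_star[cj] <- f$beta
      names(beta_star) <- c("(Intercept)", data$names)
      reps[[b]] <- structure(
        list(indices = idx, counts = tabulate(idx, n), aics_star = aics_star,
             adjusted = adjusted, selected = sel, beta_star = beta_star),
        class = "bootstrap_replicate")
    }
  }
  structure(
    list(table = data.frame(model = geom$labels, count = sel_counts,
                            frequency = sel_counts / B,
                            stringsAsFactors = FALSE),
         masks = geom$masks, replicates = reps, B = B, adjusted = adjusted,
         n = n, redraws = redraws, seed = seed),
    class = "bmf_result")
}

#' @export
print.bmf_result <- function(x, ...) {
  cat("<bmf_result> ", x$B, " bootstrap replicates (",
      if (x$adjusted) "adjusted" else "unadjusted",
      " criterion), n = ", x$n,
      if (x$redraws) paste0(", ", x$redraws, " degenerate redraws"), "\n",
      sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
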