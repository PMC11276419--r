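#' Assemble a regression dataset
#'
#' Bundles a continuous outcome vector with a numeric covariate matrix into
#' the container used throughout the package. The covariate matrix holds the
#' `p - 1` candidate explanatory variables; the intercept is implicit and is
#' added to every design matrix at fit time.
#'
#' @param y Numeric outcome vector of length `n >= 2`, no missing values.
#' @param X Numeric matrix with `n` rows, one column per candidate covariate.
#'   May have zero columns (or be `NULL`) for an intercept-only problem.
#' @param names Character vector of covariate labels, one per column of `X`.
#'   Defaults to `colnames(X)`.
#'
#' @return An object of class `"bmf_data"`: a list with elements `y`, `X`,
#'   `names` and `n`.
#' @examples
#' d <- bmf_data(rnorm(10), matrix(rnorm(20), 10, 2), c("x1", "x2"))
#' d$n
#' @export
bmf_data <- function(y, X = NULL, names = colnames(X)) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L)
    stop("need at least 2 observations, got ", n)
  if (anyNA(y) || !all(is.finite(y)))
    stop("outcome contains missing or non-finite values")
  if (is.null(X)) {
    X <- matrix(numeric(0), nrow = n, ncol = 0L)
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != n)
    stop("X has ", nrow(X), " rows but y has length ", n)
  if (anyNA(X) || (length(X) && !all(is.finite(X))))
    stop("covariate matrix contains missing or non-finite values")
  if (is.null(names)) {
    names <- if (ncol(X)) paste0("x", seq_len(ncol(X))) else character(0)
  }
  names <- as.character(names)
  if (length(names) != ncol(X))
    stop("got ", length(names), " covariate names for ", ncol(X), " columns")
  colnames(X) <- names
  structure(list(y = y, X = X, names = names, n = n), class = "bmf_data")
}

#' @export
print.bmf_data <- function(x, ...) {
  cat("<bmf_data> n =", x$n, "observations,",
      length(x$names), "candidate covariates\n")
  if (length(x$names)) cat("  covariates:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate the all-subsets candidate model set
#'
#' Builds every model that can be formed from the candidate covariates, each
#' with an intercept, giving `2^(p-1)` specifications. The ordering is
#' deterministic binary counting with covariate 1 as the least significant
#' bit, so the intercept-only model always comes first and the full model
#' last; frequency tables computed over the set are therefore comparable
#' across runs.
#'
#' @param names Character vector of covariate labels (`p - 1` of them). At
#'   most 20 covariates are allowed, since the candidate set doubles with
#'   each additional variable.
#'
#' @return A list of `"model_spec"` objects, each with elements `mask`
#'   (logical inclusion indicator over the covariates) and `label`.
#' @examples
#' specs <- enumerate_models(c("x1", "x2", "x3"))
#' length(specs)   # 8
#' specs[[1]]$label
#' @export
enumerate_models <- function(names) {
  names <- as.character(names)
  p1 <- length(names)
  if (p1 > 20L)
    stop("refusing to enumerate 2^", p1,
         " candidate models; at most 20 covariates are supported")
  lapply(0:(2^p1 - 1L), function(m) {
    mask <- if (p1) as.logical(bitwAnd(m, bitwShiftL(1L, 0:(p1 - 1L)))) else logical(0)
    new_model_spec(mask, names)
  })
}

new_model_spec <- function(mask, names) {
  structure(
    list(mask = mask,
         label = if (any(mask)) paste(names[mask], collapse = "+") else "(intercept)"),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$label, "\n")
  invisible(x)
}

# Design matrix for a spec: intercept column plus the masked covariates.
design_matrix <- function(data, spec) {
  cbind(`(Intercept)` = rep(1, data$n), data$X[, spec$mask, drop = FALSE])
}

log2pi <- log(2 * pi)

# Maximized Gaussian log-likelihood from a residual sum of squares, using the
# ML variance estimate RSS/n.
loglik_from_rss <- function(rss, n) {
  -0.5 * n * (log2pi + log(rss / n) + 1)
}

# Least squares via the pivoting QR in .lm.fit, with coefficients returned in
# the original column order.
ols_solve <- function(Z, y) {
  fit <- stats::.lm.fit(Z, y)
  beta <- numeric(ncol(Z))
  beta[fit$pivot] <- fit$coefficients
  list(beta = beta, rss = sum(fit$residuals^2), rank = fit$rank)
}

# Relative threshold below which a residual sum of squares is treated as an
# exact interpolation (unbounded likelihood).
degenerate_rss <- function(rss, y) {
  rss <= 1e-12 * max(sum(y * y), .Machine$double.eps)
}

#' Gaussian maximum-likelihood fit of one candidate model
#'
#' Fits the linear model given by a covariate subset (plus intercept) by
#' least squares, which coincides with the Gaussian maximum-likelihood
#' solution for the mean parameters. The error variance uses the ML divisor
#' `n`, not the residual degrees of freedom, because the AIC goodness-of-fit
#' term is the maximized log-likelihood. The parameter count `k` includes
#' the error variance, so an intercept-only model has `k = 2`.
#'
#' @param data A [bmf_data] object.
#' @param spec A `"model_spec"` from [enumerate_models()].
#'
#' @return An object of class `"gaussian_fit"` with elements `beta_hat`
#'   (named, intercept first), `sigma2_hat`, `loglik`, `k`, `aic`, `rss`,
#'   `n` and `spec`.
#' @examples
#' d <- bmf_data(c(-1, 1))
#' f <- fit_gaussian_ml(d, enumerate_models(character(0))[[1]])
#' f$aic
#' @export
fit_gaussian_ml <- function(data, spec) {
  stopifnot(inherits(data, "bmf_data"), inherits(spec, "model_spec"))
  Z <- design_matrix(data, spec)
  q <- ncol(Z)
  if (data$n <= q)
    stop("model '", spec$label, "' has ", q, " mean parameters but only ",
         data$n, " observations")
  sol <- ols_solve(Z, data$y)
  if (sol$rank < q)
    stop("singular design for model '", spec$label,
         "': rank ", sol$rank, " < ", q, " columns")
  if (degenerate_rss(sol$rss, data$y))
    stop("degenerate fit for model '", spec$label,
         "': residual sum of squares is zero, log-likelihood unbounded")
  sigma2 <- sol$rss / data$n
  ll <- loglik_from_rss(sol$rss, data$n)
  k <- q + 1L
  beta <- sol$beta
  names(beta) <- colnames(Z)
  structure(
    list(beta_hat = beta, sigma2_hat = sigma2, loglik = ll, k = k,
         aic = -2 * ll + 2 * k, rss = sol$rss, n = data$n, spec = spec),
    class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat("<gaussian_fit>", x$spec$label,
      sprintf(" (k = %d, logLik = %.4f, AIC = %.4f)\n", x$k, x$loglik, x$aic))
  print(round(x$beta_hat, 4))
  invisible(x)
}

#' Akaike weights for a candidate set
#'
#' Converts AIC values into AIC differences `delta_i = AIC_i - min(AIC)` and
#' Akaike weights `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`. The
#' minimum is subtracted before exponentiating, so the weights are invariant
#' to a constant shift of all AIC values and never overflow.
#'
#' Akaike weights are a relative-plausibility measure. They are often read
#' as model selection probabilities, but for nested models the weight ratio
#' is bounded by a function of the penalty difference (see [weight_bounds()])
#' while the true selection-probability ratio is not, so the two can differ
#' substantially; bootstrap model frequencies ([bmf()]) approximate selection
#' probabilities directly.
#'
#' @param aics Numeric vector of AIC values, all finite.
#' @param models Optional labels for the rows (defaults to `M1 ... Mm`).
#'
#' @return A data frame of class `"criterion_table"` with columns `model`,
#'   `aic`, `delta` and `weight`. `min(delta)` is 0 and the weights sum to 1.
#' @examples
#' akaike_weights(c(10, 12, 14))$weight
#' @export
akaike_weights <- function(aics, models = NULL) {
  aics <- as.numeric(aics)
  if (!length(aics))
    stop("empty AIC vector")
  if (!all(is.finite(aics)))
    stop("AIC values must all be finite")
  if (is.null(models)) models <- paste0("M", seq_along(aics))
  delta <- aics - min(aics)
  w <- exp(-0.5 * delta)
  w <- w / sum(w)
  structure(
    data.frame(model = as.character(models), aic = aics, delta = delta,
               weight = w, stringsAsFactors = FALSE),
    class = c("criterion_table", "data.frame"))
}

#' Select the AIC-minimizing model
#'
#' Returns the index of the smallest AIC. Exact ties are broken first in
#' favor of the model with fewer parameters, then by lower index, so the
#' selection is deterministic.
#'
#' @param aics Numeric vector of criterion values.
#' @param ks Integer vector of parameter counts, same length as `aics`.
#'
#' @return The 1-based index of the selected model.
#' @examples
#' select_min_aic(c(3, 2, 5), c(3, 2, 4))  # 2
#' @export
select_min_aic <- function(aics, ks) {
  if (!length(aics) || length(aics) != length(ks))
    stop("aics and ks must be non-empty vectors of the same length")
  order(aics, ks, seq_along(aics))[1L]
}
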