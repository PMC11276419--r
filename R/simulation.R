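# Monte Carlo scenario generators and study drivers.
#
# Three data-generating mechanisms are provided:
#   two_model  - intercept-only truth y = 1 + N(0,1) noise plus one
#                irrelevant standard-normal candidate covariate, the
#                minimal null-vs-alternative setting;
#   correlated - y = 1 + 2*x1 + 1*x2 + 0*x3 + N(0,1) noise with
#                (x1,x2,x3) trivariate normal, unit variances, all pairwise
#                covariances 0.5, means (1,1,1);
#   mixture    - same mean structure and covariate law, but errors from the
#                centered scale mixture Z*N(0,3) + (1-Z)*N(0,1) with
#                Z ~ Bernoulli(0.8), so every Gaussian candidate model is
#                misspecified in its error distribution.

#' Generate a dataset from the two-model (null-truth) scenario
#'
#' The truth is intercept-only, `y = 1 + e`, `e ~ N(0,1)`; a single
#' candidate covariate `x1 ~ N(0,1)` independent of `y` is supplied, so the
#' all-subsets candidate set holds a correctly specified null and an
#' overspecified alternative.
#'
#' @param n Sample size (`>= 3`).
#' @param seed Optional integer seed.
#' @return A [bmf_data] object with one covariate.
#' @export
gen_two_model <- function(n, seed = NULL) {
  stopifnot(n >= 3)
  if (!is.null(seed)) set.seed(seed)
  y <- 1 + stats::rnorm(n)
  x <- stats::rnorm(n)
  bmf_data(y, matrix(x, ncol = 1), "x1")
}

# Covariates common to the correlated and mixture scenarios: trivariate
# normal, mean (1,1,1), unit variances, pairwise covariance 0.5.
gen_trivariate_x <- function(n) {
  Sigma <- matrix(0.5, 3, 3); diag(Sigma) <- 1
  X <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(Sigma) + 1
  colnames(X) <- c("x1", "x2", "x3")
  X
}

mean_structure <- function(X) 1 + 2 * X[, 1] + 1 * X[, 2] + 0 * X[, 3]

#' Generate a dataset from the correlated-covariate scenario
#'
#' `y = 1 + 2*x1 + 1*x2 + 0*x3 + e` with `e ~ N(0,1)` and `(x1,x2,x3)`
#' trivariate normal (means 1, unit variances, pairwise covariances 0.5).
#' Of the eight subset models, only the two containing both `x1` and `x2`
#' subsume the correct mean structure.
#'
#' @param n Sample size (`>= 5`).
#' @param seed Optional integer seed.
#' @return A [bmf_data] object with three covariates.
#' @export
gen_correlated <- function(n, seed = NULL) {
  stopifnot(n >= 5)
  if (!is.null(seed)) set.seed(seed)
  X <- gen_trivariate_x(n)
  bmf_data(mean_structure(X) + stats::rnorm(n), X)
}

#' Generate a dataset from the mixture-error (misspecified) scenario
#'
#' Same mean structure and covariate law as [gen_correlated()], but the
#' errors come from the centered two-component normal scale mixture
#' `Z * N(0, wide_var) + (1 - Z) * N(0, 1)`, `Z ~ Bernoulli(mix_prob)`.
#' The second parameter of each component is read as a VARIANCE, so the
#' default error variance is `0.8 * 3 + 0.2 * 1 = 2.6`; pass
#' `wide_var = 9` for the standard-deviation-3 reading.
#'
#' @param n Sample size (`>= 5`).
#' @param seed Optional integer seed.
#' @param wide_var Variance of the wide mixture component (default 3).
#' @param mix_prob Mixing probability of the wide component (default 0.8).
#' @return A [bmf_data] object with three covariates.
#' @export
gen_mixture <- function(n, seed = NULL, wide_var = 3, mix_prob = 0.8) {
  stopifnot(n >= 5, wide_var > 0, mix_prob >= 0, mix_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  X <- gen_trivariate_x(n)
  z <- stats::rbinom(n, 1, mix_prob)
  e <- stats::rnorm(n, 0, sqrt(ifelse(z == 1, wide_var, 1)))
  bmf_data(mean_structure(X) + e, X)
}

#' Configure a Monte Carlo selection study
#'
#' @param scenario One of `"two_model"`, `"correlated"`, `"mixture"`.
#' @param n Sample size per simulated dataset (`>= 2`).
#' @param S Number of simulated datasets (`>= 1`).
#' @param B Bootstrap replicates per dataset (`>= 1`).
#' @param adjusted Logical; use the bias-adjusted bootstrap AIC (default
#'   `TRUE`).
#' @param seed Integer master seed driving both data generation and the
#'   bootstrap.
#' @param wide_var,mix_prob Mixture-scenario error parameters (see
#'   [gen_mixture()]); ignored by the other scenarios.
#'
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario = c("two_model", "correlated", "mixture"),
                            n, S, B, adjusted = TRUE, seed = NULL,
                            wide_var = 3, mix_prob = 0.8) {
  scenario <- match.arg(scenario)
  stopifnot(n >= 2, S >= 1, B >= 1)
  structure(list(scenario = scenario, n = as.integer(n), S = as.integer(S),
                 B = as.integer(B), adjusted = isTRUE(adjusted), seed = seed,
                 wide_var = wide_var, mix_prob = mix_prob),
            class = "scenario_config")
}

scenario_generator <- function(config) {
  switch(config$scenario,
         two_model = function(n) gen_two_model(n),
         correlated = function(n) gen_correlated(n),
         mixture = function(n) gen_mixture(n, wide_var = config$wide_var,
                                           mix_prob = config$mix_prob))
}

scenario_names <- function(config) {
  if (config$scenario == "two_model") "x1" else c("x1", "x2", "x3")
}

# Original-sample AICs for every candidate model.
original_aics <- function(geom, data) {
  gof <- all_model_gof(geom, geom$Zfull, data$y)
  if (isTRUE(attr(gof, "bad")))
    stop("degenerate fit on an original sample for model '",
         attr(gof, "offender"), "'")
  gof + 2 * geom$ks
}

#' Empirical model selection probabilities under repeated sampling
#'
#' Draws `S` independent datasets from the scenario's generating model,
#' selects the AIC-minimizing candidate on each ORIGINAL sample (no
#' bootstrap), and returns the selection fractions. These fractions
#' estimate the multinomial selection-probability vector that bootstrap
#' model frequencies aim to approximate from a single sample.
#'
#' @param config A [scenario_config()] (its `B` and `adjusted` fields are
#'   not used here).
#' @param specs Optional candidate list; defaults to the full all-subsets
#'   set for the scenario's covariates.
#'
#' @return A named numeric vector of selection fractions (each a multiple
#'   of `1/S`, summing to 1).
#' @export
true_selection_probabilities <- function(config, specs = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  gen <- scenario_generator(config)
  if (is.null(specs)) specs <- enumerate_models(scenario_names(config))
  if (!is.null(config$seed)) set.seed(config$seed)
  data_seeds <- sample.int(.Machine$integer.max - 1L, config$S)
  geom <- NULL
  tally <- integer(length(specs))
  for (s in seq_len(config$S)) {
    set.seed(data_seeds[s])
    d <- gen(config$n)
    if (is.null(geom)) geom <- candidate_geometry(d, specs)
    else geom$Zfull <- cbind(rep(1, d$n), d$X)
    aics <- original_aics(geom, d)
    sel <- select_min_aic(aics, geom$ks)
    tally[sel] <- tally[sel] + 1L
  }
  stats::setNames(tally / config$S, geom$labels)
}

#' Run a full selection study: BMFs vs Akaike weights vs truth
#'
#' For each of `S` datasets drawn from the scenario's generating model, the
#' driver computes (a) the Akaike weights of every candidate on the
#' original sample, (b) the bootstrap model frequencies from `B` pairs
#' resamples, and (c) the identity of the AIC-selected model on the
#' original sample. Averaging (a) and (b) over datasets and tallying (c)
#' gives the three columns of the study table; the same `S` datasets are
#' used for all three.
#'
#' @param config A [scenario_config()].
#'
#' @return An object of class `"selection_study"`: a list with `table`
#'   (data frame: mask columns, `bmf`, `weight`, `probability`),
#'   `bmf_trace` and `weight_trace` (`S x` models matrices of per-dataset
#'   values), `selected` (per-dataset selected model index), `config`, and
#'   `redraws`. Each of the three summary columns sums to 1.
#' @examples
#' st <- run_study(scenario_config("two_model", n = 20, S = 5, B = 20,
#'                                 seed = 1))
#' st$table
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  gen <- scenario_generator(config)
  specs <- enumerate_models(scenario_names(config))
  m <- length(specs)
  if (!is.null(config$seed)) set.seed(config$seed)
  data_seeds <- sample.int(.Machine$integer.max - 1L, config$S)
  boot_seeds <- sample.int(.Machine$integer.max - 1L, config$S)
  bmf_trace <- matrix(NA_real_, config$S, m)
  weight_trace <- matrix(NA_real_, config$S, m)
  selected <- integer(config$S)
  geom <- NULL
  redraws <- 0L
  for (s in seq_len(config$S)) {
    set.seed(data_seeds[s])
    d <- gen(config$n)
    if (is.null(geom)) geom <- candidate_geometry(d, specs)
    aics <- original_aics(candidate_geometry(d, specs), d)
    weight_trace[s, ] <- akaike_weights(aics, geom$labels)$weight
    selected[s] <- select_min_aic(aics, geom$ks)
    run <- bmf(d, specs, B = config$B, adjusted = config$adjusted,
               seed = boot_seeds[s], keep_replicates = FALSE)
    bmf_trace[s, ] <- run$table$frequency
    redraws <- redraws + run$redraws
  }
  colnames(bmf_trace) <- colnames(weight_trace) <- geom$labels
  tab <- data.frame(geom$masks, check.names = FALSE)
  names(tab) <- scenario_names(config)
  tab$model <- geom$labels
  tab$bmf <- colMeans(bmf_trace)
  tab$weight <- colMeans(weight_trace)
  tab$probability <- tabulate(selected, m) / config$S
  structure(list(table = tab, bmf_trace = bmf_trace,
                 weight_trace = weight_trace, selected = selected,
                 config = config, redraws = redraws),
            class = "selection_study")
}

#' @export
print.selection_study <- function(x, ...) {
  cfg <- x$config
  cat("<selection_study> scenario =", cfg$scenario,
      sprintf("(n = %d, S = %d, B = %d, %s criterion)\n", cfg$n, cfg$S,
              cfg$B, if (cfg$adjusted) "adjusted" else "unadjusted"))
  tab <- x$table
  tab$bmf <- round(tab$bmf, 4)
  tab$weight <- round(tab$weight, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Asymptotic null-model selection probability for a nested pair
#'
#' When the smaller of two nested Gaussian models is true and their
#' dimensions differ by `dim_gap`, twice the log-likelihood-ratio between
#' the fits is asymptotically chi-squared with `dim_gap` degrees of
#' freedom, and AIC selects the smaller model exactly when that statistic
#' falls below the penalty difference. The selection probability is
#' therefore the chi-squared CDF evaluated at the penalty gap (by default
#' `2 * dim_gap`, the AIC value).
#'
#' @param dim_gap Dimension difference between the nested models (`>= 1`).
#' @param penalty_gap Point at which to evaluate the CDF (default
#'   `2 * dim_gap`).
#'
#' @return The probability that the smaller (true) model is selected.
#' @examples
#' analytic_null_probability(1)  # 0.8427
#' @export
analytic_null_probability <- function(dim_gap, penalty_gap = 2 * dim_gap) {
  stopifnot(dim_gap >= 1)
  stats::pchisq(penalty_gap, df = dim_gap)
}

#' Analytic bounds on Akaike weights for a true null in a nested pair
#'
#' With a true null model nested in an alternative `dim_gap` dimensions
#' larger, the likelihood-ratio statistic is nonnegative, so the AIC
#' difference exceeds `-2 * dim_gap` and the null-model weight is bounded
#' above by `1 / (1 + exp(-dim_gap))` while the alternative's weight is
#' bounded below by `1 / (1 + exp(dim_gap))`. The weight ratio
#' `w0 / w1` is correspondingly bounded by `exp(dim_gap)` and can never
#' reach the asymptotic selection-probability ratio: the structural reason
#' Akaike weights fail as selection-probability approximations.
#'
#' @param dim_gap Dimension difference (`>= 1`).
#'
#' @return A list with `upper_null`, `lower_alt` (summing to 1) and
#'   `ratio_bound = exp(dim_gap)`.
#' @examples
#' weight_bounds(1)  # 0.7311, 0.2689, 2.7183
#' @export
weight_bounds <- function(dim_gap) {
  stopifnot(dim_gap >= 1)
  list(upper_null = 1 / (1 + exp(-dim_gap)),
       lower_alt = 1 / (1 + exp(dim_gap)),
       ratio_bound = exp(dim_gap))
}
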