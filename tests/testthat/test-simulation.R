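test_that("two-model generator has the stated moments and is reproducible", {
  d1 <- gen_two_model(100, seed = 161)
  d2 <- gen_two_model(100, seed = 161)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$X, d2$X)

  big <- gen_two_model(1e5, seed = 162)
  expect_lt(abs(mean(big$y) - 1), 3 / sqrt(1e5))
  expect_lt(abs(cor(big$y, big$X[, 1])), 3 / sqrt(1e5))
})

test_that("correlated-covariate generator matches its trivariate law", {
  big <- gen_correlated(1e5, seed = 171)
  X <- big$X
  # pairwise covariance 0.5, SE of a sample covariance of bivariate normals
  se_cov <- sqrt((1 + 0.5^2) / 1e5)
  expect_lt(abs(cov(X[, 1], X[, 2]) - 0.5), 3 * se_cov)
  expect_lt(abs(cov(X[, 1], X[, 3]) - 0.5), 3 * se_cov)
  expect_true(all(abs(colMeans(X) - 1) < 3 * sqrt(1 / 1e5)))

  # OLS at n = 1e5 recovers beta = (1, 2, 1, 0) within 3 standard errors
  f <- fit_gaussian_ml(big, enumerate_models(big$names)[[8]])
  Z <- cbind(1, X)
  ses <- sqrt(diag(solve(crossprod(Z))) * f$sigma2_hat)
  expect_true(all(abs(f$beta_hat - c(1, 2, 1, 0)) < 3 * ses))

  # E[y] = 1 + 2 + 1 + 0 = 4
  expect_lt(abs(mean(big$y) - 4), 3 * sd(big$y) / sqrt(1e5))
})

test_that("mixture-error generator produces the stated scale mixture", {
  big <- gen_mixture(1e5, seed = 181)
  e <- big$y - (1 + 2 * big$X[, 1] + big$X[, 2])
  # Var = 0.8 * 3 + 0.2 * 1 = 2.6 under the variance reading of N(0, 3)
  se_var <- sd(e^2) / sqrt(1e5)
  expect_lt(abs(mean(e)), 3 * sd(e) / sqrt(1e5))
  expect_lt(abs(mean(e^2) - 2.6), 3 * se_var)
  # scale mixtures of centered normals are leptokurtic
  kurt <- mean((e - mean(e))^4) / var(e)^2
  expect_gt(kurt, 3)

  # the standard-deviation reading is available as an explicit variance
  wide <- gen_mixture(1e5, seed = 182, wide_var = 9)
  ew <- wide$y - (1 + 2 * wide$X[, 1] + wide$X[, 2])
  expect_lt(abs(mean(ew^2) - (0.8 * 9 + 0.2)), 3 * sd(ew^2) / sqrt(1e5))
})

test_that("analytic selection probabilities and weight bounds match closed forms", {
  expect_equal(analytic_null_probability(1), pchisq(2, 1))
  expect_equal(round(analytic_null_probability(1), 4), 0.8427)
  expect_equal(analytic_null_probability(1, penalty_gap = 0), 0)
  p <- analytic_null_probability(1)
  expect_equal(round(p / (1 - p), 4), 5.3573)
  expect_equal(analytic_null_probability(3), pchisq(6, 3))

  wb <- weight_bounds(1)
  expect_equal(round(wb$upper_null, 4), 0.7311)
  expect_equal(round(wb$lower_alt, 4), 0.2689)
  expect_equal(round(wb$ratio_bound, 4), 2.7183)
  expect_equal(wb$upper_null + wb$lower_alt, 1)
  wb2 <- weight_bounds(2)
  expect_equal(wb2$upper_null + wb2$lower_alt, 1)
  expect_equal(wb2$ratio_bound, exp(2))
})

test_that("empirical selection fractions are multinomial tallies", {
  cfg <- scenario_config("two_model", n = 20, S = 1, B = 1, seed = 191)
  p1 <- true_selection_probabilities(cfg)
  expect_equal(sort(p1, decreasing = TRUE), c(1, 0), ignore_attr = TRUE)

  cfg <- scenario_config("two_model", n = 20, S = 40, B = 1, seed = 192)
  ph <- true_selection_probabilities(cfg)
  expect_equal(sum(ph), 1)
  expect_true(all(abs(ph * 40 - round(ph * 40)) < 1e-9))
})

test_that("selection-fraction noise scales like the binomial standard error", {
  # quadrupling S should roughly halve the spread of the estimate
  reps <- 30
  est <- function(S, seed)
    true_selection_probabilities(
      scenario_config("two_model", n = 20, S = S, B = 1, seed = seed))[1]
  small <- vapply(1:reps, function(i) est(50, 7000 + i), numeric(1))
  large <- vapply(1:reps, function(i) est(200, 8000 + i), numeric(1))
  ratio <- sd(large) / sd(small)
  expect_gt(ratio, 0.25)
  expect_lt(ratio, 0.85)
})

test_that("study driver averages weights, BMFs and tallies over the same datasets", {
  st <- run_study(scenario_config("two_model", n = 20, S = 6, B = 15,
                                  seed = 201))
  expect_equal(sum(st$table$bmf), 1, tolerance = 1e-9)
  expect_equal(sum(st$table$weight), 1, tolerance = 1e-9)
  expect_equal(sum(st$table$probability), 1, tolerance = 1e-9)
  expect_equal(dim(st$bmf_trace), c(6L, 2L))
  expect_equal(unname(rowSums(st$bmf_trace)), rep(1, 6), tolerance = 1e-9)
  expect_equal(unname(rowSums(st$weight_trace)), rep(1, 6), tolerance = 1e-9)
  expect_equal(st$table$bmf, unname(colMeans(st$bmf_trace)))

  # degenerate S = 1, B = 1 run: every column is one-hot
  st1 <- run_study(scenario_config("correlated", n = 50, S = 1, B = 1,
                                   seed = 202))
  expect_equal(sort(st1$table$bmf, decreasing = TRUE)[1], 1)
  expect_equal(sort(st1$table$probability, decreasing = TRUE)[1], 1)
  expect_equal(sum(st1$table$weight), 1, tolerance = 1e-9)
})
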