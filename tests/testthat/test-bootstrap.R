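test_that("case resampling is reproducible and counts rows by index identity", {
  # tied outcome values: multiplicities must come from row indices, not values
  d <- bmf_data(c(1, 1, 2, 2, 3), matrix(1:5, 5, 1), "x1")
  r1 <- resample_cases(d, seed = 7)
  r2 <- resample_cases(d, seed = 7)
  expect_identical(r1$indices, r2$indices)
  expect_identical(r1$counts, r2$counts)
  expect_identical(sum(r1$counts), d$n)
  expect_identical(r1$counts, tabulate(r1$indices, d$n))

  # multinomial(n, 1/n) moments: E[count_i] = 1, Var[count_i] = 1 - 1/n
  d <- bmf_data(rnorm(5))
  set.seed(8)
  counts <- t(replicate(10000, resample_cases(d)$counts))
  se <- sqrt((1 - 1 / 5) / 10000)
  expect_true(all(abs(colMeans(counts) - 1) < 3 * se))
})

test_that("bootstrap AIC satisfies the penalty identities", {
  d <- make_dataset(30, 2, seed = 61)
  rep1 <- resample_cases(d, seed = 62)
  db <- bmf_data(d$y[rep1$indices], d$X[rep1$indices, , drop = FALSE], d$names)
  specs <- enumerate_models(d$names)
  for (s in specs) {
    fs <- fit_gaussian_ml(db, s)
    unadj <- bootstrap_aic(fs, adjusted = FALSE)
    adj <- bootstrap_aic(fs, adjusted = TRUE)
    expect_equal(adj - unadj, fs$k)
    expect_equal(unadj, -2 * fs$loglik + 2 * fs$k)
    expect_equal(unadj,
                 -2 * oracle_loglik(db$y, drop(cbind(1, db$X[, s$mask, drop = FALSE])
                                               %*% fs$beta_hat), fs$sigma2_hat) +
                   2 * fs$k,
                 tolerance = 1e-10)
  }
  # intercept-only: total adjusted penalty is 3k = 6
  f0 <- fit_gaussian_ml(db, specs[[1]])
  expect_equal(bootstrap_aic(f0, adjusted = TRUE), -2 * f0$loglik + 6)
})

test_that("plug-in discrepancy evaluates the bootstrap fit on the original sample", {
  d <- make_dataset(25, 2, seed = 71)
  spec <- enumerate_models(d$names)[[4]]

  # fitted on the original data itself: equals -2 loglik = AIC - 2k
  f0 <- fit_gaussian_ml(d, spec)
  expect_equal(plugin_discrepancy(f0, d), f0$aic - 2 * f0$k)
  expect_equal(plugin_discrepancy(f0, d), -2 * f0$loglik)

  # fitted on a resample: matches the per-observation density-sum oracle
  rep1 <- resample_cases(d, seed = 72)
  db <- bmf_data(d$y[rep1$indices], d$X[rep1$indices, , drop = FALSE], d$names)
  fs <- fit_gaussian_ml(db, spec)
  mu <- drop(cbind(1, d$X[, spec$mask, drop = FALSE]) %*% fs$beta_hat)
  per_row <- vapply(seq_len(d$n), function(i)
    -2 * oracle_loglik(d$y[i], mu[i], fs$sigma2_hat), numeric(1))
  expect_equal(plugin_discrepancy(fs, d), sum(per_row), tolerance = 1e-10)

  # ML dominance: no other parameter value beats the ML fit on y
  expect_gte(plugin_discrepancy(fs, d), -2 * f0$loglik)
})

test_that("EIC is reproducible and tracks AIC in a correctly specified model", {
  d <- gen_two_model(40, seed = 81)
  spec <- enumerate_models(d$names)[[1]]
  e1 <- eic(d, spec, B = 30, seed = 82)
  e2 <- eic(d, spec, B = 30, seed = 82)
  expect_identical(e1, e2)
  expect_gt(e1$optimism, 0)   # refitting on the resample is always optimistic

  # both AIC and EIC estimate the expected discrepancy: their means over
  # datasets agree within Monte Carlo error (correct specification, n large)
  S <- 200; B <- 500; n <- 200
  set.seed(83)
  seeds <- sample.int(1e6, S)
  diffs <- vapply(seq_len(S), function(s) {
    ds <- gen_two_model(n, seed = seeds[s])
    sp <- enumerate_models(ds$names)[[1]]
    f <- fit_gaussian_ml(ds, sp)
    eic(ds, sp, B = B, seed = seeds[s] + 1L)$eic - f$aic
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(S))
})

test_that("bootstrap model frequencies count selections and recompute exactly", {
  d <- make_dataset(40, 2, seed = 91)
  specs <- enumerate_models(d$names)

  # single-model candidate set: frequency 1 regardless of data
  one <- bmf(d, specs[1], B = 25, seed = 92)
  expect_equal(one$table$frequency, 1)

  run <- bmf(d, specs, B = 200, seed = 93)
  expect_equal(sum(run$table$count), run$B)
  expect_equal(sum(run$table$frequency), 1)

  # brute-force recount from the stored per-replicate criterion values
  ks <- vapply(specs, function(s) sum(s$mask) + 2L, integer(1))
  recount <- integer(length(specs))
  for (r in run$replicates) {
    sel <- oracle_select(r$aics_star, ks)
    expect_identical(sel, r$selected)
    recount[sel] <- recount[sel] + 1L
    # zero-filled coefficients: excluded covariates are exactly 0
    excluded <- c(FALSE, !specs[[sel]]$mask)
    expect_true(all(r$beta_star[excluded] == 0))
    expect_identical(sum(r$counts), d$n)
  }
  expect_identical(recount, run$table$count)
})

test_that("adjusted and unadjusted runs share resamples and order model size", {
  for (seed in c(111, 112, 113)) {
    d <- gen_correlated(25, seed = seed)
    specs <- enumerate_models(d$names)
    ks <- vapply(specs, function(s) sum(s$mask) + 2L, integer(1))
    adj <- bmf(d, specs, B = 150, adjusted = TRUE, seed = seed + 1000L)
    una <- bmf(d, specs, B = 150, adjusted = FALSE, seed = seed + 1000L)
    for (b in seq_len(adj$B)) {
      expect_identical(adj$replicates[[b]]$indices, una$replicates[[b]]$indices)
      # stiffer penalty can never select a larger model on the same resample
      expect_lte(ks[adj$replicates[[b]]$selected],
                 ks[una$replicates[[b]]$selected])
    }
    # hence no less mass on the smaller model of any nested pair
    expect_gte(adj$table$frequency[1] + 0, una$table$frequency[1] - 1e-12)
  }
})
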