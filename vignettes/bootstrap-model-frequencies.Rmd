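---
title: "Bootstrap model frequencies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap model frequencies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmfboot)
```

# The estimand: model selection probabilities

Take a continuous outcome $y$ of length $n$ and $p-1$ candidate
covariates, and let $\mathcal{M} = \{M_1, \dots, M_{2^{p-1}}\}$ be the
all-subsets candidate collection (every model keeps the intercept). Each
model is fitted by Gaussian maximum likelihood — least squares for the
mean, $\hat\sigma^2 = \mathrm{RSS}/n$ for the variance — and scored by

$$\mathrm{AIC} = -2\,\ell(\hat\theta \mid y) + 2k,$$

where $k$ counts the mean parameters *plus one* for $\sigma^2$. Counting
$\sigma^2$ matters: it makes an intercept-only model $k = 2$ and makes
nested models that differ by one covariate differ by exactly one
dimension, which is the geometry all the analytic results below use.

Under repeated sampling from the truth, the indicator "model $M_i$
minimizes AIC" makes the selection tallies over $S$ samples
multinomial$(S, \pi)$. The vector $\pi$ of **selection probabilities** is
the uncertainty the usual select-then-infer workflow throws away, and it
is the estimand of this package.

## Why Akaike weights are not selection probabilities

The Akaike weight $w_i \propto e^{-\Delta_i/2}$ is a fine relative
plausibility measure, but treating it as $P(M_i)$ equates the log
relative risk with $-\tfrac12(\mathrm{AIC}_i - \mathrm{AIC}_j)$. For a
true null nested one dimension below an alternative, the
likelihood-ratio statistic is nonnegative, so
$\mathrm{AIC}_0 - \mathrm{AIC}_1 > -2$ always, giving the *pointwise*
bounds $w_0 < 1/(1+e^{-1}) = 0.7311$ and $w_1 > 1/(1+e^{1}) = 0.2689$,
and a weight ratio capped at $e = 2.7183$. The actual asymptotic
selection probability is $P(\chi^2_1 \le 2) = 0.8427$, a relative risk of
$5.3573$ — unreachable by the weights. `analytic_null_probability()` and
`weight_bounds()` expose these closed forms; the test suite checks the
bounds hold for *every* simulated dataset, not just on average.

# Bootstrap model frequencies and the penalty ladder

The bootstrap estimate of $\pi_i$ repeats the selection on pairs
(case) resamples: draw rows of $(y, X)$ jointly with replacement, fit
every candidate to the same resample, record the winner, and average the
indicator over $B$ replicates (`bmf()`).

Resampling the *selection criterion* is where the bias enters. Writing
$d(\cdot)$ for $-2 \times$ log-likelihood evaluations, three
configurations arise, and each estimates the expected Kullback–Leibler
discrepancy of the fitted model after adding a different penalty:

| evaluation | penalty | reading |
|---|---|---|
| $-2\ell(\hat\theta^* \mid y)$ | $+k$ | pseudo out-of-sample: fit on the resample, score on the original |
| $-2\ell(\hat\theta \mid y)$ | $+2k$ | the classical AIC situation |
| $-2\ell(\hat\theta^* \mid y^*)$ | $+3k$ | fit and score on the same resample |

The third row is the one the naive bootstrap AIC uses with only $+2k$:
the bootstrap-fitted likelihood meets the very resample that produced it,
and that resample's duplicated rows hold fewer independent pieces of
information than $y$, so the optimism exceeds the classical $2k$ by a
further $k$. The package therefore defines the **bias-adjusted**
bootstrap criterion $\mathrm{AIC}^*_{\mathrm{adj}} = -2\ell(\hat\theta^*
\mid y^*) + 3k$ and uses it by default (`adjusted = TRUE`); the
unadjusted variant is retained for paired comparisons. Because the extra
penalty grows with $k$, on any shared resample the adjusted criterion can
never select a larger model than the unadjusted one — a monotonicity the
tests assert replicate by replicate.

The ladder is not taken on faith: the acceptance tests simulate a
correctly specified null scenario ($n = 200$, 200 datasets, 200
replicates — sizes chosen so each rung's Monte Carlo standard error is a
few hundredths) and verify that the three penalty-completed rows agree
within three combined standard errors, and `eic()` exposes the
bootstrap-estimated-optimism criterion whose dataset-mean must agree with
AIC under correct specification.

# Bootstrap smoothing

Each replicate's winning model yields a coefficient vector with zeros in
the unselected positions (the intercept, present everywhere, is smoothed
like any coefficient). `smoothed_estimates()` averages these vectors;
`smoothed_sd()` computes, per original row $i$ and coefficient $j$,

$$\widehat{\mathrm{cov}}_{ij} = \frac1B \sum_b (Y^*_{bi} - \bar Y_i)
(\hat\beta^*_j(b) - \tilde\beta_j), \qquad
\widetilde{sd}_j = \Big(\sum_i \widehat{\mathrm{cov}}_{ij}^2\Big)^{1/2},$$

with $Y^*_{bi}$ the multiplicity of row $i$ in resample $b$; and
`smoothed_ci()` forms $\tilde\beta_j \pm 1.96\,\widetilde{sd}_j$.

Three choices deserve a note:

* **Counts are by row index, not value.** Defining $Y^*_{bi}$ by
  matching outcome *values* is ambiguous when $y$ has ties; multiplicity
  of the row index is the well-defined reading and is what the resampler
  records.
* **$\bar Y_i$ is estimated from the replicates actually drawn**, not
  fixed at its theoretical value 1: the estimator is stated for the
  finite-$B$ ("non-ideal") setting and should be internally consistent
  at any $B$. No small-$B$ bias correction is applied; results always
  carry $B$ so readers can judge.
* **$z = 1.96$ by default.** The multiplier is exposed for other levels,
  but the default matches the convention used in the package's reports.

# Simulation scenarios

`scenario_config()` + `run_study()` drive three generators. Their
defaults *are* the study conditions; they are not tuning knobs.

* **two_model** — intercept-only truth $y = 1 + \varepsilon$,
  $\varepsilon \sim N(0,1)$, plus one irrelevant $N(0,1)$ covariate. The
  minimal setting in which weights, BMFs and the truth can all be
  computed and compared; headline sizes $n = 20$, $S = 500$, $B = 1000$.
* **correlated** — $y = 1 + 2x_1 + 1x_2 + 0x_3 + \varepsilon$,
  $\varepsilon \sim N(0,1)$, covariates trivariate normal with means 1,
  unit variances, pairwise covariances $0.5$. Two of the eight subsets
  subsume the truth; the correlation makes underspecified models
  genuinely competitive at small $n$. Headline sizes $n = 1000$,
  $S = 100$, $B = 100$.
* **mixture** — same mean structure and covariates, errors from
  $Z\,N(0,3) + (1-Z)\,N(0,1)$ with $Z \sim \mathrm{Bernoulli}(0.8)$, so
  every Gaussian candidate is misspecified in its error law. The second
  component parameter is read as a **variance** (error variance
  $0.8\cdot3 + 0.2\cdot1 = 2.6$); the convention is ambiguous in common
  usage, so `gen_mixture(wide_var = 9)` runs the standard-deviation-3
  reading. The variance reading is the default because "N(mean,
  variance)" is the dominant convention in the statistics literature the
  method sits in.

One analytic anchor is worth recording. In the two-model scenario the
squared sample correlation of an irrelevant regressor is
$\mathrm{Beta}(\tfrac12, \tfrac{n-2}2)$, so the probability that AIC
keeps the null is *exactly*

$$P\!\left(R^2 \le 1 - e^{-2/n}\right)
 = \texttt{pbeta}\!\left(1 - e^{-2/n}, \tfrac12, \tfrac{n-2}2\right),$$

which is `r round(pbeta(1 - exp(-2/20), 0.5, 9), 4)` at $n = 20$ and
approaches the $\chi^2_1$ value 0.8427 as $n \to \infty$. Published
Monte Carlo tables for such studies are themselves estimates with
binomial standard errors ($\approx 0.016$ at $S = 500$, $\approx 0.042$
at $S = 100$), and replications should be judged against those errors,
which is why every stochastic tolerance in the test suite is computed
from the run itself (three empirical standard errors of the reported
mean, or three binomial standard errors for a selection fraction) rather
than hard-coded.

What the generators do **not** emulate: non-Gaussian outcomes beyond the
scale-mixture errors, heteroscedasticity linked to covariates, missing
data, measurement error, and model spaces other than all-subsets linear
regression. Passing tests say the machinery is faithful to these
idealized laws, not that BMFs are well calibrated for an arbitrary real
dataset.

# Numerical policies

* **Ties.** `select_min_aic()` breaks exact AIC ties toward the smaller
  $k$, then the lower index. Ties have probability zero under continuous
  data but occur in constructed examples; the rule keeps every downstream
  count deterministic.
* **Degenerate resamples.** A resample can make a candidate design
  rank-deficient or fit with zero residual variance (unbounded
  likelihood), especially at small $n$. Such replicates are discarded
  and redrawn, with a total budget of $100B$ draws; exceeding the budget
  is an error naming the offending model, and every run reports its
  redraw count. This is a package policy for handling pathologies, not
  part of the estimand.
* **RNG.** A single master seed yields one derived seed per replicate
  (`substream_seeds()`), so replicate $b$ is reproducible in isolation
  and adjusted/unadjusted runs with the same seed see *identical*
  resamples — selection consumes no randomness. All drivers derive
  per-dataset seeds the same way.
* **Overflow.** Weights are computed from $\Delta_i$, never from raw
  AIC values, making them exactly shift-invariant and overflow-proof.
* **Degenerate-fit detection** uses a relative residual threshold
  ($\mathrm{RSS} \le 10^{-12} \sum y_i^2$) rather than exact zero, so a
  constant outcome is caught in floating point.

# Problem sizes and limitations

The shipped checks run the studies at their headline sizes (the
two-model study at $S = 500, B = 1000$; the $n = 1000$ scenarios at
$S = 100, B = 100$; the penalty ladder at $n = 200$ with $200 \times
200$ replicates), which keeps the whole suite at a couple of minutes on
one CPU. Larger $S$ and $B$ tighten the Monte Carlo tolerances
proportionally to $\sqrt{S}$.

Known limitations: the candidate space is all-subsets Gaussian linear
regression only (no GLMs, no penalized selection); intervals are
normal-theory smoothed intervals (no percentile or BCa variants); the
$3k$ adjustment is an asymptotic result for candidates subsuming the
truth, and at very small $n$ or under strong misspecification BMFs and
true selection probabilities can both drift from their large-sample
behavior — the misspecified mixture scenario exists precisely to observe
that drift.
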