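# bmfboot

Bootstrap model frequencies for multimodel inference in all-subsets
Gaussian linear regression.

## The problem

When a regression model is chosen from a candidate set by the Akaike
information criterion (AIC) and inference then proceeds as if that model
had been fixed in advance, the sampling variability of the *selection
step* is ignored: standard errors shrink, p-values and confidence
intervals become optimistic, and results are hard to replicate. A
frequentist accounting of this uncertainty needs the **model selection
probabilities** — for each candidate model `M_i`, the probability
`π_i = P(Δ_i = 0)` that it minimizes AIC under repeated sampling, where
`Δ_i = AIC_i − min_j AIC_j`. Across `S` hypothetical samples the selection
tallies are multinomial(`S`, `π`).

Akaike weights,

```
w_i = exp(−Δ_i/2) / Σ_j exp(−Δ_j/2),
```

are widely used as a surrogate for `π`, but they cannot play that role:
for a true null model nested one dimension below an alternative, the
weight ratio `w_0/w_1` is bounded above by `e ≈ 2.7183`, while the actual
selection-probability ratio is `P(χ²₁ ≤ 2)/(1 − P(χ²₁ ≤ 2)) ≈
0.8427/0.1573 ≈ 5.36` — a value the weights can never attain.

`bmfboot` instead estimates `π` by **bootstrap model frequencies (BMFs)**:
repeat the whole selection on pairs-bootstrap resamples and record how
often each model wins,

```
P*(M_i) = (1/B) Σ_b 1{Δ*_i(b) = 0}.
```

The subtlety is that the naive bootstrap criterion
`AIC* = −2ℓ(θ̂*|y*) + 2k` is biased: the bootstrap-fitted likelihood is
evaluated on the very resample used to fit it, whose duplicated rows carry
less information than the original sample. Matching the optimism of the
three ways a fitted likelihood can meet a sample gives a penalty ladder —
`k` for `−2ℓ(θ̂*|y)`, `2k` for `−2ℓ(θ̂|y)`, and `3k` for `−2ℓ(θ̂*|y*)` —
so the **bias-adjusted** bootstrap criterion is `AIC* + k` (total penalty
`3k`). The package implements both variants; the adjusted one is the
default.

On top of the frequencies, the package computes Efron-style
**bootstrap-smoothed** coefficient estimates: each replicate contributes
its selected model's coefficients (zeros for unselected covariates),

```
β̃_j = (1/B) Σ_b β̂*_j(b),
sd̃_j = ( Σ_i cov̂_ij² )^{1/2},   cov̂_ij = (1/B) Σ_b (Y*_bi − Ȳ_i)(β̂*_j(b) − β̃_j),
```

where `Y*_bi` counts how often original row `i` appears in resample `b`,
with the smoothed 95% interval `β̃_j ± 1.96·sd̃_j`.

## Worked example

```r
library(bmfboot)

d     <- gen_correlated(1000, seed = 2)       # y = 1 + 2 x1 + 1 x2 + 0 x3 + N(0,1)
specs <- enumerate_models(d$names)            # 8 subset models
aics  <- sapply(specs, function(s) fit_gaussian_ml(d, s)$aic)

akaike_weights(aics, sapply(specs, `[[`, "label"))[4, ]
#>   model     aic delta    weight
#> 4 x1+x2 2817.97     0 0.5052747

run <- bmf(d, specs, B = 1000, adjusted = TRUE, seed = 3)
run$table[run$table$count > 0, ]
#>      model count frequency
#> 4    x1+x2   606     0.606
#> 8 x1+x2+x3   394     0.394

smooth_coefficients(run)
#> <smoothed_result>B = 1000 replicates, z = 1.96
#>     variable estimate      se   ci_low ci_high
#>  (Intercept)  1.04752 0.07770  0.89523  1.1998
#>           x1  1.89824 0.05371  1.79297  2.0035
#>           x2  1.04241 0.05448  0.93564  1.1492
#>           x3  0.03532 0.05878 -0.07988  0.1505
```

Only the two models that subsume the true mean structure receive any
mass. On this sample the parsimonious `{x1, x2}` model carries an Akaike
weight of 0.51 but a bias-adjusted BMF of 0.61; the weight understates
how often the selection would actually land on it. The smoothed
estimates recover the generating coefficients `(1, 2, 1, 0)` with
intervals that fold the 39% of replicates choosing the full model into
the uncertainty for `x3`.

Monte Carlo drivers reproduce the package's simulation studies end to
end — here the null-truth study in which the average BMF (0.738) tracks
the empirical selection fraction (0.796) far better than the average
Akaike weight (0.597) does:

```r
st <- run_study(scenario_config("two_model", n = 20, S = 500, B = 1000, seed = 101))
st$table
#>  x1       model      bmf    weight probability
#>   0 (intercept) 0.738168 0.5973525       0.796
#>   1          x1 0.261832 0.4026475       0.204
```

The `fit` and `simulate` subcommands of `inst/cli/bmfboot.R` expose the
same functionality from the shell, reading a CSV and writing TSV reports:

```sh
Rscript inst/cli/bmfboot.R fit --data trial.csv --outcome y \
    --covariates treatment,sex,age --bootstraps 1000 --smooth --seed 1 --out run1
Rscript inst/cli/bmfboot.R simulate --scenario correlated --n 1000 \
    --datasets 100 --bootstraps 100 --seed 1 --out study1
```

## Documentation

The methods vignette (`vignettes/bootstrap-model-frequencies.Rmd`)
derives the penalty ladder, documents the simulation scenarios, the
numerical policies (tie-breaks, degenerate resamples, RNG substreams) and
the known limitations.
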