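Package: bmfboot
Title: Bootstrap Model Frequencies for Multimodel Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Approximates model selection probabilities for all-subsets
    Gaussian linear regression by bias-adjusted bootstrap model frequencies
    (BMFs), contrasts them with Akaike weights, and produces
    bootstrap-smoothed coefficient estimates with smoothed standard errors
    and confidence intervals that account for model-selection uncertainty.
    The naive bootstrap analogue of the Akaike information criterion is
    optimistic because the bootstrap-fitted likelihood is evaluated on the
    very resample used to fit it; the package applies the extra penalty of
    one parameter count per model that restores approximate unbiasedness
    for the expected Kullback-Leibler discrepancy, and provides Monte Carlo
    drivers for the simulation scenarios that exhibit the correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
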