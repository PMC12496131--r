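Package: acmglr
Title: Calibration of Variant Effect Scores into ACMG/AMP Evidence Strengths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts continuous variant-effect scores, from multiplexed assays
    of variant effects (MAVEs) or computational variant effect predictors,
    into positive likelihood ratios of pathogenicity with confidence bounds,
    ACMG/AMP evidence-strength assignments, and per-level score thresholds.
    Class-conditional score densities are estimated by bootstrapped Gaussian
    kernel density estimation with biased cross-validation bandwidths,
    stabilised by adaptive shrinkage and isotonic regression, and summarised
    by sign-test confidence intervals for the median log likelihood ratio.
    Evidence-strength likelihood points are derived from the ACMG/AMP
    combining rules under a user-specified prior probability of pathogenicity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
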