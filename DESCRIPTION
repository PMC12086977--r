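Package: litterdecay
Title: Decay-Rate Estimation and Mixture Additivity for Litterbag Experiments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for litterbag decomposition experiments with
    factorial rainfall-exclusion designs. Estimates instantaneous per-bag decay
    rates and multi-group linearized negative-exponential (Olson) decay slopes
    with shared intercept, tests litter-mixture additivity against averaged
    monospecific rates, computes rank-concordance statistics (Kendall's W,
    Spearman correlation), summarizes plot-level environmental covariates
    (soil-moisture grids, growing degree-days, basal-area-weighted shade
    tolerance, compositional soil texture) with permutation group tests, and
    generates synthetic experiments with the statistical structure the
    estimators assume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
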