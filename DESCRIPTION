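Package: idscale
Title: Forecasting How Identification Accuracy Scales with Population Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for statistical disclosure control and biometric risk
    assessment: models the sizes of anonymity sets in a gallery of records
    with a two-parameter Pitman-Yor prior and derives closed-form expected
    correctness (rank-1 identification rate), population uniqueness, and
    k-anonymity violation rates as functions of population size. Fits the
    prior to observed anonymity-set frequency data by maximum a posteriori
    estimation of the exchangeable partition likelihood, and extrapolates
    measured correctness curves from small-scale identification experiments
    to much larger populations, with entropy-only, exponential-decay,
    power-law, and random baselines for comparison. Includes generators for
    synthetic geometric, Poisson, and Zipf galleries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
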