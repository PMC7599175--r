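Package: neoprog
Title: Two-Step Neurodevelopmental Outcome Prediction for Very Preterm Infants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-step predictor of motor and cognitive
    developmental delay in very preterm infants from MR spectroscopy
    metabolite ratios and diffusion tensor imaging characteristics measured
    at term-equivalent age. Step one screens characteristics by their
    localisation degree (the fraction of the eight equal-width octiles of a
    characteristic's pooled range occupied by delayed infants' values) and
    builds developmental-delay common relaxed zones; infants outside the
    zones are classified as normally developing. Step two classifies zone
    members with an ensemble of single-hidden-layer feed-forward neural
    networks trained under fourfold cross-validation, combined by per-type
    majority voting and a final two-vote aggregation. Includes a synthetic
    cohort generator with class-conditional feature distributions, clinical
    confusion-matrix bookkeeping (sensitivity, specificity, PPV, NPV at
    in-zone and whole-dataset scope), and a reproducible end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nnet,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
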