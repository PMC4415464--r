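Package: twostageval
Title: Conditionally Unbiased Inference for Two-Stage Diagnostic Test
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Point estimation and exact inference for the sensitivity of a
    binary diagnostic classifier selected at the interim analysis of a
    two-stage validation study.  When the best of several candidate
    classifiers is carried forward to a confirmatory stage, the pooled
    maximum likelihood estimate of its sensitivity is biased high and naive
    confidence intervals under-cover.  The package computes the uniformly
    minimum variance conditionally unbiased estimator (UMVCUE) under
    arbitrary futility cut-offs, generalized ranking rules and unequal
    stage-one sample sizes, exact conditional (Sill-Sampson type) and
    Clopper-Pearson confidence intervals, selection-aware nonparametric
    bootstrap intervals, interval-backed one-sided hypothesis tests, trial
    simulation drivers for bias/MSE, coverage and operating-characteristic
    studies, a correlated-binary data generator, and the Fisher's-exact-test
    threshold and balanced-accuracy ranking machinery used by family history
    questionnaire validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
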