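Package: methylmetrics
Title: Beta- and M-Value Metrics and Titration-Based Evaluation for
    Infinium Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying DNA methylation from Illumina
    Infinium-style two-channel intensity data. Computes Beta-values and
    M-values from methylated/unmethylated probe intensities,
    inter-converts them through the logit relationship, and diagnoses
    the heteroscedasticity of the Beta-value scale via mean-standard
    deviation binning on technical replicates. Includes a synthetic
    titration-experiment simulator with known ground truth, detection
    p-value prefiltering, simple scaling normalization, Welch's t-test
    based differential methylation calling with range grouping and
    difference thresholds, and a correlation-based true-positive
    framework producing top-N and threshold-sweep performance curves
    with data-driven difference-threshold guidance.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
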