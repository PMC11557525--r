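Package: hdmea
Title: Feature Extraction and Analysis for HD-MEA Cardiomyocyte Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts electrophysiological features from high-density
    microelectrode-array (HD-MEA) recordings of cardiomyocyte cultures:
    extracellular field-potential features (R-spike amplitude and width,
    field-potential duration), conduction speed by fitting beat latencies to a
    cone-shaped surface, time-domain heart-rate-variability metrics, and
    intracellular-like action-potential features (APD50/APD90). Includes a
    synthetic-recording generator with analytic ground truth, a parallel batch
    pipeline persisting timestamped feature rows to an SQL store, and a
    feature-analysis backend (Spearman correlation triage, variance-inflation
    screening, similarity clustering, stratified cross-validated
    classification, majority baseline, permutation importance, and
    Mann-Whitney group comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    parallel,
    purrr,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    jsonlite,
    optparse,
    randomForest,
    readr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
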