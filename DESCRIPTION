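Package: antihep
Title: Heartbeat-Aware Event-Related Potential Analysis of Mental Workload
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how heartbeat-evoked
    potentials (HEPs) interfere with event-related potentials (ERPs). Generates
    synthetic multichannel EEG with a condition-dependent P600 component,
    R-peak-locked alpha-band HEP components and artifact transients; reproduces
    a standard ERP preprocessing chain (down-sampling, common average
    reference, amplitude-threshold epoch rejection, epoching and baseline
    correction); partitions target-locked epochs into heartbeat-affected and
    heartbeat-free sets from R-peak latencies; extracts P600 mean amplitude and
    peak latency on eight scalp electrodes; and compares low- versus high-
    mental-workload conditions with paired tests, Hedges' g effect sizes with
    confidence intervals, Bonferroni families, partial correlations and a
    cross-validated RBF-SVM classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
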