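Package: rsnr
Title: Condition-Specific Gene Selection for Time-Course Expression
    Classification via the Relative Signal-to-Noise Ratio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies genes relevant to a specific experimental condition
    in multi-condition (time-course or static) expression data using the
    relative signal-to-noise ratio (rSNR), the ratio of a gene's
    signal-to-noise ratio within the condition of interest to its
    signal-to-noise ratio across unrelated conditions. Provides transition
    profiles (difference and mean of two time points), a Pearson-correlation
    1-nearest-neighbor classifier with per-condition feature subsets,
    baseline selectors (two-class SNR, Welch's t statistic, random and
    protein-interaction-based selection), leave-one-out cross-validation in
    two replicate-handling scenarios, query-versus-database ROC/AUC
    evaluation, and a synthetic data generator with planted
    condition-specific genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
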