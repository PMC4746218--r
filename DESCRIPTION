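Package: tcut
Title: Tumor-Size Threshold Selection by Genome-Wide Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects the tumor-size cut point that best separates two patient
    groups by genome-wide differential expression across one or more expression
    studies. Implements three objectives scanned over a grid of candidate
    thresholds: Fisher's inverse chi-square meta-score built on per-gene
    Wilcoxon-Mann-Whitney p-values, the mDEDS multi-statistic distance
    synthesis (t, SAM, fold change, B, moderated t and moderated F statistics
    against a permutation-calibrated extreme point), and a totally-extreme-point
    (TEP) variant that shares one extreme point across the whole scan. Includes
    a synthetic-data generator emulating multi-cohort microarray studies with
    normal, gamma and Poisson expression blocks for download-free validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
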