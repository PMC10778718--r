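Package: edrna
Title: Exosomal RNA Fold Changes and Blood-Count Dynamics for Early-Death
    Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of paired (pre- versus on-treatment)
    plasma exosomal RNA sequencing counts and serial complete-blood-count
    (CBC) dynamics in chemoradiotherapy cohorts. Implements detection
    filtering, trimmed-mean-of-M-values (TMM) normalization and
    per-patient log2 fold changes; CBC dynamics features (baseline, nadir,
    geometric mean, week-2 value, log recovery ratio, and the NLR/PLR/LMR
    ratios); outcome-group assignment and propensity-score-matched group
    comparisons; RNA-CBC-outcome Pearson correlation matrices with a
    homeostasis screen; correlation-network construction of early-death
    associated RNAs; key-RNA selection by exhaustive all-subsets
    regression inclusion frequency and all-CBC coverage; and three-RNA
    composite-score stratification of disease-specific survival. A
    synthetic-cohort generator with planted driver RNAs makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    igraph
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    fgsea,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
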