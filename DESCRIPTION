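Package: chemoscreen
Title: Chemogenomic Screening-Library Design and Imaging-Screen Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analytic procedures for designing target-annotated anticancer
    compound libraries and for analysing imaging-based phenotypic screens.
    Covers bioactivity curation (replicate aggregation, potency cutoffs,
    target-specific and global percentile activity filters), molecular
    fingerprint similarity with near-duplicate removal, data-driven selection
    of a compound-similarity threshold by a Kolmogorov-Smirnov/AIC grid scan,
    protein-interaction target-space expansion, per-target representative
    selection with availability substitution and coverage accounting, and
    survival-fraction/z-score/dose-AUC readouts with two-component Gaussian
    mixture hit calling. Seeded synthetic-data generators emulate the
    statistical structure of each stage so the whole pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, ChemmineR, ChemmineOB, igraph,
    pracma, mclust, jsonlite, yaml, optparse
biocViews: CellBasedAssays, Cheminformatics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
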