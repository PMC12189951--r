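Package: endoscore
Title: Day-of-Cycle Calibrated Percentile Scoring of Endometrial Marker-Gene Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for endometrial diagnostic scoring from droplet
    digital PCR marker-gene copy numbers. Builds day-indexed (days after the
    LH surge) reference distributions for the stromal decidual-reaction ratio
    (PLA2G2A/DIO2) and the uterine NK expansion ratio (ITGAD/CD160), choosing
    between gamma and log-normal families by the Cramer-von Mises criterion;
    converts samples to percentile ranks, quartile bins and binary state
    flags; analyses paired-cycle biopsies with 4x4 quartile contingency
    tables, Fisher/chi-square enrichment and recurrence rates; and estimates
    pregnancy-outcome odds ratios with optional exclusion of aneuploid
    losses. Includes a Gaussian-copula synthetic cohort generator so every
    stage can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
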