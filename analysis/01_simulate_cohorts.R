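#!/usr/bin/env Rscript
# Generates the three synthetic study cohorts used throughout the analysis:
# a single-biopsy calibration cohort (n = 779, the size of the timed-biopsy
# reference series), a paired-biopsy cohort (316 women, two cycles each)
# and a prospective pre-pregnancy outcome cohort (n = 261).

suppressPackageStartupMessages(library(endoscore))
dir.create("results/cohorts", showWarnings = FALSE, recursive = TRUE)
seed <- 20260923L

params <- simulation_params(seed = seed)

reference <- simulate_reference_cohort(params, n = 779)
write_cohort_csv(reference, "results/cohorts/reference.csv")
message(sprintf("reference cohort: %d biopsies, LH+%d..LH+%d",
                nrow(reference), min(reference$lh_day),
                max(reference$lh_day)))

paired <- simulate_paired_cohort(params, n_pairs = 316, seed = seed + 1L)
write_cohort_csv(paired, "results/cohorts/paired.csv")
message(sprintf("paired cohort: %d biopsies from %d subjects",
                nrow(paired), length(unique(paired$subject_id))))

outcome <- simulate_outcome_cohort(params, n = 261, seed = seed + 2L)
write_cohort_csv(outcome, "results/cohorts/outcome.csv")
s <- outcome_summary(outcome)
message(sprintf(
  "outcome cohort: %d subjects, %d miscarriages (%.1f%%), %d karyotyped",
  s$n, s$n_miscarriage, s$miscarriage_rate_pct, s$n_karyotyped))
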