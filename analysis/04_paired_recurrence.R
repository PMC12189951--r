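#!/usr/bin/env Rscript
# Intercycle analysis of the paired-biopsy cohort: 4x4 quartile contingency
# table, per-cell Fisher enrichment with Bonferroni correction, B-biopsy
# uniformity per A bin, recurrence rates, and stratification by prior
# pregnancy losses.

suppressPackageStartupMessages(library(endoscore))
paired <- read_cohort_csv("results/cohorts/paired.csv")
model <- read_reference_model("results/model.json")
scores <- score_cohort(paired, model)

for (ratio in c("stromal", "unk")) {
  pairs <- pair_scores(scores, ratio)
  res <- paired_quartile_analysis(pairs$quartA, pairs$quartB)
  message(sprintf("%s ratio, %d pairs:", ratio, res$table$n_pairs))
  print(res$table$counts)
  message(sprintf("  recurrence by quartile: %s",
                  paste(sprintf("%s %.0f%%", names(res$recurrence),
                                100 * res$recurrence), collapse = ", ")))
  sig <- res$enrichment[res$enrichment$significant, ]
  if (nrow(sig) > 0) {
    for (k in seq_len(nrow(sig))) {
      message(sprintf("  cell (%s,%s) %s (adj. p = %.2g)", sig$A[k],
                      sig$B[k], sig$direction[k], sig$adjusted_p[k]))
    }
  } else {
    message("  no Bonferroni-significant cells")
  }
  jsonlite::write_json(
    list(counts = res$table$counts, recurrence = as.list(res$recurrence),
         enrichment = res$enrichment),
    sprintf("results/paired_%s.json", ratio),
    auto_unbox = TRUE, digits = I(17), force = TRUE, pretty = TRUE)
}

pairs <- pair_scores(scores, "stromal")
strata <- ifelse(pairs$prior_losses >= 2, "2+ prior losses",
                 "0-1 prior losses")
strat <- stratified_recurrence(pairs$quartA, pairs$quartB, strata)
for (s in names(strat)) {
  message(sprintf("stratum %s: stalled-state recurrence %.0f%% (%d pairs)",
                  s, 100 * strat[[s]]$recurrence[["Q1"]],
                  strat[[s]]$table$n_pairs))
}
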