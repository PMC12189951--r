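#!/usr/bin/env Rscript
# Scores the calibration cohort against its own reference model: percentile
# ranks, quartile bins and state flags per sample; checks the probability
# integral transform (self-scored percentiles should be uniform) and the
# correlation between the stromal and uNK percentile scores.

suppressPackageStartupMessages(library(endoscore))
cohort <- read_cohort_csv("results/cohorts/reference.csv")
model <- read_reference_model("results/model.json")
scores <- score_cohort(cohort, model)
write_cohort_csv(scores, "results/scores_reference.csv")
message(sprintf("scored %d of %d samples (%d skipped)", nrow(scores),
                nrow(cohort), nrow(attr(scores, "skip_log"))))

for (d in model$day_range[1]:model$day_range[2]) {
  u <- scores$stromal_percentile[scores$lh_day == d] / 100
  ks <- suppressWarnings(ks.test(u, "punif"))
  message(sprintf("  LH+%d PIT: KS distance %.3f (n = %d)", d,
                  unname(ks$statistic), length(u)))
}

cross <- spearman_percentiles(scores$stromal_percentile,
                              scores$unk_percentile)
message(sprintf(
  "cross-score Spearman rho = %.3f (p = %.2g, n = %d): decidual strength and uNK expansion are coregulated but far from interchangeable",
  cross$rho, cross$p, cross$n))

message(sprintf("state flags: %.1f%% stalled, %.1f%% heightened, %.1f%% suboptimal uNK, %.1f%% strong uNK",
                100 * mean(scores$stalled), 100 * mean(scores$heightened),
                100 * mean(scores$suboptimal_unk),
                100 * mean(scores$strong_unk)))
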