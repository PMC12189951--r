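#!/usr/bin/env Rscript
# Association analyses: quartile-bin frequencies by number of prior losses,
# pregnancy-outcome odds ratios per state flag (with and without exclusion
# of karyotyped aneuploid losses), and Kruskal-Wallis/Dunn comparison of
# uNK percentiles across stromal quartile bins.

suppressPackageStartupMessages(library(endoscore))
model <- read_reference_model("results/model.json")

ref_scores <- score_cohort(read_cohort_csv("results/cohorts/reference.csv"),
                           model)
freq <- suppressWarnings(
  frequency_by_losses(ref_scores$stromal_quartile,
                      ref_scores$prior_losses))
for (bin in names(freq)) {
  f <- freq[[bin]]$freq
  message(sprintf("%s frequency by prior losses: %s", bin,
                  paste(sprintf("%s: %.0f%% (%s)", f$group, f$pct,
                                f$letters), collapse = ", ")))
}

kd <- kruskal_dunn(ref_scores$unk_percentile, ref_scores$stromal_quartile)
message(sprintf(
  "uNK percentile by stromal quartile: Kruskal-Wallis H = %.1f (p = %.2g); letters %s",
  kd$H, kd$p, paste(names(kd$letters), kd$letters, sep = "=",
                    collapse = " ")))

outcome <- read_cohort_csv("results/cohorts/outcome.csv")
out_scores <- score_cohort(outcome, model)
s <- outcome_summary(out_scores)
message(sprintf("prospective cohort: %d subjects, miscarriage rate %.0f%%",
                s$n, s$miscarriage_rate_pct))

forest_all <- outcome_forest(out_scores)
forest_excl <- outcome_forest(out_scores, exclude_aneuploid = TRUE)
for (fl in unique(forest_all$flag)) {
  a <- forest_all[forest_all$flag == fl &
                    forest_all$outcome == "live_birth", ]
  e <- forest_excl[forest_excl$flag == fl &
                     forest_excl$outcome == "live_birth", ]
  message(sprintf(
    "%s live-birth OR %.2f (%.2f-%.2f); aneuploid-excluded %.2f (%.2f-%.2f)",
    fl, a$or, a$ci_low, a$ci_high, e$or, e$ci_low, e$ci_high))
}
jsonlite::write_json(
  list(summary = s, forest = forest_all, forest_excluded = forest_excl,
       frequency_by_losses = lapply(freq, `[[`, "freq")),
  "results/outcome_associations.json",
  auto_unbox = TRUE, digits = I(17), force = TRUE, pretty = TRUE)
message("written: results/outcome_associations.json")
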