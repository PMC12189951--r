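#!/usr/bin/env Rscript
# Calibrates the day-indexed reference model on the simulated reference
# cohort: per-LH-day gamma-vs-lognormal fits for the two marker ratios
# (family chosen by the Cramer-von Mises criterion) and log10-normal fits
# for genes and hormones. Writes the model as versioned JSON.

suppressPackageStartupMessages(library(endoscore))
cohort <- read_cohort_csv("results/cohorts/reference.csv")
model <- build_reference_model(cohort, day_range = c(6L, 10L), min_n = 20L)
print(model)
for (ratio in names(model$ratio_fits)) {
  for (fit in model$ratio_fits[[ratio]]) {
    message(sprintf(
      "  %s LH+%d: %s selected (W2 gamma %.4f vs lognormal %.4f, n = %d)",
      ratio, fit$lh_day, fit$family, fit$cvm_gamma, fit$cvm_lognormal,
      fit$n))
  }
}
write_reference_model(model, "results/model.json")
message("model written: results/model.json")
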