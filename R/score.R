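ratio_fit_cdf <- function(fit, x) {
  if (fit$family == "gamma") {
    stats::pgamma(x, shape = fit$params$shape, scale = fit$params$scale)
  } else {
    stats::plnorm(x, meanlog = fit$params$meanlog, sdlog = fit$params$sdlog)
  }
}

get_ratio_fit <- function(model, ratio_name, lh_day) {
  if (lh_day < model$day_range[1] || lh_day > model$day_range[2]) {
    stop_endoscore(sprintf("LH+%d outside calibrated range %d..%d", lh_day,
                           model$day_range[1], model$day_range[2]),
                   "endoscore_day_out_of_range")
  }
  fit <- model$ratio_fits[[ratio_name]][[as.character(lh_day)]]
  if (is.null(fit)) {
    stop_endoscore(sprintf("no %s fit for LH+%d", ratio_name, lh_day),
                   "endoscore_missing_fit")
  }
  fit
}

#' Percentile rank of a marker ratio in its day's reference distribution
#'
#' 100 x F_day(ratio) with F_day the fitted CDF (gamma or log-normal,
#' whichever the Cramer-von Mises criterion selected for that LH day).
#'
#' @param ratio strictly positive marker ratio.
#' @param lh_day day after the LH surge (must be in the calibrated range).
#' @param model a `reference_model`.
#' @param ratio_name "stromal" (PLA2G2A/DIO2) or "unk" (ITGAD/CD160).
#' @return percentile in [0, 100].
#' @export
ratio_percentile <- function(ratio, lh_day, model, ratio_name) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop_endoscore("ratio must be strictly positive", "endoscore_nonpositive")
  }
  fit <- get_ratio_fit(model, ratio_name, lh_day)
  100 * ratio_fit_cdf(fit, ratio)
}

#' Percentile rank of a gene or hormone level
#'
#' 100 x Phi((log10 value - log_mean) / log_sd) against the analyte's
#' per-day normal reference.
#'
#' @param value strictly positive measurement.
#' @param lh_day day after the LH surge.
#' @param model a `reference_model`.
#' @param analyte analyte name present in the model.
#' @return percentile in [0, 100].
#' @export
analyte_percentile <- function(value, lh_day, model, analyte) {
  if (lh_day < model$day_range[1] || lh_day > model$day_range[2]) {
    stop_endoscore(sprintf("LH+%d outside calibrated range", lh_day),
                   "endoscore_day_out_of_range")
  }
  fit <- model$analyte_fits[[analyte]][[as.character(lh_day)]]
  if (is.null(fit)) {
    stop_endoscore(sprintf("no %s fit for LH+%d", analyte, lh_day),
                   "endoscore_missing_fit")
  }
  100 * stats::pnorm((log_transform_copies(value) - fit$log_mean) / fit$log_sd)
}

#' Quartile bin and state flags for a percentile score
#'
#' Bins: [0,25) Q1, [25,50) Q2, [50,75) Q3, [75,100] Q4. The low flag is
#' strict (`percentile < 25`, so 25.0 is not flagged) and the high flag is
#' strict (`percentile > 75`, so 75.0 falls in Q4 but is not flagged),
#' matching the "< 25th percentile" / "> 75th percentile" definitions of a
#' stalled and a heightened decidual reaction.
#'
#' @param percentile score(s) in [0, 100].
#' @return a `data.frame` with `quartile` (factor Q1..Q4), `low` and
#'   `high` logical flags.
#' @export
assign_quartile <- function(percentile) {
  if (any(!is.finite(percentile)) || any(percentile < 0 | percentile > 100)) {
    stop_endoscore("percentile must lie in [0, 100]", "endoscore_out_of_range")
  }
  q <- cut(percentile, breaks = c(0, 25, 50, 75, 100), right = FALSE,
           labels = quartile_levels())
  q[percentile == 100] <- "Q4"
  data.frame(quartile = factor(q, levels = quartile_levels()),
             low = percentile < 25, high = percentile > 75)
}

#' Score a cohort against a reference model
#'
#' Computes both marker-ratio percentiles, quartile bins and the binary
#' state flags for every usable sample; optionally also hormone
#' percentiles for analytes present in both cohort and model. Samples with
#' zero or missing copy numbers, or an LH day outside the calibrated
#' range, are skipped and listed (with reasons) in the `skip_log`
#' attribute rather than extrapolated.
#'
#' @param cohort a cohort `data.frame`.
#' @param model a `reference_model`.
#' @return a `data.frame` of class `score_result` with columns
#'   `stromal_percentile`, `unk_percentile`, `stromal_quartile`,
#'   `unk_quartile` and flags `stalled`, `heightened`, `suboptimal_unk`,
#'   `strong_unk`.
#' @export
score_cohort <- function(cohort, model) {
  if (anyDuplicated(cohort$sample_id)) {
    stop_endoscore("duplicate sample_id in cohort", "endoscore_duplicate_id")
  }
  genes <- ratio_genes()
  needed <- unname(unlist(genes))
  ok_copies <- rowSums(!is.finite(as.matrix(cohort[, needed])) |
                         as.matrix(cohort[, needed]) <= 0) == 0
  ok_day <- cohort$lh_day >= model$day_range[1] &
    cohort$lh_day <= model$day_range[2] & !is.na(cohort$lh_day)
  usable <- ok_copies & ok_day
  skip_log <- data.frame(
    sample_id = cohort$sample_id[!usable],
    reason = ifelse(!ok_copies[!usable], "zero or missing copy numbers",
                    "LH day outside calibrated range"),
    stringsAsFactors = FALSE)
  sub <- cohort[usable, , drop = FALSE]
  n <- nrow(sub)
  out <- data.frame(sample_id = sub$sample_id, subject_id = sub$subject_id,
                    cycle_index = sub$cycle_index, lh_day = sub$lh_day,
                    stringsAsFactors = FALSE)
  percentiles <- list()
  for (ratio in names(genes)) {
    r <- sub[[genes[[ratio]]["num"]]] / sub[[genes[[ratio]]["den"]]]
    p <- numeric(n)
    for (d in unique(sub$lh_day)) {
      idx <- sub$lh_day == d
      p[idx] <- ratio_percentile(r[idx], d, model, ratio)
    }
    percentiles[[ratio]] <- p
  }
  qs <- assign_quartile(percentiles$stromal)
  qu <- assign_quartile(percentiles$unk)
  out$stromal_percentile <- percentiles$stromal
  out$unk_percentile <- percentiles$unk
  out$stromal_quartile <- qs$quartile
  out$unk_quartile <- qu$quartile
  out$stalled <- qs$low
  out$heightened <- qs$high
  out$suboptimal_unk <- qu$low
  out$strong_unk <- qu$high
  for (analyte in intersect(names(model$analyte_fits),
                            c("progesterone", "estradiol", "tsh"))) {
    if (!analyte %in% names(sub)) next
    v <- sub[[analyte]]
    p <- rep(NA_real_, n)
    good <- is.finite(v) & v > 0
    for (d in unique(sub$lh_day[good])) {
      idx <- good & sub$lh_day == d
      p[idx] <- analyte_percentile(v[idx], d, model, analyte)
    }
    out[[paste0(analyte, "_percentile")]] <- p
  }
  for (col in intersect(c("prior_losses", "outcome", "karyotype"),
                        names(sub))) {
    out[[col]] <- sub[[col]]
  }
  rownames(out) <- NULL
  attr(out, "skip_log") <- skip_log
  class(out) <- c("score_result", class(out))
  out
}
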