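cohort_mandatory_cols <- function() {
  c("sample_id", "subject_id", "cycle_index", "lh_day",
    "copies_pla2g2a", "copies_dio2", "copies_itgad", "copies_cd160")
}

cohort_optional_cols <- function() {
  c("prior_losses", "outcome", "karyotype",
    "progesterone", "estradiol", "tsh")
}

#' Read a cohort CSV
#'
#' Validates the sample schema (mandatory identifier, timing and ddPCR
#' copy columns; optional clinical covariates), coerces types, turns empty
#' strings into missing values, preserves unknown extra columns, and
#' collects malformed rows (negative copy numbers, karyotype without a
#' miscarriage) into a `rejected` attribute instead of failing.
#'
#' @param path CSV file path.
#' @return cohort `data.frame`; attribute `rejected` holds dropped rows
#'   with reasons.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    stop_endoscore(sprintf("file not found: %s", path), "endoscore_io")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(cohort_mandatory_cols(), names(raw))
  if (length(missing_cols) > 0) {
    stop_endoscore(sprintf("missing mandatory column(s): %s",
                           paste(missing_cols, collapse = ", ")),
                   "endoscore_schema")
  }
  raw[raw == ""] <- NA
  num_cols <- c("lh_day", "cycle_index", "copies_pla2g2a", "copies_dio2",
                "copies_itgad", "copies_cd160", "prior_losses",
                "progesterone", "estradiol", "tsh")
  for (col in intersect(num_cols, names(raw))) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  for (col in intersect(c("lh_day", "cycle_index", "prior_losses"),
                        names(raw))) {
    raw[[col]] <- as.integer(raw[[col]])
  }
  copy_cols <- grep("^copies_", cohort_mandatory_cols(), value = TRUE)
  neg <- rowSums(!is.na(raw[, copy_cols]) & raw[, copy_cols] < 0) > 0
  bad_karyo <- if (all(c("karyotype", "outcome") %in% names(raw))) {
    !is.na(raw$karyotype) & raw$karyotype != "unknown" &
      (is.na(raw$outcome) | raw$outcome != "miscarriage")
  } else rep(FALSE, nrow(raw))
  bad <- neg | bad_karyo
  rejected <- raw[bad, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reject_reason <- ifelse(neg[bad], "negative copy number",
                                     "karyotype without miscarriage outcome")
    warning(sprintf("%d malformed row(s) rejected", nrow(rejected)),
            call. = FALSE)
  }
  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a cohort CSV
#'
#' Missing values are written as empty strings, per the cohort schema.
#'
#' @param cohort a cohort `data.frame`.
#' @param path output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' @param params a [simulation_params()] object (used when cohorts are
#'   simulated rather than read from disk).
#' @param day_range calibrated LH-day range.
#' @param min_n minimum per-day calibration sample size.
#' @param pool_adjacent pool sparse days with their nearest neighbour.
#' @param alpha significance level.
#' @param bonferroni_m Fisher-enrichment family size (16 cells).
#' @param exclude_aneuploid drop aneuploid losses in outcome analyses.
#' @param n_reference,n_pairs,n_outcome stage cohort sizes.
#' @param seed master seed; every stage derives from it.
#' @param out_dir output directory for the report bundle.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(params = simulation_params(),
                            day_range = c(6L, 10L), min_n = 20L,
                            pool_adjacent = FALSE, alpha = 0.05,
                            bonferroni_m = 16L, exclude_aneuploid = FALSE,
                            n_reference = 2000L, n_pairs = 316L,
                            n_outcome = 2000L, seed = 1L,
                            out_dir = tempfile("endoscore_run_")) {
  structure(list(params = params, day_range = day_range, min_n = min_n,
                 pool_adjacent = pool_adjacent, alpha = alpha,
                 bonferroni_m = bonferroni_m,
                 exclude_aneuploid = exclude_aneuploid,
                 n_reference = n_reference, n_pairs = n_pairs,
                 n_outcome = n_outcome, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# Hash of everything that determines the numbers (out_dir excluded, so the
# same analysis written elsewhere hashes identically).
config_hash <- function(config) {
  payload <- unclass(config)
  payload$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(rapply(payload, unclass, how = "replace"),
                       tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on simulated cohorts
#'
#' simulate -> calibrate -> score -> paired recurrence -> outcome
#' association. Writes `model.json`, `scores.csv`, `report.json` and a
#' human-readable `summary.txt` under `config$out_dir`; all outputs embed
#' the package version and a configuration hash, and all randomness
#' derives from `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the model, scored cohorts, paired
#'   analysis, outcome forest and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config$params
  seed <- config$seed

  reference <- simulate_reference_cohort(params, n = config$n_reference,
                                         seed = seed)
  model <- build_reference_model(reference, day_range = config$day_range,
                                 min_n = config$min_n,
                                 pool_adjacent = config$pool_adjacent)
  model_path <- file.path(config$out_dir, "model.json")
  write_reference_model(model, model_path)

  ref_scores <- score_cohort(reference, model)
  cross <- spearman_percentiles(ref_scores$stromal_percentile,
                                ref_scores$unk_percentile)

  paired <- simulate_paired_cohort(params, n_pairs = config$n_pairs,
                                   seed = seed + 1L)
  paired_scores <- score_cohort(paired, model)
  pairs <- pair_scores(paired_scores, "stromal")
  paired_analysis <- paired_quartile_analysis(pairs$quartA, pairs$quartB,
                                              alpha = config$alpha,
                                              m = config$bonferroni_m)

  outcome <- simulate_outcome_cohort(params, n = config$n_outcome,
                                     seed = seed + 2L)
  outcome_scores <- score_cohort(outcome, model)
  forest <- outcome_forest(outcome_scores,
                           exclude_aneuploid = config$exclude_aneuploid)
  freq <- frequency_by_losses(ref_scores$stromal_quartile,
                              ref_scores$prior_losses,
                              alpha = config$alpha)

  scores_path <- file.path(config$out_dir, "scores.csv")
  write_cohort_csv(ref_scores, scores_path)

  meta <- list(package_version = as.character(utils::packageVersion("endoscore")),
               config_hash = config_hash(config), seed = seed)
  report <- list(
    meta = meta,
    cross_score_spearman = cross,
    paired = list(
      counts = paired_analysis$table$counts,
      recurrence = as.list(paired_analysis$recurrence),
      enrichment = paired_analysis$enrichment),
    outcome_forest = forest,
    frequency_by_losses = lapply(freq, `[[`, "freq"))
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                       digits = I(17), force = TRUE, pretty = TRUE)

  summary_path <- file.path(config$out_dir, "summary.txt")
  q1_rec <- paired_analysis$recurrence["Q1"]
  writeLines(c(
    sprintf("endoscore %s run (seed %d, config %s)", meta$package_version,
            seed, meta$config_hash),
    sprintf("reference cohort: n = %d over LH+%d..LH+%d", config$n_reference,
            config$day_range[1], config$day_range[2]),
    sprintf("cross-score Spearman rho = %.3f (p = %.3g)", cross$rho, cross$p),
    sprintf("paired cohort: %d pairs; stalled-state recurrence = %.1f%%",
            config$n_pairs, 100 * q1_rec),
    sprintf("outcome cohort: n = %d; stalled live-birth OR = %.3f",
            config$n_outcome,
            forest$or[forest$flag == "stalled" &
                        forest$outcome == "live_birth"])),
    summary_path)

  invisible(list(model = model, reference_scores = ref_scores,
                 cross_score = cross, paired_analysis = paired_analysis,
                 outcome_forest = forest, frequency_by_losses = freq,
                 paths = list(model = model_path, scores = scores_path,
                              report = report_path, summary = summary_path)))
}
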