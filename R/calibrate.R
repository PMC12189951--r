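#' Log-transform ddPCR copy numbers
#'
#' @param copies positive copy numbers.
#' @return log10 of `copies`.
#' @export
log_transform_copies <- function(copies) {
  if (any(!is.finite(copies)) || any(copies <= 0)) {
    stop_endoscore("copy numbers must be strictly positive",
                   "endoscore_nonpositive")
  }
  log10(copies)
}

#' Cramer-von Mises goodness-of-fit statistic
#'
#' W^2 = 1/(12n) + sum_i (F(x_(i)) - (2i-1)/(2n))^2, the squared distance
#' between the candidate CDF evaluated at the order statistics and the
#' plotting positions. Lower bound 1/(12n), attained exactly when
#' F(x_(i)) = (2i-1)/(2n) for every i.
#'
#' @param values numeric sample (sorted internally).
#' @param cdf vectorized cumulative distribution function.
#' @return the W^2 statistic.
#' @export
cvm_statistic <- function(values, cdf) {
  n <- length(values)
  if (n < 1L) stop_endoscore("empty sample", "endoscore_empty")
  x <- sort(values)
  u <- cdf(x)
  pp <- (2 * seq_len(n) - 1) / (2 * n)
  1 / (12 * n) + sum((u - pp)^2)
}

# Gamma maximum likelihood: Newton iteration on the profile shape equation
# log(a) - digamma(a) = log(mean x) - mean(log x), method-of-moments start,
# tolerance 1e-10, max 200 iterations; scale = mean(x) / shape.
fit_gamma_mle <- function(x, tol = 1e-10, max_iter = 200L) {
  s <- log(mean(x)) - mean(log(x))
  if (s <= 0) {          # numerically degenerate (near-constant data)
    stop_endoscore("degenerate data for gamma fit", "endoscore_degenerate")
  }
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  if (!is.finite(a) || a <= 0) a <- mean(x)^2 / stats::var(x)
  for (i in seq_len(max_iter)) {
    f <- log(a) - digamma(a) - s
    step <- f / (1 / a - trigamma(a))
    a_new <- a - step
    if (a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < tol * (1 + a)) {
      a <- a_new
      break
    }
    a <- a_new
  }
  list(shape = a, scale = mean(x) / a)
}

#' Fit the per-day reference distribution for a marker ratio
#'
#' Fits both a gamma and a log-normal distribution to the raw ratios by
#' maximum likelihood, computes the Cramer-von Mises W^2 for each fitted
#' CDF on the raw ratio scale, and selects the family with the smaller W^2
#' (ties broken toward log-normal, the natural family for a ratio of
#' log-scaled quantities). Both statistics are retained.
#'
#' @param ratios strictly positive marker ratios for one LH day.
#' @param lh_day the day after the LH surge these ratios belong to.
#' @param min_n minimum sample size (default 20).
#' @return an object of class `ratio_fit` with the selected `family`, its
#'   parameters, both W^2 statistics and `n`.
#' @export
fit_ratio_reference <- function(ratios, lh_day = NA_integer_, min_n = 20L) {
  n <- length(ratios)
  if (n < min_n) {
    stop_endoscore(sprintf(
      "calibration for LH+%s needs at least %d samples, got %d",
      lh_day, min_n, n), "endoscore_undersized")
  }
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop_endoscore("ratios must be strictly positive", "endoscore_nonpositive")
  }
  lx <- log(ratios)
  meanlog <- mean(lx)
  sdlog <- sqrt(mean((lx - meanlog)^2))
  if (sdlog < 1e-6) {
    stop_endoscore("degenerate ratio data (zero spread)",
                   "endoscore_degenerate")
  }
  g <- fit_gamma_mle(ratios)
  cvm_g <- cvm_statistic(ratios, function(x) {
    stats::pgamma(x, shape = g$shape, scale = g$scale)
  })
  cvm_l <- cvm_statistic(ratios, function(x) {
    stats::plnorm(x, meanlog = meanlog, sdlog = sdlog)
  })
  family <- if (cvm_g < cvm_l) "gamma" else "lognormal"
  params <- if (family == "gamma") {
    list(shape = g$shape, scale = g$scale)
  } else {
    list(meanlog = meanlog, sdlog = sdlog)
  }
  structure(list(lh_day = as.integer(lh_day), family = family,
                 params = params, cvm_gamma = cvm_g, cvm_lognormal = cvm_l,
                 n = n),
            class = "ratio_fit")
}

#' Fit the per-day reference distribution for a gene or hormone
#'
#' Maximum-likelihood normal fit of log10 values (mean, and sd with the
#' 1/n variance convention).
#'
#' @param values strictly positive measurements for one LH day.
#' @param analyte analyte name.
#' @param lh_day day after the LH surge.
#' @param min_n minimum sample size (default 20).
#' @return an object of class `analyte_fit`.
#' @export
fit_analyte_reference <- function(values, analyte, lh_day = NA_integer_,
                                  min_n = 20L) {
  n <- length(values)
  if (n < min_n) {
    stop_endoscore(sprintf(
      "calibration of %s for LH+%s needs at least %d samples, got %d",
      analyte, lh_day, min_n, n), "endoscore_undersized")
  }
  lx <- log_transform_copies(values)
  m <- mean(lx)
  s <- sqrt(mean((lx - m)^2))
  if (s < 1e-6) {
    stop_endoscore(sprintf("degenerate data for %s (zero spread)", analyte),
                   "endoscore_degenerate")
  }
  structure(list(lh_day = as.integer(lh_day), analyte = analyte,
                 log_mean = m, log_sd = s, n = n),
            class = "analyte_fit")
}

#' Build the day-indexed reference model from a calibration cohort
#'
#' For every day in `day_range` fits each marker ratio (gamma vs log-normal
#' selected by the Cramer-von Mises criterion) and a log10-normal reference
#' for each gene and any hormone columns present. Samples with zero or
#' missing copy numbers are excluded from the affected fit and recorded in
#' the model's skip log.
#'
#' @param cohort a cohort `data.frame` (see [read_cohort_csv()] schema).
#' @param day_range integer `c(min, max)` of LH days to calibrate.
#' @param min_n minimum usable samples per (ratio, day); days below it
#'   raise an error unless `pool_adjacent` is set.
#' @param pool_adjacent if `TRUE`, a sparse day borrows the samples of its
#'   nearest available neighbouring day instead of failing.
#' @param analytes analyte columns to fit normal references for; defaults
#'   to the four marker genes plus any hormone columns present.
#' @return an object of class `reference_model`.
#' @export
build_reference_model <- function(cohort, day_range = c(6L, 10L),
                                  min_n = 20L, pool_adjacent = FALSE,
                                  analytes = NULL) {
  days <- seq.int(day_range[1], day_range[2])
  missing_days <- setdiff(days, unique(cohort$lh_day))
  if (length(missing_days) > 0 && !pool_adjacent) {
    stop_endoscore(sprintf("no samples for LH day(s) %s",
                           paste(missing_days, collapse = ", ")),
                   "endoscore_missing_days")
  }
  genes <- ratio_genes()
  if (is.null(analytes)) {
    hormone_cols <- intersect(c("progesterone", "estradiol", "tsh"),
                              names(cohort))
    hormone_cols <- hormone_cols[vapply(hormone_cols, function(col) {
      any(is.finite(cohort[[col]]) & cohort[[col]] > 0)
    }, logical(1))]
    analytes <- c(unname(unlist(lapply(genes, `[`, "num"))),
                  unname(unlist(lapply(genes, `[`, "den"))),
                  hormone_cols)
  }
  skip_log <- list()
  ratio_fits <- list()
  for (ratio in names(genes)) {
    num <- cohort[[genes[[ratio]]["num"]]]
    den <- cohort[[genes[[ratio]]["den"]]]
    usable <- is.finite(num) & is.finite(den) & num > 0 & den > 0
    if (any(!usable)) {
      skip_log[[ratio]] <- cohort$sample_id[!usable]
      warning(sprintf(
        "%d sample(s) excluded from %s ratio calibration (zero or missing copies)",
        sum(!usable), ratio), call. = FALSE)
    }
    r <- (num / den)[usable]
    d_all <- cohort$lh_day[usable]
    fits <- list()
    for (d in days) {
      vals <- r[d_all == d]
      if (length(vals) < min_n) {
        if (!pool_adjacent) {
          stop_endoscore(sprintf(
            "LH+%d has %d usable samples for the %s ratio (minimum %d)",
            d, length(vals), ratio, min_n), "endoscore_undersized")
        }
        counts <- table(factor(d_all, levels = days))
        candidates <- days[counts >= min_n]
        if (length(candidates) == 0) {
          stop_endoscore("no day has enough samples to pool from",
                         "endoscore_undersized")
        }
        neighbour <- candidates[which.min(abs(candidates - d))]
        vals <- c(vals, r[d_all == neighbour])
      }
      fits[[as.character(d)]] <- fit_ratio_reference(vals, lh_day = d,
                                                     min_n = min_n)
    }
    ratio_fits[[ratio]] <- fits
  }
  analyte_fits <- list()
  for (analyte in analytes) {
    v_all <- cohort[[analyte]]
    usable <- is.finite(v_all) & v_all > 0
    fits <- list()
    ok <- TRUE
    for (d in days) {
      vals <- v_all[usable & cohort$lh_day == d]
      if (length(vals) < min_n) {
        ok <- FALSE
        break
      }
      fits[[as.character(d)]] <- fit_analyte_reference(vals, analyte,
                                                       lh_day = d,
                                                       min_n = min_n)
    }
    if (ok) analyte_fits[[analyte]] <- fits
  }
  structure(list(version = as.character(utils::packageVersion("endoscore")),
                 day_range = as.integer(day_range),
                 ratio_fits = ratio_fits, analyte_fits = analyte_fits,
                 quartile_edges = c(25, 50, 75), skip_log = skip_log),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("Day-indexed reference model (v%s), LH+%d..LH+%d\n",
              x$version, x$day_range[1], x$day_range[2]))
  for (ratio in names(x$ratio_fits)) {
    fams <- vapply(x$ratio_fits[[ratio]], `[[`, character(1), "family")
    ns <- vapply(x$ratio_fits[[ratio]], `[[`, numeric(1), "n")
    cat(sprintf("  %s ratio: %s (n = %s)\n", ratio,
                paste(fams, collapse = "/"),
                paste(ns, collapse = "/")))
  }
  if (length(x$analyte_fits) > 0) {
    cat("  analytes:", paste(names(x$analyte_fits), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a reference model to JSON
#'
#' Full-precision JSON; a load round-trip reproduces identical percentile
#' scores.
#'
#' @param model a `reference_model`.
#' @param path output file path.
#' @export
write_reference_model <- function(model, path) {
  payload <- unclass(model)
  payload$ratio_fits <- lapply(payload$ratio_fits,
                               function(fits) lapply(fits, unclass))
  payload$analyte_fits <- lapply(payload$analyte_fits,
                                 function(fits) lapply(fits, unclass))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_reference_model
#' @return `read_reference_model` returns the `reference_model`.
#' @export
read_reference_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  payload$day_range <- as.integer(unlist(payload$day_range))
  payload$quartile_edges <- as.numeric(unlist(payload$quartile_edges))
  payload$ratio_fits <- lapply(payload$ratio_fits, function(fits) {
    lapply(fits, function(f) {
      f$lh_day <- as.integer(f$lh_day)
      f$params <- lapply(f$params, as.numeric)
      structure(f, class = "ratio_fit")
    })
  })
  payload$analyte_fits <- lapply(payload$analyte_fits, function(fits) {
    lapply(fits, function(f) {
      f$lh_day <- as.integer(f$lh_day)
      structure(f, class = "analyte_fit")
    })
  })
  structure(payload, class = "reference_model")
}
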