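#' 4x4 quartile contingency table for paired biopsies
#'
#' Rows index the first (A) biopsy's quartile, columns the second (B)
#' biopsy's; row-conditional percentages give, for each A-quartile, the
#' distribution of the B biopsy.
#'
#' @param quartA,quartB aligned quartile vectors (factor or character
#'   Q1..Q4), one entry per subject.
#' @return an object of class `quartile_table` with `counts`,
#'   `row_conditional_pct` and `n_pairs`.
#' @export
build_quartile_table <- function(quartA, quartB) {
  if (length(quartA) != length(quartB)) {
    stop_endoscore("paired quartile vectors must have equal length",
                   "endoscore_unpaired")
  }
  qa <- factor(as.character(quartA), levels = quartile_levels())
  qb <- factor(as.character(quartB), levels = quartile_levels())
  if (anyNA(qa) || anyNA(qb)) {
    stop_endoscore("invalid quartile labels", "endoscore_invalid_quartile")
  }
  counts <- table(A = qa, B = qb)
  counts <- matrix(as.integer(counts), 4, 4,
                   dimnames = list(A = quartile_levels(),
                                   B = quartile_levels()))
  rt <- rowSums(counts)
  pct <- counts / ifelse(rt > 0, rt, NA_real_) * 100
  structure(list(counts = counts, row_conditional_pct = pct,
                 n_pairs = sum(counts)),
            class = "quartile_table")
}

#' @export
print.quartile_table <- function(x, ...) {
  cat(sprintf("Paired quartile table (%d pairs)\n", x$n_pairs))
  print(x$counts)
  invisible(x)
}

# Two-sided Fisher exact p for a 2x2 table: the sum of all hypergeometric
# outcomes with probability no larger than the observed one (the convention
# of standard statistical environments).
fisher_p_2x2 <- function(m) {
  stats::fisher.test(m)$p.value
}

# Collapse the 4x4 table to the 2x2 one-vs-all grid for cell (i, j):
# membership of the A biopsy in row-bin i crossed with membership of the B
# biopsy in column-bin j.
collapse_cell <- function(tab, i, j) {
  cnt <- tab$counts
  a <- cnt[i, j]
  b <- sum(cnt[i, ]) - a
  c_ <- sum(cnt[, j]) - a
  d <- tab$n_pairs - a - b - c_
  matrix(c(a, b, c_, d), 2, 2, byrow = TRUE)
}

#' One-versus-all chi-square test for a quartile bin
#'
#' Collapses the 4x4 table to a 2x2 grid (in-bin vs not, for each biopsy)
#' and tests independence with Yates' continuity correction; when any
#' expected count falls below 5 the p-value comes from Fisher's exact test
#' instead.
#'
#' @param tab a `quartile_table`.
#' @param bin the bin to test: a single quartile index/label (tests the
#'   diagonal cell) or a length-2 vector `(row, column)`.
#' @return list with `statistic` (NA on the exact path), `p`, `method`
#'   and the collapsed `table`.
#' @export
one_vs_all_chi2 <- function(tab, bin) {
  ij <- resolve_bin(bin)
  m <- collapse_cell(tab, ij[1], ij[2])
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_endoscore("degenerate 2x2 grid: zero margin", "endoscore_zero_margin")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    return(list(statistic = NA_real_, p = fisher_p_2x2(m),
                method = "fisher_exact", table = m))
  }
  ct <- stats::chisq.test(m, correct = TRUE)
  list(statistic = unname(ct$statistic), p = ct$p.value,
       method = "chisq_yates", table = m)
}

resolve_bin <- function(bin) {
  to_idx <- function(b) {
    if (is.character(b) || is.factor(b)) {
      match(as.character(b), quartile_levels())
    } else as.integer(b)
  }
  ij <- to_idx(bin)
  if (length(ij) == 1L) ij <- c(ij, ij)
  if (length(ij) != 2L || anyNA(ij) || any(ij < 1 | ij > 4)) {
    stop_endoscore("bin must identify a quartile cell", "endoscore_invalid_bin")
  }
  ij
}

#' Per-cell Fisher enrichment/depletion over a paired quartile table
#'
#' For each of the 16 cells, a two-sided Fisher exact test on the
#' one-vs-all 2x2 collapse; direction is enriched or depleted according to
#' the observed count versus the independence expectation (ties:
#' direction none, never significant); Bonferroni correction over the
#' `m` cells of the family.
#'
#' @param tab a `quartile_table`.
#' @param alpha significance level after correction (default 0.05).
#' @param m Bonferroni family size (default 16, all cells of the table;
#'   4 tests one column at a time).
#' @return a `data.frame` of class `enrichment_result` with one row per
#'   cell: observed, expected, direction, raw_p, adjusted_p, significant.
#' @export
fisher_cell_enrichment <- function(tab, alpha = 0.05, m = 16L) {
  if (tab$n_pairs <= 0) {
    stop_endoscore("empty table", "endoscore_empty")
  }
  rows <- expand.grid(A = quartile_levels(), B = quartile_levels(),
                      stringsAsFactors = FALSE)[, 2:1]
  rows <- rows[order(match(rows$A, quartile_levels()),
                     match(rows$B, quartile_levels())), , drop = FALSE]
  res <- lapply(seq_len(nrow(rows)), function(k) {
    i <- match(rows$A[k], quartile_levels())
    j <- match(rows$B[k], quartile_levels())
    obs <- tab$counts[i, j]
    expd <- sum(tab$counts[i, ]) * sum(tab$counts[, j]) / tab$n_pairs
    p <- fisher_p_2x2(collapse_cell(tab, i, j))
    direction <- if (obs > expd) "enriched" else if (obs < expd) "depleted" else "none"
    data.frame(A = rows$A[k], B = rows$B[k], observed = obs,
               expected = expd, direction = direction, raw_p = p,
               adjusted_p = min(1, m * p), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$significant <- res$adjusted_p < alpha & res$direction != "none"
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "family_size") <- m
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Chi-square goodness-of-fit test of B-biopsy uniformity within one A bin
#'
#' Tests the four B-quartile counts of one A-quartile row against a
#' uniform expectation (df = 3).
#'
#' @param tab a `quartile_table`.
#' @param a_bin the A-biopsy quartile (index or label).
#' @return list with `statistic`, `df` and `p`.
#' @export
column_uniformity <- function(tab, a_bin) {
  i <- resolve_bin(a_bin)[1]
  row <- tab$counts[i, ]
  if (sum(row) == 0) {
    stop_endoscore("empty A-quartile row", "endoscore_empty")
  }
  ct <- stats::chisq.test(row, p = rep(0.25, 4))
  list(statistic = unname(ct$statistic), df = 3, p = ct$p.value)
}

#' Recurrence rate of a quartile state across paired biopsies
#'
#' The conditional probability that the second biopsy falls in `bin` given
#' that the first did: `counts[bin, bin] / row_total[bin]`.
#'
#' @param tab a `quartile_table`.
#' @param bin quartile index or label (default Q1, the stalled state).
#' @return a proportion in [0, 1], or `NA` (with a warning) for an empty
#'   row.
#' @export
recurrence_rate <- function(tab, bin = "Q1") {
  i <- resolve_bin(bin)[1]
  rt <- sum(tab$counts[i, ])
  if (rt == 0) {
    warning(sprintf("no pairs with first biopsy in %s; recurrence undefined",
                    quartile_levels()[i]), call. = FALSE)
    return(NA_real_)
  }
  tab$counts[i, i] / rt
}

#' Full paired-biopsy quartile analysis
#'
#' Builds the 4x4 table and computes per-cell Fisher enrichment,
#' one-vs-all chi-square for the diagonal bins, B-biopsy uniformity per A
#' bin and recurrence rates of every quartile state.
#'
#' @param quartA,quartB aligned quartile vectors.
#' @inheritParams fisher_cell_enrichment
#' @return list with `table`, `enrichment`, `diagonal_tests`,
#'   `uniformity` and `recurrence`.
#' @export
paired_quartile_analysis <- function(quartA, quartB, alpha = 0.05, m = 16L) {
  tab <- build_quartile_table(quartA, quartB)
  diag_tests <- lapply(quartile_levels(), function(b) {
    tryCatch(one_vs_all_chi2(tab, b), endoscore_error = function(e) NULL)
  })
  names(diag_tests) <- quartile_levels()
  unif <- lapply(quartile_levels(), function(b) {
    if (sum(tab$counts[resolve_bin(b)[1], ]) == 0) return(NULL)
    column_uniformity(tab, b)
  })
  names(unif) <- quartile_levels()
  rec <- vapply(quartile_levels(), function(b) {
    suppressWarnings(recurrence_rate(tab, b))
  }, numeric(1))
  list(table = tab,
       enrichment = fisher_cell_enrichment(tab, alpha = alpha, m = m),
       diagonal_tests = diag_tests, uniformity = unif, recurrence = rec)
}

#' Paired analysis stratified by number of prior pregnancy losses
#'
#' Runs the full paired quartile analysis separately within each
#' prior-loss stratum; the Bonferroni family is the 16 cells within each
#' stratum. Empty strata are skipped with a warning.
#'
#' @param quartA,quartB aligned quartile vectors.
#' @param strata stratum label per pair (e.g. number of prior losses).
#' @inheritParams fisher_cell_enrichment
#' @return named list of per-stratum analyses (see
#'   [paired_quartile_analysis()]).
#' @export
stratified_recurrence <- function(quartA, quartB, strata, alpha = 0.05,
                                  m = 16L) {
  if (length(strata) != length(quartA)) {
    stop_endoscore("strata must align with pairs", "endoscore_unpaired")
  }
  out <- list()
  for (s in sort(unique(strata))) {
    idx <- strata == s
    if (!any(idx)) {
      warning(sprintf("stratum '%s' is empty; skipped", s), call. = FALSE)
      next
    }
    out[[as.character(s)]] <-
      paired_quartile_analysis(quartA[idx], quartB[idx], alpha = alpha, m = m)
  }
  out
}

#' Align a scored paired cohort into first/second-biopsy quartiles
#'
#' @param scores a `score_result` containing `cycle_index` 1 and 2 rows.
#' @param ratio "stromal" or "unk": which quartile column to pair.
#' @return a `data.frame` with one row per subject: `subject_id`,
#'   `quartA`, `quartB` and (if present) `prior_losses`.
#' @export
pair_scores <- function(scores, ratio = c("stromal", "unk")) {
  ratio <- match.arg(ratio)
  col <- paste0(ratio, "_quartile")
  a <- scores[scores$cycle_index == 1L, ]
  b <- scores[scores$cycle_index == 2L, ]
  common <- intersect(a$subject_id, b$subject_id)
  if (length(common) == 0) {
    stop_endoscore("no subjects with both biopsies scored",
                   "endoscore_unpaired")
  }
  a <- a[match(common, a$subject_id), ]
  b <- b[match(common, b$subject_id), ]
  out <- data.frame(subject_id = common,
                    quartA = a[[col]], quartB = b[[col]],
                    stringsAsFactors = FALSE)
  if ("prior_losses" %in% names(a)) out$prior_losses <- a$prior_losses
  out
}
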