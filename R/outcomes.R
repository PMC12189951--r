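# Compact letter display: groups share a letter iff they are not
# significantly different (insert-and-absorb construction).
compact_letters <- function(group_names, sig_pairs) {
  sets <- list(group_names)
  if (nrow(sig_pairs) > 0) {
    for (k in seq_len(nrow(sig_pairs))) {
      gi <- sig_pairs$g1[k]
      gj <- sig_pairs$g2[k]
      new_sets <- list()
      for (s in sets) {
        if (gi %in% s && gj %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, gi)), list(setdiff(s, gj)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a != b && keep[a] && all(new_sets[[a]] %in% new_sets[[b]]) &&
              !(all(new_sets[[b]] %in% new_sets[[a]]) && a < b)) {
            keep[a] <- FALSE
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  lab <- letters[seq_along(sets)]
  vapply(group_names, function(g) {
    paste0(lab[vapply(sets, function(s) g %in% s, logical(1))], collapse = "")
  }, character(1))
}

#' Quartile-bin frequencies by number of prior pregnancy losses
#'
#' For each prior-loss group (0, 1, 2, 3, 4 or more), the percentage of
#' samples in the requested quartile bin(s), with pairwise 2x2 chi-square
#' tests (in-bin vs not, group vs group), Bonferroni correction over the
#' number of pairwise comparisons, and a compact-letter grouping in which
#' groups sharing a letter are not significantly different.
#'
#' @param quartiles quartile labels per sample (e.g. `stromal_quartile`).
#' @param prior_losses number of prior losses per sample (capped at 4).
#' @param bins quartile bins to analyse (default lowest and highest).
#' @param alpha significance level (default 0.05).
#' @return named list per bin: `freq` data.frame (group, n, in_bin, pct,
#'   letters) and `pairwise` data.frame of tests.
#' @export
frequency_by_losses <- function(quartiles, prior_losses,
                                bins = c("Q1", "Q4"), alpha = 0.05) {
  keep <- !is.na(prior_losses) & !is.na(quartiles)
  quartiles <- as.character(quartiles)[keep]
  losses <- pmin(as.integer(prior_losses[keep]), 4L)
  grp <- factor(ifelse(losses >= 4, "4+", as.character(losses)),
                levels = c("0", "1", "2", "3", "4+"))
  present <- levels(grp)[table(grp) > 0]
  if (length(present) < length(levels(grp))) {
    warning(sprintf("empty prior-loss group(s) excluded: %s",
                    paste(setdiff(levels(grp), present), collapse = ", ")),
            call. = FALSE)
  }
  grp <- factor(as.character(grp), levels = present)
  out <- list()
  for (bin in bins) {
    in_bin <- quartiles == bin
    n_g <- as.integer(table(grp))
    k_g <- as.integer(table(grp[in_bin]))
    freq <- data.frame(group = present, n = n_g, in_bin = k_g,
                       pct = 100 * k_g / n_g, stringsAsFactors = FALSE)
    pairs <- if (length(present) >= 2) t(utils::combn(present, 2)) else
      matrix(character(0), 0, 2)
    m <- nrow(pairs)
    pw <- NULL
    if (m > 0) {
      pw <- do.call(rbind, lapply(seq_len(m), function(i) {
        g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
        tab <- rbind(c(k_g[present == g1], n_g[present == g1] - k_g[present == g1]),
                     c(k_g[present == g2], n_g[present == g2] - k_g[present == g2]))
        p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
          suppressWarnings(stats::chisq.test(tab)$p.value)
        } else if (identical(tab[1, ] / sum(tab[1, ]), tab[2, ] / sum(tab[2, ]))) {
          1
        } else {
          stats::fisher.test(tab)$p.value
        }
        data.frame(g1 = g1, g2 = g2, raw_p = p,
                   adjusted_p = min(1, m * p), stringsAsFactors = FALSE)
      }))
      pw$significant <- pw$adjusted_p < alpha
    }
    sig <- if (is.null(pw)) data.frame(g1 = character(0), g2 = character(0)) else
      pw[pw$significant, c("g1", "g2"), drop = FALSE]
    freq$letters <- compact_letters(present, sig)
    out[[bin]] <- list(freq = freq, pairwise = pw)
  }
  out
}

#' Odds ratio with Woolf (log-OR) confidence interval
#'
#' Tabulates exposure against live birth, computes OR = ad/bc, a 95%
#' normal-approximation interval on the log scale, and a two-sided p from
#' the log-OR z statistic. A zero cell triggers the Haldane-Anscombe +0.5
#' correction (flagged in the result). With `exclude_aneuploid`, subjects
#' whose miscarriage is karyotyped aneuploid are removed before
#' tabulation, isolating losses attributable to the endometrium rather
#' than embryonic chromosome errors.
#'
#' @param exposed logical exposure flag per subject.
#' @param live_birth logical outcome per subject.
#' @param karyotype optional per-subject karyotype ("aneuploid",
#'   "euploid", "unknown" or NA).
#' @param exclude_aneuploid drop confirmed aneuploid losses first.
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `or_result`: `table`, `or_estimate`,
#'   `ci_low`, `ci_high`, `p`, `haldane_corrected`, `exclusion_applied`.
#' @export
odds_ratio_ci <- function(exposed, live_birth, karyotype = NULL,
                          exclude_aneuploid = FALSE, conf_level = 0.95) {
  stopifnot(length(exposed) == length(live_birth))
  keep <- !is.na(exposed) & !is.na(live_birth)
  if (exclude_aneuploid) {
    if (is.null(karyotype)) {
      stop_endoscore("exclude_aneuploid requires karyotype data",
                     "endoscore_missing_karyotype")
    }
    keep <- keep & !(!live_birth & !is.na(karyotype) & karyotype == "aneuploid")
  }
  e <- exposed[keep]; y <- live_birth[keep]
  tab <- matrix(c(sum(e & y), sum(e & !y), sum(!e & y), sum(!e & !y)),
                2, 2, byrow = TRUE,
                dimnames = list(exposure = c("exposed", "unexposed"),
                                outcome = c("live_birth", "no_live_birth")))
  cells <- as.numeric(t(tab))
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(table = tab, or_estimate = or,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se),
                 p = 2 * stats::pnorm(-abs(log(or) / se)),
                 haldane_corrected = haldane,
                 exclusion_applied = exclude_aneuploid),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f), p = %.4g%s%s\n",
              x$or_estimate, x$ci_low, x$ci_high, x$p,
              if (x$exclusion_applied) ", aneuploid losses excluded" else "",
              if (x$haldane_corrected) ", Haldane-corrected" else ""))
  invisible(x)
}

#' Forest-plot tabulations of outcome odds ratios by state flag
#'
#' For each binary state flag (stalled / heightened decidual reaction,
#' suboptimal / strong uNK expansion), odds ratios for both codings of the
#' same cohort: live birth (flagged vs not) and miscarriage (flagged vs
#' not, the reciprocal coding).
#'
#' @param scores a `score_result` with `outcome` (and optionally
#'   `karyotype`) columns.
#' @param exclude_aneuploid drop confirmed aneuploid losses first.
#' @param flags which flags to tabulate.
#' @return a `data.frame`: one row per (flag, outcome coding) with OR, CI
#'   and p.
#' @export
outcome_forest <- function(scores, exclude_aneuploid = FALSE,
                           flags = c("stalled", "heightened",
                                     "suboptimal_unk", "strong_unk")) {
  keep <- !is.na(scores$outcome) & scores$outcome != "none"
  sub <- scores[keep, ]
  live <- sub$outcome == "live_birth"
  kt <- if ("karyotype" %in% names(sub)) sub$karyotype else NULL
  rows <- lapply(flags, function(fl) {
    ex <- sub[[fl]]
    res_live <- odds_ratio_ci(ex, live, kt, exclude_aneuploid)
    res_misc <- odds_ratio_ci(ex, !live, kt, exclude_aneuploid)
    data.frame(flag = fl,
               outcome = c("live_birth", "miscarriage"),
               or = c(res_live$or_estimate, res_misc$or_estimate),
               ci_low = c(res_live$ci_low, res_misc$ci_low),
               ci_high = c(res_live$ci_high, res_misc$ci_high),
               p = c(res_live$p, res_misc$p),
               exclusion_applied = exclude_aneuploid,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Outcome counts and miscarriage rate of a cohort
#'
#' @param cohort a cohort or `score_result` with an `outcome` column.
#' @return list with `n`, `n_live_birth`, `n_miscarriage`,
#'   `miscarriage_rate_pct`, `n_karyotyped`, `n_aneuploid`.
#' @export
outcome_summary <- function(cohort) {
  oc <- cohort$outcome
  known <- !is.na(oc) & oc != "none"
  n <- sum(known)
  n_misc <- sum(oc[known] == "miscarriage")
  kt <- if ("karyotype" %in% names(cohort)) cohort$karyotype else NULL
  list(n = n, n_live_birth = sum(oc[known] == "live_birth"),
       n_miscarriage = n_misc,
       miscarriage_rate_pct = 100 * n_misc / n,
       n_karyotyped = if (is.null(kt)) 0L else
         sum(!is.na(kt) & kt %in% c("euploid", "aneuploid")),
       n_aneuploid = if (is.null(kt)) 0L else
         sum(!is.na(kt) & kt == "aneuploid"))
}

#' Spearman rank correlation between two percentile scores
#'
#' Average ranks for ties; two-sided p from the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom.
#'
#' @param x,y aligned numeric vectors, n >= 3.
#' @return list with `rho`, `p` and `n`; `rho` is `NA` (with a warning)
#'   when either vector is constant.
#' @export
spearman_percentiles <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop_endoscore("need at least 3 pairs", "endoscore_undersized")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant vector: Spearman correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Kruskal-Wallis omnibus test with Dunn's pairwise comparisons
#'
#' Omnibus Kruskal-Wallis H with tie correction; pairwise Dunn z tests on
#' the pooled mean ranks with tie-corrected variance, adjusted by
#' Bonferroni (default) or Holm; compact letters over the adjusted
#' significance pattern.
#'
#' @param values numeric observations.
#' @param groups group label per observation (>= 2 non-empty groups).
#' @param adjust "bonferroni" or "holm".
#' @param alpha significance level (default 0.05).
#' @return list with `H`, `df`, `p`, `pairwise` data.frame and `letters`.
#' @export
kruskal_dunn <- function(values, groups, adjust = c("bonferroni", "holm"),
                         alpha = 0.05) {
  adjust <- match.arg(adjust)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(as.character(groups[keep]))
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) {
    stop_endoscore("need at least two groups", "endoscore_undersized")
  }
  if (length(unique(values)) == 1L) {
    gl <- levels(groups)
    return(list(H = 0, df = nlevels(groups) - 1, p = 1,
                pairwise = NULL,
                letters = stats::setNames(rep("a", length(gl)), gl)))
  }
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  gl <- levels(groups)
  pairs <- t(utils::combn(gl, 2))
  m <- nrow(pairs)
  pw <- do.call(rbind, lapply(seq_len(m), function(i) {
    g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
    z <- (rbar[g1] - rbar[g2]) / sqrt(v0 * (1 / ng[g1] + 1 / ng[g2]))
    data.frame(g1 = g1, g2 = g2, z = unname(z),
               raw_p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  pw$adjusted_p <- stats::p.adjust(pw$raw_p, method = adjust)
  pw$significant <- pw$adjusted_p < alpha
  rownames(pw) <- NULL
  letters_out <- compact_letters(gl, pw[pw$significant, c("g1", "g2")])
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairwise = pw, letters = letters_out)
}
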