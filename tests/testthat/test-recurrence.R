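qlv <- c("Q1", "Q2", "Q3", "Q4")

test_that("quartile table counts, percentages and symmetry", {
  # one pair per cell
  grid <- expand.grid(A = qlv, B = qlv, stringsAsFactors = FALSE)
  tab <- build_quartile_table(grid$A, grid$B)
  expect_true(all(tab$counts == 1))
  expect_true(all(tab$row_conditional_pct == 25))
  expect_equal(tab$n_pairs, 16)
  expect_equal(rowSums(tab$row_conditional_pct), rep(100, 4),
               ignore_attr = TRUE, tolerance = 1e-9)

  # degenerate: everything in (Q1, Q1)
  tab2 <- build_quartile_table(rep("Q1", 12), rep("Q1", 12))
  expect_equal(tab2$counts[1, 1], 12L)
  expect_equal(sum(tab2$counts), 12)
  expect_equal(tab2$row_conditional_pct[1, 1], 100)
  expect_true(all(is.na(tab2$row_conditional_pct[2:4, ])))

  # swapping the pair order transposes the table
  set.seed(81)
  a <- sample(qlv, 200, replace = TRUE)
  b <- sample(qlv, 200, replace = TRUE)
  expect_equal(build_quartile_table(a, b)$counts,
               t(build_quartile_table(b, a)$counts), ignore_attr = TRUE)

  expect_error(build_quartile_table(a, b[-1]),
               class = "endoscore_unpaired")
  expect_error(build_quartile_table(c("Q1", "Q5"), c("Q1", "Q1")),
               class = "endoscore_invalid_quartile")
})

test_that("one-vs-all chi-square matches hand arithmetic", {
  # collapsed [[25,75],[75,225]] is exactly independent
  tab_ind <- build_quartile_table(
    rep(qlv, times = c(100, 100, 100, 100)),
    c(rep(qlv, times = c(25, 25, 25, 25)),
      rep(qlv, times = c(25, 25, 25, 25)),
      rep(qlv, times = c(25, 25, 25, 25)),
      rep(qlv, times = c(25, 25, 25, 25))))
  res <- one_vs_all_chi2(tab_ind, "Q1")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # collapsed [[10,20],[20,10]]: Yates chi-square 5.4, p ~ 0.0201
  quartA <- rep(c("Q1", "Q2"), times = c(30, 30))
  quartB <- c(rep(c("Q1", "Q2"), times = c(10, 20)),
              rep(c("Q1", "Q2"), times = c(20, 10)))
  tab <- build_quartile_table(quartA, quartB)
  res2 <- one_vs_all_chi2(tab, "Q1")
  expect_equal(res2$statistic, 5.4, tolerance = 1e-9)
  expect_equal(res2$p, 0.0201367, tolerance = 1e-5)
  expect_identical(res2$method, "chisq_yates")

  # zero margin is an error
  empty_b <- build_quartile_table(rep("Q1", 10), rep("Q2", 10))
  expect_error(one_vs_all_chi2(empty_b, "Q3"),
               class = "endoscore_zero_margin")

  # small expected counts switch to the exact test
  small <- build_quartile_table(rep(qlv, times = c(3, 3, 3, 3)),
                                rep(qlv, times = c(3, 3, 3, 3)))
  expect_identical(one_vs_all_chi2(small, "Q1")$method, "fisher_exact")
})

test_that("Fisher cell enrichment: p-values, direction, Bonferroni", {
  # embed the 2x2 [[3,1],[1,3]] as the (Q1, Q1) one-vs-all collapse
  quartA <- rep(c("Q1", "Q2"), times = c(4, 4))
  quartB <- c(rep(c("Q1", "Q2"), times = c(3, 1)),
              rep(c("Q1", "Q2"), times = c(1, 3)))
  tab <- build_quartile_table(quartA, quartB)
  res <- fisher_cell_enrichment(tab)
  cell <- res[res$A == "Q1" & res$B == "Q1", ]
  expect_equal(cell$raw_p, 0.485714, tolerance = 1e-6)
  expect_equal(cell$raw_p, fisher_p_enum(3, 1, 1, 3), tolerance = 1e-9)
  expect_identical(cell$direction, "enriched")
  expect_equal(cell$adjusted_p, min(1, 16 * cell$raw_p))

  # exact null: observed equals expected, direction none, never significant
  quartA2 <- rep(c("Q1", "Q2"), times = c(4, 4))
  quartB2 <- rep(c("Q1", "Q2", "Q1", "Q2"), times = c(2, 2, 2, 2))
  res2 <- fisher_cell_enrichment(build_quartile_table(quartA2, quartB2))
  cell2 <- res2[res2$A == "Q1" & res2$B == "Q1", ]
  expect_equal(cell2$raw_p, 1)
  expect_identical(cell2$direction, "none")
  expect_false(cell2$significant)

  # Bonferroni arithmetic
  expect_equal(min(1, 16 * 0.002), 0.032)
  expect_true(min(1, 16 * 0.002) < 0.05)
})

test_that("module Fisher p equals hypergeometric enumeration (property)", {
  set.seed(83)
  for (rep in 1:200) {
    n <- sample(4:30, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
    m <- matrix(cells, 2, 2, byrow = TRUE)
    expect_equal(endoscore:::fisher_p_2x2(m),
                 fisher_p_enum(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("B-biopsy uniformity test matches hand arithmetic", {
  tab <- build_quartile_table(rep("Q1", 100),
                              rep(qlv, times = c(25, 25, 25, 25)))
  res <- column_uniformity(tab, "Q1")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  tab2 <- build_quartile_table(rep("Q1", 100),
                               rep(qlv, times = c(40, 20, 20, 20)))
  res2 <- column_uniformity(tab2, "Q1")
  expect_equal(res2$statistic, 12)
  expect_equal(res2$df, 3)
  expect_equal(res2$p, 0.00738, tolerance = 1e-3)

  expect_error(column_uniformity(tab2, "Q2"), class = "endoscore_empty")
})

test_that("recurrence rate is the diagonal row-conditional probability", {
  tab <- build_quartile_table(rep("Q1", 80),
                              rep(qlv, times = c(44, 12, 12, 12)))
  expect_equal(recurrence_rate(tab, "Q1"), 0.55)

  # independence-structured table: recurrence equals the marginal 25%
  grid <- expand.grid(A = qlv, B = qlv, stringsAsFactors = FALSE)
  tab_ind <- build_quartile_table(grid$A, grid$B)
  for (b in qlv) expect_equal(recurrence_rate(tab_ind, b), 0.25)

  # diagonal-only table: perfect persistence
  tab_diag <- build_quartile_table(rep(qlv, 5), rep(qlv, 5))
  for (b in qlv) expect_equal(recurrence_rate(tab_diag, b), 1)

  expect_warning(r <- recurrence_rate(tab, "Q2"), "undefined")
  expect_true(is.na(r))
})

test_that("row-weighted conditional shares recover the marginal share", {
  set.seed(84)
  a <- sample(qlv, 500, replace = TRUE)
  b <- sample(qlv, 500, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  tab <- build_quartile_table(a, b)
  w <- rowSums(tab$counts) / tab$n_pairs
  for (j in 1:4) {
    marginal <- sum(tab$counts[, j]) / tab$n_pairs
    expect_equal(sum(w * tab$counts[, j] / rowSums(tab$counts)), marginal,
                 tolerance = 1e-12)
  }
})

test_that("stratified analysis reduces to unstratified for one stratum", {
  set.seed(85)
  a <- sample(qlv, 120, replace = TRUE)
  b <- sample(qlv, 120, replace = TRUE)
  whole <- paired_quartile_analysis(a, b)
  strat <- stratified_recurrence(a, b, rep(0L, 120))
  expect_length(strat, 1)
  expect_identical(strat[["0"]]$table$counts, whole$table$counts)
  expect_equal(strat[["0"]]$enrichment$raw_p, whole$enrichment$raw_p)
  expect_equal(strat[["0"]]$recurrence, whole$recurrence)
})

test_that("strata generated with different intercycle dependence separate", {
  model <- cached_model()
  score_pairs <- function(rho, seed) {
    coh <- simulate_paired_cohort(default_params(rho_cycle = rho), 4000,
                                  seed = seed)
    pair_scores(score_cohort(coh, model))
  }
  null_pairs <- score_pairs(0, 86)
  dep_pairs <- score_pairs(0.62, 87)
  combined_a <- c(as.character(null_pairs$quartA),
                  as.character(dep_pairs$quartA))
  combined_b <- c(as.character(null_pairs$quartB),
                  as.character(dep_pairs$quartB))
  strata <- rep(c("low_risk", "high_risk"), each = 4000)
  res <- stratified_recurrence(combined_a, combined_b, strata)
  expect_lt(abs(res$low_risk$recurrence[["Q1"]] - 0.25), 0.03)
  expect_lt(abs(res$high_risk$recurrence[["Q1"]] - 0.55), 0.03)
})

test_that("pairs whose stratum lacks first-biopsy Q1 report missing", {
  a <- rep(c("Q2", "Q3"), 20)
  b <- rep(c("Q1", "Q4"), 20)
  res <- paired_quartile_analysis(a, b)
  expect_true(is.na(res$recurrence[["Q1"]]))
})
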