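test_that("log transform of copy numbers is log10 with strict positivity", {
  expect_equal(log_transform_copies(1), 0)
  expect_equal(log_transform_copies(1000), 3)
  expect_equal(log_transform_copies(250), 2.39794, tolerance = 1e-5)
  expect_error(log_transform_copies(0), class = "endoscore_nonpositive")
  expect_error(log_transform_copies(-5), class = "endoscore_nonpositive")
})

test_that("Cramer-von Mises statistic matches its definition", {
  # single point at the median: only the 1/(12n) floor remains
  expect_equal(cvm_statistic(5, function(x) rep(0.5, length(x))), 1 / 12)
  # F equal to the plotting positions exactly: the lower bound
  cdf_pp <- function(x) c(0.25, 0.75)[match(x, c(1, 2))]
  expect_equal(cvm_statistic(c(1, 2), cdf_pp), 1 / 24)
  # hand arithmetic on the definition
  cdf_half <- function(x) rep(0.5, length(x))
  expect_equal(cvm_statistic(c(1, 2), cdf_half), 1 / 24 + 2 * 0.25^2)
  expect_error(cvm_statistic(numeric(0), cdf_half),
               class = "endoscore_empty")
})

test_that("CvM statistic agrees with a brute-force reimplementation", {
  brute_cvm <- function(x, cdf) {
    x <- sort(x)
    n <- length(x)
    total <- 1 / (12 * n)
    for (i in seq_len(n)) {
      total <- total + (cdf(x[i]) - (2 * i - 1) / (2 * n))^2
    }
    total
  }
  set.seed(77)
  for (rep in 1:20) {
    x <- rlnorm(sample(5:200, 1))
    cdf <- function(v) plnorm(v, 0.2, 1.3)
    expect_equal(cvm_statistic(x, cdf), brute_cvm(x, cdf))
    expect_gte(cvm_statistic(x, cdf), 1 / (12 * length(x)))
  }
})

test_that("gamma MLE agrees with the MASS fitdistr oracle", {
  skip_if_not_installed("MASS")
  set.seed(42)
  for (rep in 1:5) {
    x <- rgamma(500, shape = runif(1, 0.5, 5), scale = runif(1, 0.2, 3))
    ours <- endoscore:::fit_gamma_mle(x)
    oracle <- suppressWarnings(MASS::fitdistr(x, "gamma"))
    expect_equal(ours$shape, unname(oracle$estimate["shape"]),
                 tolerance = 1e-4)
    expect_equal(1 / ours$scale, unname(oracle$estimate["rate"]),
                 tolerance = 1e-4)
  }
})

test_that("CvM family selection is consistent for large samples", {
  n_rep <- 40
  pick_family <- function(gen, seed) {
    vapply(seq_len(n_rep), function(r) {
      x <- with_seed_test(seed + r, gen())
      fit_ratio_reference(x, lh_day = 7)$family
    }, character(1))
  }
  from_lnorm <- pick_family(function() rlnorm(5000, 0, 1), 100)
  expect_gte(mean(from_lnorm == "lognormal"), 0.95)
  from_gamma <- pick_family(function() rgamma(5000, shape = 2, scale = 1), 200)
  expect_gte(mean(from_gamma == "gamma"), 0.95)
})

test_that("ratio fit stores both statistics and enforces preconditions", {
  set.seed(5)
  x <- rlnorm(100)
  fit <- fit_ratio_reference(x, lh_day = 8)
  expect_s3_class(fit, "ratio_fit")
  expect_gte(fit$cvm_gamma, 1 / (12 * 100))
  expect_gte(fit$cvm_lognormal, 1 / (12 * 100))
  selected_cvm <- if (fit$family == "gamma") fit$cvm_gamma else fit$cvm_lognormal
  expect_lte(selected_cvm, min(fit$cvm_gamma, fit$cvm_lognormal))
  expect_error(fit_ratio_reference(rlnorm(10), lh_day = 6),
               class = "endoscore_undersized")
  expect_error(fit_ratio_reference(c(rlnorm(30), -1), lh_day = 6),
               class = "endoscore_nonpositive")
  expect_error(fit_ratio_reference(rep(2, 50), lh_day = 6),
               class = "endoscore_degenerate")
})

test_that("scale equivariance leaves percentile scores unchanged", {
  set.seed(9)
  x <- rgamma(400, shape = 3, scale = 0.7)
  c_ <- 4.2
  fit1 <- fit_ratio_reference(x, lh_day = 7)
  fit2 <- fit_ratio_reference(c_ * x, lh_day = 7)
  expect_identical(fit1$family, fit2$family)
  if (fit1$family == "gamma") {
    expect_equal(fit2$params$shape, fit1$params$shape, tolerance = 1e-7)
    expect_equal(fit2$params$scale, c_ * fit1$params$scale, tolerance = 1e-7)
  } else {
    expect_equal(fit2$params$meanlog, fit1$params$meanlog + log(c_),
                 tolerance = 1e-9)
  }
  q <- quantile(x, c(0.1, 0.5, 0.9))
  p1 <- vapply(q, function(v) endoscore:::ratio_fit_cdf(fit1, v), numeric(1))
  p2 <- vapply(c_ * q, function(v) endoscore:::ratio_fit_cdf(fit2, v),
               numeric(1))
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("analyte fits are log10-normal MLE with degenerate-data guard", {
  fit <- fit_analyte_reference(c(10, 100, 1000), "tsh", lh_day = 7,
                               min_n = 3)
  expect_equal(fit$log_mean, 2)
  expect_equal(fit$log_sd, sqrt(2 / 3))
  expect_error(fit_analyte_reference(rep(50, 30), "tsh", lh_day = 7),
               class = "endoscore_degenerate")
  expect_error(fit_analyte_reference(c(10, 100), "tsh", lh_day = 7),
               class = "endoscore_undersized")
})

test_that("reference model covers the day range and recovers families", {
  cohort <- simulate_reference_cohort(default_params(), n = 2000, seed = 55)
  model <- build_reference_model(cohort)
  for (ratio in c("stromal", "unk")) {
    expect_length(model$ratio_fits[[ratio]], 5)
  }
  # generating families: stromal lognormal, unk gamma on every day
  stromal_fams <- vapply(model$ratio_fits$stromal, `[[`, character(1),
                         "family")
  unk_fams <- vapply(model$ratio_fits$unk, `[[`, character(1), "family")
  expect_gte(sum(stromal_fams == "lognormal"), 4)
  expect_gte(sum(unk_fams == "gamma"), 4)
})

test_that("missing days fail loudly unless adjacent pooling is enabled", {
  cohort <- simulate_reference_cohort(default_params(), n = 800, seed = 56)
  restricted <- cohort[cohort$lh_day %in% c(6, 7), ]
  err <- expect_error(build_reference_model(restricted),
                      class = "endoscore_missing_days")
  expect_match(conditionMessage(err), "8, 9, 10")
  pooled <- build_reference_model(restricted, pool_adjacent = TRUE)
  expect_length(pooled$ratio_fits$stromal, 5)
})

test_that("model serialization round-trips to identical scores", {
  model <- cached_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_reference_model(model, path)
  model2 <- read_reference_model(path)
  cohort <- simulate_reference_cohort(default_params(), n = 100, seed = 57)
  s1 <- score_cohort(cohort, model)
  s2 <- score_cohort(cohort, model2)
  expect_identical(s1$stromal_percentile, s2$stromal_percentile)
  expect_identical(s1$unk_percentile, s2$unk_percentile)
})

test_that("samples with zero copies are excluded with a warning", {
  cohort <- simulate_reference_cohort(default_params(), n = 500, seed = 58)
  cohort$copies_pla2g2a[1:3] <- 0
  expect_warning(model <- build_reference_model(cohort, min_n = 15),
                 "excluded")
  expect_length(model$ratio_fits$stromal, 5)
})
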