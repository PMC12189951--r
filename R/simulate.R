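#' Simulation parameters for synthetic endometrial cohorts
#'
#' Bundles every knob of the Gaussian-copula cohort generator: per-LH-day
#' marker-ratio distributions (gamma or log-normal), denominator-gene copy
#' levels, latent correlations, prior-loss and pregnancy-outcome models, and
#' the seed. Defaults reproduce the statistical structure the downstream
#' analyses assume: a cross-trait latent correlation of 0.377 (so the
#' Spearman correlation between the two percentile scores is about 0.36), an
#' intercycle latent correlation of 0.62 for the stromal trait (so the
#' lowest-quartile state recurs in about 55% of paired biopsies), and a
#' stalled-state live-birth model giving an odds ratio near 0.52.
#'
#' @param n_samples default cohort size for [simulate_reference_cohort()].
#' @param day_range integer vector `c(min, max)` of days after the LH surge.
#' @param lh_day_weights sampling probabilities over `day_range` (must sum
#'   to 1); default uniform.
#' @param per_day_ratio_spec nested list `ratio -> day -> spec`, each spec a
#'   list with `family` ("gamma" or "lognormal") and its parameters
#'   (`shape`/`scale` or `meanlog`/`sdlog`, natural-log scale).
#' @param per_day_gene_spec nested list `gene -> day -> list(log_mean,
#'   log_sd)` (log10 copies) for the denominator gene of each ratio.
#' @param hormone_spec optional nested list `analyte -> day ->
#'   list(log_mean, log_sd)` (log10 units) for circulating hormones.
#' @param rho_cross latent correlation in [-1, 1] between the stromal and
#'   uNK traits within a sample.
#' @param rho_cycle latent correlation in [-1, 1] between a subject's two
#'   cycle-specific stromal traits.
#' @param cycle_transition_matrix optional 4x4 row-stochastic matrix of
#'   first-cycle to second-cycle stromal quartile transition probabilities;
#'   when supplied it replaces the symmetric Gaussian intercycle copula
#'   (which cannot produce asymmetric low/high-quartile recurrence). No
#'   default values are provided.
#' @param prior_loss_model list with `probs`, category probabilities for 0,
#'   1, 2, 3, and 4-or-more prior pregnancy losses, and `trait_coef`, a
#'   logistic shift per unit of (negative) latent stromal trait linking a
#'   weak decidual reaction to more prior losses (0 = independent).
#' @param outcome_model list with `flag` (exposure definition: "stalled",
#'   "heightened", "suboptimal_unk" or "strong_unk"), `prevalence` of the
#'   flag, `p_live_exposed` / `p_live_unexposed` live-birth probabilities,
#'   `aneuploid_fraction` of karyotyped losses that are aneuploid, and
#'   `karyotyped_fraction` of losses with a karyotype result.
#' @param seed integer RNG seed; all generator randomness flows from it.
#' @return an object of class `simulation_params`.
#' @export
simulation_params <- function(n_samples = 779L,
                              day_range = c(6L, 10L),
                              lh_day_weights = NULL,
                              per_day_ratio_spec = NULL,
                              per_day_gene_spec = NULL,
                              hormone_spec = NULL,
                              rho_cross = 0.377,
                              rho_cycle = 0.62,
                              cycle_transition_matrix = NULL,
                              prior_loss_model = NULL,
                              outcome_model = NULL,
                              seed = 1L) {
  days <- seq.int(day_range[1], day_range[2])
  lh_day_weights <- lh_day_weights %||% rep(1 / length(days), length(days))
  per_day_ratio_spec <- per_day_ratio_spec %||% default_ratio_spec(days)
  per_day_gene_spec <- per_day_gene_spec %||% default_gene_spec(days)
  hormone_spec <- hormone_spec %||% default_hormone_spec(days)
  prior_loss_model <- prior_loss_model %||%
    list(probs = c(0.30, 0.20, 0.20, 0.15, 0.15), trait_coef = 0)
  outcome_model <- outcome_model %||%
    list(flag = "stalled", prevalence = 0.25,
         p_live_exposed = 0.438, p_live_unexposed = 0.600,
         aneuploid_fraction = 0.55, karyotyped_fraction = 46 / 84)

  p <- structure(
    list(n_samples = as.integer(n_samples), day_range = as.integer(day_range),
         days = days, lh_day_weights = lh_day_weights,
         per_day_ratio_spec = per_day_ratio_spec,
         per_day_gene_spec = per_day_gene_spec,
         hormone_spec = hormone_spec,
         rho_cross = rho_cross, rho_cycle = rho_cycle,
         cycle_transition_matrix = cycle_transition_matrix,
         prior_loss_model = prior_loss_model,
         outcome_model = outcome_model, seed = as.integer(seed)),
    class = "simulation_params")
  validate_simulation_params(p)
  p
}

validate_simulation_params <- function(p) {
  if (abs(sum(p$lh_day_weights) - 1) > 1e-12) {
    stop_endoscore("lh_day_weights must sum to 1", "endoscore_invalid_params")
  }
  if (abs(sum(p$prior_loss_model$probs) - 1) > 1e-12) {
    stop_endoscore("prior_loss_model$probs must sum to 1",
                   "endoscore_invalid_params")
  }
  for (rho in c(p$rho_cross, p$rho_cycle)) {
    if (!is.finite(rho) || rho < -1 || rho > 1) {
      stop_endoscore("latent correlations must lie in [-1, 1]",
                     "endoscore_invalid_params")
    }
  }
  for (ratio in names(p$per_day_ratio_spec)) {
    for (d in as.character(p$days)) {
      spec <- p$per_day_ratio_spec[[ratio]][[d]]
      if (is.null(spec)) {
        stop_endoscore(sprintf("no ratio spec for '%s' on day %s", ratio, d),
                       "endoscore_invalid_params")
      }
      if (!spec$family %in% c("gamma", "lognormal")) {
        stop_endoscore(sprintf("unknown family '%s'", spec$family),
                       "endoscore_invalid_family")
      }
      pars <- if (spec$family == "gamma") c(spec$shape, spec$scale) else spec$sdlog
      if (any(!is.finite(pars)) || any(pars <= 0)) {
        stop_endoscore(sprintf("non-positive parameters for '%s' day %s",
                               ratio, d), "endoscore_invalid_params")
      }
    }
  }
  om <- p$outcome_model
  probs <- c(om$prevalence, om$p_live_exposed, om$p_live_unexposed,
             om$aneuploid_fraction, om$karyotyped_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop_endoscore("outcome_model probabilities must lie in [0, 1]",
                   "endoscore_invalid_params")
  }
  tm <- p$cycle_transition_matrix
  if (!is.null(tm)) {
    if (!is.matrix(tm) || any(dim(tm) != 4) || any(tm < 0) ||
        any(abs(rowSums(tm) - 1) > 1e-12)) {
      stop_endoscore("cycle_transition_matrix must be 4x4 row-stochastic",
                     "endoscore_invalid_params")
    }
  }
  invisible(p)
}

# Defaults emulate the midluteal window: the decidual reaction (stromal
# PLA2G2A/DIO2 ratio) strengthens steeply from LH+6 to LH+10 while uNK
# expansion (ITGAD/CD160) rises more gently; families alternate so the
# calibration's gamma-vs-lognormal selection is exercised on both.
default_ratio_spec <- function(days) {
  stromal <- lapply(seq_along(days), function(i) {
    list(family = "lognormal", meanlog = -1.2 + 0.6 * (i - 1), sdlog = 0.9)
  })
  unk <- lapply(seq_along(days), function(i) {
    list(family = "gamma", shape = 2, scale = 0.5 * 1.35^(i - 1))
  })
  names(stromal) <- names(unk) <- as.character(days)
  list(stromal = stromal, unk = unk)
}

default_gene_spec <- function(days) {
  spec <- function(log_mean, log_sd) {
    out <- lapply(days, function(d) list(log_mean = log_mean, log_sd = log_sd))
    names(out) <- as.character(days)
    out
  }
  list(copies_dio2 = spec(2.6, 0.35), copies_cd160 = spec(2.2, 0.35))
}

default_hormone_spec <- function(days) {
  # log10 scales: progesterone ~30 ng/ml mid-luteal, estradiol ~150 pg/ml,
  # TSH ~1.6 mIU/l; mild day trends for progesterone only.
  prog <- lapply(seq_along(days), function(i) {
    list(log_mean = 1.40 + 0.02 * (i - 1), log_sd = 0.18)
  })
  names(prog) <- as.character(days)
  flat <- function(log_mean, log_sd) {
    out <- lapply(days, function(d) list(log_mean = log_mean, log_sd = log_sd))
    names(out) <- as.character(days)
    out
  }
  list(progesterone = prog, estradiol = flat(2.18, 0.22), tsh = flat(0.20, 0.25))
}

ratio_quantile <- function(u, spec) {
  switch(spec$family,
    gamma = stats::qgamma(u, shape = spec$shape, scale = spec$scale),
    lognormal = stats::qlnorm(u, meanlog = spec$meanlog, sdlog = spec$sdlog),
    stop_endoscore(sprintf("unknown family '%s'", spec$family),
                   "endoscore_invalid_family"))
}

# Converts latent standard-normal traits + LH days into the observable part
# of a cohort: the ratio is the inverse-CDF transform of the latent uniform,
# the denominator gene is drawn log-normally, and the numerator is defined
# as ratio x denominator so the ratio is exact by construction.
latents_to_records <- function(z_s, z_u, lh_day, params, subject_id,
                               sample_id, cycle_index = 1L) {
  n <- length(z_s)
  genes <- ratio_genes()
  ratios <- list(stromal = numeric(n), unk = numeric(n))
  z <- list(stromal = z_s, unk = z_u)
  for (ratio in names(ratios)) {
    u <- stats::pnorm(z[[ratio]])
    for (d in unique(lh_day)) {
      idx <- lh_day == d
      spec <- params$per_day_ratio_spec[[ratio]][[as.character(d)]]
      ratios[[ratio]][idx] <- ratio_quantile(u[idx], spec)
    }
  }
  cohort <- data.frame(
    sample_id = sample_id, subject_id = subject_id,
    cycle_index = as.integer(cycle_index), lh_day = as.integer(lh_day),
    stringsAsFactors = FALSE)
  for (ratio in names(genes)) {
    den_col <- genes[[ratio]]["den"]
    num_col <- genes[[ratio]]["num"]
    den <- numeric(n)
    for (d in unique(lh_day)) {
      idx <- lh_day == d
      gs <- params$per_day_gene_spec[[den_col]][[as.character(d)]]
      den[idx] <- 10^stats::rnorm(sum(idx), gs$log_mean, gs$log_sd)
    }
    cohort[[num_col]] <- ratios[[ratio]] * den
    cohort[[den_col]] <- den
  }
  cohort <- cohort[, c("sample_id", "subject_id", "cycle_index", "lh_day",
                       "copies_pla2g2a", "copies_dio2", "copies_itgad",
                       "copies_cd160")]
  for (analyte in names(params$hormone_spec)) {
    v <- numeric(n)
    for (d in unique(lh_day)) {
      idx <- lh_day == d
      hs <- params$hormone_spec[[analyte]][[as.character(d)]]
      v[idx] <- 10^stats::rnorm(sum(idx), hs$log_mean, hs$log_sd)
    }
    cohort[[analyte]] <- v
  }
  cohort
}

draw_prior_losses <- function(z_s, model) {
  n <- length(z_s)
  k <- length(model$probs)
  if ((model$trait_coef %||% 0) == 0) {
    return(sample.int(k, n, replace = TRUE, prob = model$probs) - 1L)
  }
  # Proportional-odds logistic link: a weaker (more negative) latent stromal
  # trait shifts mass toward more prior losses.
  cum <- cumsum(model$probs)[-k]
  alpha <- stats::qlogis(cum)                       # baseline thresholds
  losses <- integer(n)
  for (i in seq_len(n)) {
    cdf <- stats::plogis(alpha + model$trait_coef * z_s[i])
    u <- stats::runif(1)
    losses[i] <- sum(u > cdf)
  }
  losses
}

#' Simulate a reference (calibration) cohort
#'
#' Draws `n` single-biopsy samples across the implantation window. The two
#' latent traits are bivariate standard normal with correlation
#' `params$rho_cross`; each becomes that day's marker ratio through the
#' configured family's inverse CDF (a Gaussian copula on the ratio pair).
#'
#' @param params a [simulation_params()] object.
#' @param n number of samples (defaults to `params$n_samples`).
#' @param seed RNG seed (defaults to `params$seed`).
#' @return a cohort `data.frame`, one row per biopsy, with ddPCR copy
#'   numbers for PLA2G2A, DIO2, ITGAD and CD160, hormone levels, and prior
#'   pregnancy losses. Deterministic given the seed.
#' @export
simulate_reference_cohort <- function(params, n = params$n_samples,
                                      seed = params$seed) {
  validate_simulation_params(params)
  with_seed(seed, {
    lh_day <- sample(params$days, n, replace = TRUE,
                     prob = params$lh_day_weights)
    z_s <- stats::rnorm(n)
    z_u <- params$rho_cross * z_s +
      sqrt(1 - params$rho_cross^2) * stats::rnorm(n)
    ids <- sprintf("S%05d", seq_len(n))
    cohort <- latents_to_records(z_s, z_u, lh_day, params,
                                 subject_id = ids,
                                 sample_id = paste0(ids, "_c1"))
    cohort$prior_losses <- draw_prior_losses(z_s, params$prior_loss_model)
    cohort$outcome <- NA_character_
    cohort$karyotype <- NA_character_
    attr(cohort, "latents") <- data.frame(z_stromal = z_s, z_unk = z_u)
    cohort
  })
}

#' Simulate a paired-biopsy cohort (two cycles per subject)
#'
#' Each subject contributes two biopsies from different menstrual cycles.
#' The two cycle-specific latent stromal traits are bivariate standard
#' normal with correlation `params$rho_cycle`, modelling intercycle
#' persistence of the decidual-reaction state; uNK latent traits are drawn
#' independently per cycle (the uNK score of one cycle carries no
#' information about the next). LH day is drawn independently per cycle.
#'
#' If `params$cycle_transition_matrix` is supplied, the second cycle's
#' stromal quartile is instead drawn from that matrix's row for the first
#' cycle's quartile, allowing asymmetric low/high-quartile recurrence that
#' no symmetric copula can produce.
#'
#' @param params a [simulation_params()] object.
#' @param n_pairs number of subjects (each yields two rows).
#' @param seed RNG seed (defaults to `params$seed`).
#' @return a cohort `data.frame` with `cycle_index` 1 and 2 per subject.
#' @export
simulate_paired_cohort <- function(params, n_pairs, seed = params$seed) {
  validate_simulation_params(params)
  stopifnot(n_pairs >= 1)
  with_seed(seed, {
    z1 <- stats::rnorm(n_pairs)
    tm <- params$cycle_transition_matrix
    if (is.null(tm)) {
      z2 <- params$rho_cycle * z1 +
        sqrt(1 - params$rho_cycle^2) * stats::rnorm(n_pairs)
    } else {
      edges <- stats::qnorm(c(0, 0.25, 0.5, 0.75, 1))
      q1 <- findInterval(z1, edges, all.inside = TRUE)
      q2 <- vapply(q1, function(q) {
        sample.int(4L, 1L, prob = tm[q, ])
      }, integer(1))
      # uniform within the target quartile, mapped back to the normal scale
      z2 <- stats::qnorm(stats::runif(n_pairs, (q2 - 1) / 4, q2 / 4))
    }
    subj <- sprintf("P%05d", seq_len(n_pairs))
    cohorts <- lapply(1:2, function(cycle) {
      z_s <- if (cycle == 1) z1 else z2
      z_u <- stats::rnorm(n_pairs)   # no intercycle or cross-trait carryover
      lh_day <- sample(params$days, n_pairs, replace = TRUE,
                       prob = params$lh_day_weights)
      out <- latents_to_records(z_s, z_u, lh_day, params, subject_id = subj,
                                sample_id = sprintf("%s_c%d", subj, cycle),
                                cycle_index = cycle)
      out
    })
    cohort <- rbind(cohorts[[1]], cohorts[[2]])
    cohort <- cohort[order(cohort$subject_id, cohort$cycle_index), ]
    rownames(cohort) <- NULL
    losses <- draw_prior_losses(z1, params$prior_loss_model)
    cohort$prior_losses <- losses[match(cohort$subject_id, subj)]
    cohort$outcome <- NA_character_
    cohort$karyotype <- NA_character_
    attr(cohort, "latents") <- data.frame(subject_id = subj,
                                          z_stromal_1 = z1, z_stromal_2 = z2)
    cohort
  })
}

#' Simulate a prospective outcome cohort
#'
#' Draws `n` pre-pregnancy biopsies and pregnancy outcomes. The exposure
#' flag (e.g. a stalled decidual reaction) is taken directly from the
#' latent trait: the flag holds when the trait falls below the
#' `prevalence` quantile (low-tail flags "stalled"/"suboptimal_unk") or
#' above the `1 - prevalence` quantile (high-tail flags
#' "heightened"/"strong_unk"). Live birth is Bernoulli with the
#' flag-conditional probability; among miscarriages a configured fraction
#' is karyotyped, of which a configured fraction is aneuploid.
#'
#' @param params a [simulation_params()] object.
#' @param n cohort size.
#' @param seed RNG seed (defaults to `params$seed`).
#' @return a cohort `data.frame` with `outcome` and `karyotype` filled in,
#'   plus an `exposed` logical column holding the generator's exposure
#'   flag (the flag name is recorded in the `exposure_flag` attribute).
#' @export
simulate_outcome_cohort <- function(params, n, seed = params$seed) {
  validate_simulation_params(params)
  om <- params$outcome_model
  cohort <- simulate_reference_cohort(params, n = n, seed = seed)
  z <- attr(cohort, "latents")
  trait <- if (om$flag %in% c("stalled", "heightened")) z$z_stromal else z$z_unk
  exposed <- if (om$flag %in% c("stalled", "suboptimal_unk")) {
    trait < stats::qnorm(om$prevalence)
  } else {
    trait > stats::qnorm(1 - om$prevalence)
  }
  with_seed(seed + 1L, {
    p_live <- ifelse(exposed, om$p_live_exposed, om$p_live_unexposed)
    live <- stats::runif(n) < p_live
    cohort$outcome <- ifelse(live, "live_birth", "miscarriage")
    karyotyped <- !live & (stats::runif(n) < om$karyotyped_fraction)
    aneuploid <- karyotyped & (stats::runif(n) < om$aneuploid_fraction)
    cohort$karyotype <- ifelse(live, NA_character_,
                               ifelse(!karyotyped, "unknown",
                                      ifelse(aneuploid, "aneuploid", "euploid")))
  })
  cohort$exposed <- exposed
  attr(cohort, "exposure_flag") <- om$flag
  attr(cohort, "latents") <- z
  cohort
}
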