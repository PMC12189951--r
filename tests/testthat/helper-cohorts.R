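# Shared fixtures: a default parameter set and a cached reference model
# calibrated on a moderately sized simulated cohort, reused across files.

default_params <- function(...) simulation_params(...)

cached_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      cohort <- simulate_reference_cohort(default_params(), n = 2000,
                                          seed = 421L)
      model <<- build_reference_model(cohort)
    }
    model
  }
})

# Independent oracle: two-sided Fisher exact p by exhaustive hypergeometric
# enumeration over all tables with the observed margins.
fisher_p_enum <- function(a, b, c_, d) {
  m <- a + b          # row 1 total
  n_ <- c_ + d        # row 2 total
  k <- a + c_         # column 1 total
  lo <- max(0L, k - n_)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent oracle: bivariate-normal quadrant recurrence
# P(Z2 < q | Z1 < q) at the lower-quartile threshold, by 1-D integration.
orthant_recurrence <- function(rho, prob = 0.25) {
  q <- stats::qnorm(prob)
  if (rho == 0) return(prob)
  stats::integrate(function(z) {
    stats::pnorm((q - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z)
  }, -Inf, q)$value / prob
}

# Closed form for the Spearman correlation induced by a Gaussian copula.
copula_spearman <- function(rho) (6 / pi) * asin(rho / 2)

default_ratio_spec_for_test <- function() {
  endoscore:::default_ratio_spec(6:10)
}

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}
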