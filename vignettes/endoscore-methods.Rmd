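---
title: "Methods: day-calibrated percentile scoring of endometrial marker ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: day-calibrated percentile scoring of endometrial marker ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoscore)
```

## The measurement and why it needs calibration

A timed midluteal endometrial biopsy yields absolute ddPCR transcript
copies for four marker genes. Two ratios summarize the tissue state: the
strength of the decidual reaction, PLA2G2A/DIO2 (predecidual over
progesterone-resistant stromal cells), and uterine NK cell expansion,
ITGAD/CD160 (KIR+ over KIR− subsets). Both ratios shift by an order of
magnitude between LH+6 and LH+10, so each is referenced against the
distribution of samples taken on the *same* day after the LH surge. The
percentile rank — 100 times the fitted reference CDF at the observed
ratio — is the quantity all downstream analyses use. A sample below the
25th percentile of its day is called a *stalled* decidual reaction
(respectively *suboptimal* uNK expansion); above the 75th, *heightened*
(respectively *strong*).

## Reference fitting

Per day and per ratio, two families are fitted to the raw ratios by
maximum likelihood: a gamma (shape/scale; shape solved by Newton
iteration on the profile likelihood equation
$\log a - \psi(a) = \log \bar x - \overline{\log x}$, tolerance 1e-10,
at most 200 iterations, method-of-moments start) and a log-normal
(mean and 1/n-variance sd of log ratios). The Cramér–von Mises
statistic
$$W^2 = \frac{1}{12n} + \sum_{i=1}^n \Big(F(x_{(i)}) - \frac{2i-1}{2n}\Big)^2$$
is computed for both fitted CDFs on the raw ratio scale, and the family
with the smaller $W^2$ is kept. Both statistics are stored in the model
for audit. Design choices behind this stage:

- **Raw ratio scale for both candidates.** Evaluating both CDFs on the
  same data makes the two $W^2$ values directly comparable. Percentile
  ranks are invariant to monotone transforms, so whether quantiles are
  later reported on a log scale does not change any score.
- **Tie-break toward log-normal**, the natural family for a ratio of
  log-scaled quantities. Ties have probability zero in continuous data;
  the rule only pins down degenerate cases.
- **Per (ratio, day) selection.** The family is chosen independently for
  every ratio and every day, the finest granularity the day-indexed
  design supports.
- **Minimum n = 20 per day** (configurable). Below that, calibration
  refuses by default; `pool_adjacent = TRUE` instead borrows the nearest
  adequately sampled day's ratios, trading day-specificity for
  coverage.
- **Zero or missing copies** exclude a sample from the affected ratio
  only, with a logged warning — a zero denominator is a failed assay,
  not a zero ratio. A log-sd below 1e-6 raises a degenerate-data error
  rather than producing an infinitely sharp reference.

Gene and hormone levels (progesterone, estradiol, TSH) are referenced by
a normal fit of log10 values per day, giving
$100\,\Phi((\log_{10}x-\mu_d)/\sigma_d)$.

Models serialize to JSON with 17 significant digits, which round-trips
IEEE doubles exactly; a save/load cycle reproduces bit-identical
percentile scores.

## Quartiles and flags

Percentiles are binned [0,25) → Q1, [25,50) → Q2, [50,75) → Q3,
[75,100] → Q4. The state flags follow the strict printed inequalities:
stalled means percentile < 25 (so exactly 25.0 is Q2 and not stalled) and
heightened means percentile > 75 (so exactly 75.0 is Q4 but not
heightened). The reference data never state how exact boundary values
were binned; the strict convention is ours and is exercised explicitly in
the tests. Samples whose LH day lies outside the calibrated range are
skipped with a reason, never extrapolated.

## Paired-cycle recurrence

For women biopsied in two cycles, the pipeline crosses first- and
second-biopsy quartiles into a 4×4 table. Three tests run on it:

- **One-vs-all chi-square** per bin: the table collapses to a 2×2
  (in-bin vs not, per biopsy) tested with Yates' continuity correction —
  the default behaviour of the statistical environment this analysis
  style comes from — falling back to Fisher's exact test when any
  expected count is below 5.
- **Per-cell Fisher enrichment**: each of the 16 cells is tested
  two-sided against its one-vs-all collapse, with direction from
  observed vs expected under independence (exact ties get direction
  "none" and are never significant) and Bonferroni correction with
  m = 16 cells per table. m is configurable (4 per column is the
  plausible alternative) because the original family size is not
  recoverable; per-table 16 is the conservative reading.
- **Column uniformity**: chi-square goodness of fit (df = 3) of each
  first-biopsy row against a uniform second-biopsy distribution.

The recurrence rate of a state is the diagonal row-conditional
probability P(second ∈ Q | first ∈ Q). Stratified analyses (by prior
pregnancy losses) repeat everything within each stratum, with the
Bonferroni family restricted to that stratum's 16 cells.

Two conventions are deliberately pinned to the standard implementations
so the test oracles are unambiguous: the two-sided Fisher p sums all
hypergeometric outcomes no more probable than the observed one, and the
suite verifies this against an exhaustive enumeration for every 2×2
table with total ≤ 30.

## Outcome association

Odds ratios use OR = ad/bc with the Woolf log-OR interval
$\exp(\ln\mathrm{OR} \pm z_{0.975}\,\sqrt{1/a+1/b+1/c+1/d})$ and a
two-sided p from the log-OR z statistic; a zero cell triggers the
Haldane–Anscombe +0.5 correction, flagged in the result. No CI method is
named in the source analyses; Woolf is the standard unadjusted choice.
"Miscarriage risk" and "live-birth rate" forests are the two codings of
one tabulation and are emitted together (their ORs are exact
reciprocals). Excluding karyotyped aneuploid losses removes pregnancies
lost to embryonic chromosome errors, isolating the endometrial
contribution; unkaryotyped losses stay in. Each flag's OR contrasts that
quartile bin against all other samples (the reference group is not
stated in the source; bin-vs-rest is exposed as the default).

Cross-score association uses Spearman correlation with average ranks and
the t approximation for p; quartile-stratified comparisons use
Kruskal–Wallis with tie correction and Dunn's pairwise z tests,
Bonferroni-adjusted by default (Holm available), summarized by compact
letters.

## The synthetic cohort generator

The generator exists so that calibration, scoring, recurrence and
outcome stages can be validated end to end without patient data. It
encodes the statistical structure the analyses assume:

- **Per-day ratio distributions.** Defaults: the stromal ratio is
  log-normal with log-mean rising from −1.2 at LH+6 to +1.2 at LH+10
  (sd 0.9) — the decidual reaction strengthens steeply across the
  window — and the uNK ratio is gamma (shape 2) with scale growing 35%
  per day. Mixing families exercises the Cramér–von Mises selection in
  both directions; the calibration tests require the selected family to
  match the generating one.
- **Cross-trait dependence.** The two latent traits are bivariate
  standard normal with correlation 0.377; through the Gaussian copula
  this yields a Spearman correlation of $(6/\pi)\,\mathrm{asin}(\rho/2)
  = 0.362$ between the percentile scores, matching the observed ≈ 0.36.
- **Intercycle dependence.** A subject's two cycle-specific stromal
  traits correlate at 0.62, chosen because the bivariate-normal orthant
  probability at $\Phi^{-1}(0.25)$ then gives a 55% recurrence of the
  lowest-quartile state — the reported rate. uNK traits are drawn
  independently per cycle (and independently of the stromal trait in
  paired cohorts): the evidence says only that the first biopsy has no
  discernible impact on the second's uNK score, and exact independence
  is the simplest model consistent with that. A symmetric copula cannot
  simultaneously produce the asymmetric low-quartile (55%) and
  high-quartile (36%) recurrence rates; for that, a user-supplied 4×4
  quartile transition matrix can replace the copula (no default values
  are provided, since none are published).
- **Copy-number decomposition.** The denominator gene is drawn
  log-normally (log10 mean 2.6/2.2, sd 0.35) and the numerator defined
  as ratio × denominator, so the ratio is exact by construction; only
  the ratio's distribution matters downstream.
- **Outcomes.** The exposure flag is thresholded directly on the latent
  trait at the configured prevalence quantile (default 0.25); live birth
  is Bernoulli with flag-conditional probabilities (defaults 0.438
  exposed vs 0.600 unexposed, i.e. a true OR of 0.52); a configured
  fraction of losses is karyotyped (default 46/84) and, of those, 55%
  aneuploid — roughly the fraction seen in sporadic miscarriage.
- **Prior losses.** Independent of the latent trait by default
  (uniform-ish categories 0–4+, weighted toward fewer losses); an
  optional proportional-odds logistic link ties more prior losses to a
  weaker stromal trait for enrichment experiments, with a user-supplied
  coefficient.
- **Seeds.** Every generator call is deterministic given its seed, the
  caller's RNG state is restored afterwards, and replicate r of any
  multi-replicate experiment uses seed + r.

What the generator does **not** emulate: assay noise in the ddPCR counts
beyond the ratio distribution (the ratio is exact by construction),
within-sample spatial heterogeneity of the biopsy, covariate structure
(age, BMI, TSH) in outcomes, and any asymmetry of intercycle dependence
unless a transition matrix is supplied. Passing tests therefore show
that the *machinery* is correct under the assumed structure, not that
real cohorts follow a Gaussian copula.

## Validation scales and numerical choices

The validation suite uses problem sizes chosen to keep Monte-Carlo error
well inside the asserted bands: 50 calibrate-then-score replicates of
n = 779 for the cross-score correlation (band ±0.02), 200 paired
cohorts of 316 pairs for the recurrence rate (±2 percentage points, the
scoring step attenuates the latent 55.0% by about one point), 1,000
null paired cohorts for the family-wise error bound, and means over 50
cohorts of n = 20,000 for odds-ratio recovery (a single cohort's OR has
sd ≈ 0.075 at OR 2.29, so replicate averaging is what the ±0.05 band
measures — estimator bias, not sampling noise). Probability-integral
uniformity is asserted at Kolmogorov–Smirnov distance < 0.05 with at
least 1,800 samples per day.

Known limitations: percentile scores inherit the calibration cohort's
sampling error (roughly 1/√n per day), so small reference cohorts bias
flag prevalences; the gamma Newton solver assumes
$\log\bar x > \overline{\log x}$, which fails only for degenerate
(near-constant) data, where calibration correctly refuses; and
the Fisher/Bonferroni procedure is conservative for sparse tables, as
the null false-positive rate measured by the acceptance suite (≈ 0.04
at α = 0.05) shows.
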