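# endoscore

Day-of-cycle calibrated percentile scoring of endometrial marker-gene
ratios, with paired-cycle recurrence and pregnancy-outcome association
analysis.

## The problem

In each menstrual cycle, progesterone triggers an inflammatory decidual
reaction in the endometrium that first opens the implantation window and
then drives decidual transformation. The strength of that reaction in a
timed midluteal biopsy can be quantified by droplet digital PCR (ddPCR)
as the transcript-copy ratio of a predecidual marker over a
progesterone-resistant stromal marker, **PLA2G2A/DIO2**; the expansion of
immunotolerant uterine natural killer (uNK) cells is likewise proxied by
**ITGAD/CD160**. Because both ratios change steeply across the window
(days LH+6 to LH+10 after the luteinizing-hormone surge), a raw ratio is
meaningless without a day-matched reference.

`endoscore` is the analysis pipeline for this diagnostic: it builds the
day-indexed reference distributions, converts samples to percentile ranks
and quartile bins, flags a *stalled* (percentile < 25) or *heightened*
(percentile > 75) decidual reaction and suboptimal/strong uNK expansion,
quantifies how often the stalled state recurs across a woman's cycles,
and estimates how prepregnancy flags shift the odds of a live birth. A
Gaussian-copula cohort simulator with the same statistical structure
makes every stage testable without patient data.

## The model

For each LH day *d* and each marker ratio, the reference distribution is
fitted by maximum likelihood under two candidate families — gamma and
log-normal — and the family with the smaller Cramér–von Mises statistic

W² = 1/(12n) + Σᵢ [F(x₍ᵢ₎) − (2i−1)/(2n)]²

is selected. A sample with ratio *r* on day *d* receives the percentile
rank 100·F_d(r); gene and hormone levels are referenced by a normal fit
of log₁₀ values, giving 100·Φ((log₁₀x − μ_d)/σ_d). Downstream:

- **Paired biopsies:** 4×4 quartile contingency tables (first × second
  biopsy), one-vs-all 2×2 chi-square (Yates), per-cell two-sided Fisher
  exact tests with Bonferroni correction (m = 16), chi-square
  goodness-of-fit of second-biopsy uniformity within each first-biopsy
  bin, and the recurrence rate P(B ∈ Q | A ∈ Q).
- **Outcomes:** odds ratios OR = ad/bc with Woolf (log-OR) 95% intervals
  exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d)), Haldane–Anscombe correction for
  zero cells, and optional exclusion of karyotyped aneuploid losses;
  quartile-bin frequencies by number of prior pregnancy losses with
  pairwise chi-square/Bonferroni; Spearman correlation between percentile
  scores; Kruskal–Wallis with Dunn's pairwise comparisons.
- **Simulator:** latent traits are bivariate standard normal — the
  cross-trait correlation 0.377 reproduces the observed Spearman ≈ 0.36
  between scores (via ρ_S = (6/π)·asin(ρ/2)), and the intercycle stromal
  correlation 0.62 reproduces the ≈ 55% recurrence of the stalled state
  (a bivariate-normal orthant probability at Φ⁻¹(0.25)).

## Worked example

The numbered scripts under `analysis/` run the whole study on simulated
cohorts (`Rscript analysis/01_simulate_cohorts.R`, then `02` … `05`),
writing tables under `results/`. Calibrating a 779-sample cohort and
scoring it against its own model prints, per day, the selected family
and the self-consistency (probability-integral-transform) check:

```
  stromal LH+7: lognormal selected (W2 gamma 0.3943 vs lognormal 0.0667, n = 150)
  unk LH+7: gamma selected (W2 gamma 0.0385 vs lognormal 0.0752, n = 150)
  LH+7 PIT: KS distance 0.055 (n = 150)
cross-score Spearman rho = 0.382 (p = 2e-28, n = 779)
state flags: 25.8% stalled, 24.5% heightened, 25.0% suboptimal uNK, 25.7% strong uNK
```

Every day's selected family matches the generating family, percentiles
are uniform on the calibration cohort, about a quarter of samples carry
each flag, and the two scores correlate at ρ ≈ 0.38. The paired-cohort
analysis (316 simulated women) then shows the intercycle persistence of
the stromal state and the absence of uNK persistence:

```
  stromal: recurrence by quartile: Q1 43%, Q2 26%, Q3 41%, Q4 57%
  cell (Q1,Q1) enriched (adj. p = 2.6e-05)
  unk: no Bonferroni-significant cells
```

and the prospective-outcome analysis recovers the configured live-birth
odds shift of a stalled decidual reaction:

```
stalled live-birth OR 0.48 (0.26-0.88); aneuploid-excluded 0.47 (0.24-0.88)
```

In interactive use the same steps are four calls:

```r
library(endoscore)
params <- simulation_params()
cohort <- simulate_reference_cohort(params, n = 779)
model  <- build_reference_model(cohort)
scores <- score_cohort(cohort, model)
```

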