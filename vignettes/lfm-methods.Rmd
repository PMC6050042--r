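---
title: "Methods: single-cell survival, granule, and kinetic analysis of longitudinal fluorescence microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell survival, granule, and kinetic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfmkit)
```

This vignette is the package's account of the models it implements, the
choices that were genuinely open, and what the synthetic-data tests do
and do not establish about real microscope data.

## The experimental design being modeled

Primary neurons are transfected with a morphology marker plus a tagged
experimental construct and imaged at 24 h intervals for 10 days. Each
neuron is found, tracked, and followed until it dies (rounding of the
soma, loss of fluorescence, disappearance) or the experiment ends. The
single-cell times of death feed survival models; nuclear texture feeds
a granule classifier; separate confocal experiments measure molecular
mobility inside granules (FRAP) and protein turnover (optical pulse
labeling of a photoconvertible tag).

Two features of this design drive most modeling choices. First, death
is only *observed at frames*: a cell that dies between day 3 and day 4
is recorded at day 4, so event times are interval-censored onto the
imaging grid and tied en masse — the Cox fits therefore always use the
Efron tie correction. Second, every quantity is per-cell, so covariate
effects (expression level, expression change, granule state) can be
modeled at single-cell resolution rather than per-well.

## Imaging stages

**Segmentation.** Per-frame Otsu thresholding of the morphology
channel, connected-component labeling, and filtering by pixel area
(defaults 20–5000 px at the simulated scale) and solidity (≥ 0.3,
which removes threads and merged debris but keeps somata with attached
neurite stubs). Otsu is recomputed per frame so slow photobleaching
does not drift the threshold; an absolute intensity floor can be set
when channels are calibrated. Centroids are reported in 0-based
(x = column, y = row) pixel coordinates.

**Tracking.** Greedy mutual-nearest-centroid linking between
consecutive frames, with candidates admitted within `max_displacement`
(default twice the median equivalent soma radius — post-mitotic neurons
barely move between daily frames) and ties broken by distance then
label. A track may skip `gap_frames` (default 1) frames before it stops
being a linking candidate; skipped frames are omitted from time series,
never interpolated.

**Death calling.** The qualitative criteria — rounding, loss of
fluorescence, degeneration — become three ordered rules: (a) mean
morphology intensity below `fluorescence_floor` (default 0.25) times
its initial value; (b) the ROI vanishes and never reappears; (c)
eccentricity drops by `roundness_jump` (default 0.5, absolute) between
consecutive frames with intensity declining thereafter. When several
rules fire, the highest-precedence rule (a > b > c) sets the death
time. The thresholds are exposed because the published criteria are
qualitative; the defaults were fixed against the forward model below
and not revisited. A track whose last centroid lies within
`edge_margin` pixels of the border is scored "lost" and censored rather
than killed, since leaving the field is not death.

**Registration.** Phase correlation with local upsampled-DFT refinement
(translation; a small-angle rotation grid search is available for
granule FRAP stacks). Shifts are applied through the Fourier shift
theorem, which is exact for the periodic synthetic fields and adequate
for the small drifts seen in practice.

## Survival models

`fit_cox` wraps the standard Cox partial-likelihood machinery
(`survival::coxph`, Efron ties) — this is deliberately *bought*, not
re-implemented: it is the field's reference implementation, and the
test suite instead checks it against an independent exhaustive grid
maximization of the hand-written Efron partial likelihood on small
datasets.

The smooth-risk model is implemented in the package because its
internals matter here. The log relative hazard is a cubic B-spline
expansion of the covariate with 8 interior knots at covariate
quantiles, fitted by Newton–Raphson with step halving (convergence
|Δβ| < 1e-8, ≤ 100 iterations) on the penalized Efron partial
likelihood. The roughness penalty is the exact curvature integral
λ∫f″². Two choices deserve comment:

* **Penalty form.** A coefficient second-*difference* penalty — the
  textbook P-spline choice — has the linear functions in its null space
  only when knots are equally spaced. With knots at quantiles of a
  long-tailed covariate (single-cell expression is roughly log-normal),
  its smooth limit is a distorted monotone curve, which we observed as
  bias and confidence-band undercoverage even for linear truth.
  Equally spaced knots fix the null space but starve the dense data
  region of resolution. The curvature-integral (O'Sullivan) penalty
  keeps quantile knots *and* an exactly linear null space for any knot
  layout, so it is what the package uses. The covariate is affinely
  mapped to [0, 1] internally so the λ grid (30 log-spaced values,
  10⁻² to 10⁶) has a fixed scale.
* **Effect test.** λ is chosen by AIC (−2·loglik + 2·edf, with
  edf = tr[(H + λP)⁻¹H]). Referring the likelihood-ratio statistic at
  the chosen λ to χ²(edf) ignores that selection and is markedly
  anti-conservative. The package instead tests the selected AIC
  advantage, T = maxλ [LRT(λ) − 2·edf(λ)], against its null
  distribution, simulated in the whitened information/penalty
  eigenbasis where LRT(λ) = Σ ρᵢ(2 − ρᵢ)zᵢ² and edf(λ) = Σ ρᵢ with
  ρᵢ = 1/(1 + λsᵢ), z ~ N(0, I). The simulation uses a fixed internal
  seed (4000 draws), so p-values are deterministic and the caller's RNG
  is untouched. The acceptance suite verifies the empirical size at
  α = 0.05 over 200 null cohorts for both the hazard and the onset
  model; the quadratic score approximation leaves a mild residual
  liberality, within the tested band.

Pointwise confidence bands use the Bayesian covariance (H + λP)⁻¹,
which absorbs smoothing bias better than the sandwich form; fitted
curves are reported as deviations from the cohort-average log hazard,
the only scale on which a Cox-model smooth is identified. The binomial
onset model (granule formation by day 3, logit link) shares the basis,
penalty, AIC grid and selection-aware test, with the intercept
unpenalized and profiled out of the test.

## Granule classification

The nuclear CV is the *population* (divide-by-N) standard deviation
over the nuclear ROI divided by its mean — declared explicitly because
with hundreds of pixels the choice is numerically irrelevant but
bit-level reproducibility requires fixing it. CV is invariant to
multiplicative intensity rescaling, which is what makes a single
threshold transferable across acquisition settings. ROC threshold
selection maximizes the Youden index (smallest threshold on ties);
whether the widely used 0.92 operating point was Youden-optimal or
hand-picked from a ROC curve is not documented, so 0.92 ships as the
*classification* default while `build_roc` reports its own optimum. A CV exactly at
threshold classifies granule-positive (≥ rule). Granule-stratified
survival compares each stratum to a pooled copy of the full cohort —
the pooled records are reused in both contrasts, matching how such
comparisons are presented, at the price of non-independent contrasts.

## Kinetics

FRAP normalization follows the integrated-density protocol: the
pre-bleach whole-granule integrated density is the denominator, the
pre-bleach ROI fraction minus its immediate post-bleach value is the
floor, and the floor-subtracted ROI fraction is the recovery, starting
at exactly 0. If the post-bleach fraction does not fall below the
pre-bleach fraction the bleach was ineffective and the function stops.

The recovery fit y(t) = A(1 − e^(−τt)) is nonlinear least squares
(Levenberg–Marquardt) with A bounded to (0, 1.5] and τ > 0,
initialized at A₀ = max(y) and τ₀ from the half-rise time refined by a
log-linear fit over the rising phase only — plateau points carry no
information about τ and wreck a naive log-linear initializer. Four
perturbed starts are tried and the lowest-SSE convergent fit kept;
only if all fail is non-convergence reported. Downstream constants:
t½ = ln 2/τ; D = 0.88 w²/(4 t½) with w² = ROI area/π (the spot-bleach
prefactor is taken at face value — the half-granule geometry only
approximates it, a caveat inherited from the protocol itself);
r = 0.66 M^(1/3) nm with M in kDa (the published worked value,
106.4 kDa → 3.13 nm, anchors the unit convention); and
η = k_B T/(6πDr) with k_B = 1.380649 × 10⁻²³ J/K and T defaulting to
310.15 K (a 37 °C chamber), converted internally to SI. No correction
for acquisition photobleaching is applied by default.

OPL half-lives are ordinary least squares on log intensity vs time;
k = −slope, t½ = ln 2/k. A rising trace yields a `valid = FALSE` flag
rather than a negative half-life.

## The synthetic generator: what it emulates and what it does not

The generator exists so that every stage has ground truth. It renders
anisotropic Gaussian somata (axis ratio 1.8, eccentricity ≈ 0.83) with
thin neurite segments, log-normal expression (median 500 AU,
sdlog 0.6), Gaussian read noise (sd 2% of the typical peak) plus
optional Poisson noise over a constant background, and slow centroid
drift. Death is a proportional-hazards draw (exponential baseline by
default); a dying cell is rendered once as a rounded, dimmed soma at
its death frame and is gone the next — a crisp one-frame forward model
chosen so death-calling is testable, where real deaths smear over
hours. Granule onset is logistic in the day-over-day expression ratio
and monotone once acquired. Annotated nuclear images share a
chromatin-scale texture between classes (so the diffuse class has
realistic nonzero CV) and give granular nuclei puncta whose per-cell
contrast is log-normally dispersed — without that dispersion the
classes separate perfectly and the ROC operating point is
uninformative. FRAP traces default to 1 s sampling over 60 s, keeping
several samples on the rising phase of the reference τ = 0.1 s⁻¹
recovery (a sampling interval of about t½/5 or finer); OPL noise is
multiplicative log-normal so intensities stay positive.

Passing tests on these fields shows the pipeline's logic is correct
under a known forward model. It does *not* establish performance on
real data, where somata are not Gaussian, deaths are gradual, focus
drifts, debris mimics cells, and granules sit inside a structured
nucleoplasm. The thresholds that matter (death rules, area filters, CV
threshold) are therefore all exposed configuration, not constants.

## Problem sizes used by the test and acceptance suites

Cohort-level checks use 1000 cells/arm (tabular) and 10 fields of 50
cells per arm (rendered, 320×320 px, 10 daily frames); calibration
checks use 200 null cohorts of 250–300 cells; Monte-Carlo recovery
checks use 100 traces. These sizes put binomial/standard errors well
inside the asserted bands while keeping the full suite in the tens of
minutes.

## Known limitations

Single-channel Otsu segmentation merges touching somata rather than
splitting them; tracking has no motion model and will swap labels if
cells cross; the death rules assume the morphology marker fills the
cell; the spline effect test's null law is a quadratic (score)
approximation; FRAP modeling is single-exponential with no
reaction–diffusion or 3D-geometry terms; competing risks, time-varying
covariates and frailty are out of scope. The stratified-survival
contrast reuses the pooled cohort and should be read as descriptive,
not as two independent tests.
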