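# lfmkit

Single-cell analysis of longitudinal fluorescence microscopy (LFM)
experiments in primary neurons, of the kind used to ask whether an
overexpressed or depleted RNA-binding protein kills neurons, whether the
intranuclear granules it forms are protective or toxic, and how mobile
the protein is inside those granules. The package is aimed at groups
running automated survival microscopy — repeated imaging of the same
transfected neurons every 24 h for ~10 days — together with confocal
FRAP and optical pulse labeling (OPL) follow-up experiments.

Everything is testable without microscope data: a ground-truthed
synthetic generator renders time-lapse fields of Gaussian-profile
somata (with neurites, death events, and intranuclear puncta), survival
cohorts, annotated nuclear images, FRAP traces and OPL decay curves, so
every stage of the pipeline can be validated against known truth.

## What it computes

**Imaging.** Per-frame soma segmentation (Otsu threshold, size and
solidity filters), greedy nearest-centroid tracking, and automated
death calling from the three live-imaging criteria — loss of
fluorescence (mean intensity below a floor fraction of its initial
value), disappearance of the ROI, and soma rounding (an eccentricity
collapse followed by declining intensity). Rigid-body stack
registration uses phase correlation with subpixel refinement.

**Survival statistics.** Each tracked neuron contributes one record
(time of death in days, or censoring at last observation). Group
effects are hazard ratios HR = exp(β) from a Cox proportional-hazards
model (Efron tie correction; deaths are observed on a daily grid, so
ties are ubiquitous). The relationship between a continuous single-cell
covariate x (e.g. reporter intensity at 24 h) and risk is a penalized
spline: the log relative hazard is a cubic B-spline expansion f(x)
inside the Cox partial likelihood, with a second-order roughness
penalty λ∫f″(x)²dx and λ chosen by AIC over a log-spaced grid. The
covariate-effect p-value accounts for the data-driven choice of λ
(see the methods vignette).

**Granules.** A nuclear coefficient of variation CV = σ/μ of reporter
intensity over the nuclear ROI separates punctate from diffuse cells;
a ROC curve against annotated labels selects the operating threshold
(Youden index), and cells are classified at the published threshold
CV ≥ 0.92 by default. Granule fractions are compared by Fisher's exact
test, granule-onset risk is a penalized-spline logistic model of
expression (or expression ratio), and granule-stratified survival
compares each stratum against the pooled cohort.

**Kinetics.** FRAP recovery is fit to y(t) = A(1 − e^(−τt)); the
half-time is t½ = ln 2 / τ, the diffusion coefficient
D = 0.88 w² / (4 t½) with w² approximated by the bleach-ROI area / π,
and the viscosity follows from Einstein–Stokes, η = k_B T / (6 π D r),
with the Stokes radius r = 0.66 M^(1/3) nm of a globular protein of M
kDa. OPL half-lives come from a log-linear fit of the photoconverted
signal, t½ = ln 2 / k.

**Localization.** Nuclear masking inside the soma ROI,
nucleocytoplasmic mean-intensity ratios (with an unbounded-ratio guard
for background-level cytoplasm), background-subtracted
immunofluorescence with condition fold-changes, and group comparisons
by t-test or one-way ANOVA with Tukey HSD.

## Worked example

```r
library(lfmkit)

# a two-arm experiment at the study's scale: ~1250 neurons per arm,
# 10 days of daily imaging, true hazard ratio 1.48
co <- simulate_survival_cohort(c(1286, 1183),
                               c(egfp = 0, matr3_egfp = log(1.48)),
                               baseline_hazard = 0.08, follow_up = 10,
                               seed = 101)
fit_cox(co$records, reference = "egfp")
#> Cox proportional hazards (Efron ties), reference = egfp (n = 1286, 1548 events total)
#>       group    hr         se        p    n
#>  matr3_egfp 1.494 0.05103988 3.52e-15 1183
```

The hazard ratio of 1.494 says neurons in the tagged-construct arm die
at ~1.5 times the instantaneous rate of controls; the Wald p is the
test of β = log HR = 0.

```r
# classify granule-bearing nuclei at the published CV threshold
cls <- classify_cells(c(rep(1.5, 2081), rep(0.3, 653)), threshold = 0.92)
cls$summary
#>   group n_positive n_total percent
#> 1   all       2081    2734    76.1

# full kinetic report for one bleached granule
tr <- simulate_frap_trace(0.7, 0.02, duration = 600, dt = 5,
                          noise_sd = 0.03, bleach_roi_area_um2 = 0.8,
                          seed = 411)
str(frap_report(tr, M_kda = 106.4), give.attr = FALSE)
#> List of 11
#>  $ A                  : num 0.701
#>  $ tau                : num 0.0192
#>  $ t_half             : num 36.1
#>  ...
#>  $ D_um2_s            : num 0.00155
#>  $ stokes_radius_nm   : num 3.13
#>  $ eta_pa_s           : num 46.8
```

A granule whose bleached half recovers with t½ ≈ 36 s over a 0.8 µm²
ROI has an effective diffusion coefficient of ~1.6 × 10⁻³ µm²/s, which
for a 106.4 kDa protein (Stokes radius 3.13 nm) corresponds to an
internal viscosity of ~47 Pa·s — liquid, but four orders of magnitude
more viscous than water.

The numbered scripts under `analysis/` run the full set of analyses
(simulated cohorts → Cox and spline models → granule classification →
kinetics → end-to-end imaging) and write their tables under `results/`.

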