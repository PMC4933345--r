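---
title: "Size-dependent microvascular entrapment and first-pass cell retention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-dependent microvascular entrapment and first-pass cell retention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icretention)
```

## The scientific problem

When a suspension of donor cells is injected into the coronary arteries,
most of the cells wash straight through the heart and appear in the
coronary effluent within a minute; only a minority lodge in the
microvasculature. The *initial retention rate* — the percentage of
injected cells still in the heart a few minutes after injection — is the
quantity of interest for cell-therapy dosing, and the central empirical
claim this package operationalises is that retention is governed by
passive, mechanical entrapment of cells in vessels narrower than their own
diameter. Coronary capillaries run at roughly 5–7 µm; unfractionated bone
marrow mononuclear cells (BMMNC, median diameter ≈ 7 µm) are retained at
only ~20%, whereas culture-expanded mesenchymal stromal cells (MSC, median
≈ 11.5 µm) are retained at ~78%, and within either population larger
cells are retained preferentially, saturating near 9 µm.

The package implements three estimators of retention plus the generative
model that ties them together:

1. **Effluent arm.** In an ex-vivo perfused heart every millilitre of
   coronary outflow can be collected. The per-minute effluent cell number
   is `mean(concentration reads) × flow volume`, the windowed total is its
   sum over minutes 1..W (W = 5 by default), and

   retention (%) = (injected − total effluent) / injected × 100.

2. **Size-stratified retention.** Automated counters report cell counts in
   1-µm diameter bins. Applying the same subtraction bin by bin to the
   pre-injection and effluent histograms yields a retention rate per
   diameter bin.

3. **Histology arm (stereology).** Labelled cells counted on thin
   cryosections give an areal density (cells/mm²). Dividing by the section
   thickness (mm) converts it to a volumetric density, and multiplying by
   the myocardial volume — heart mass in mg under the 1 mg ≡ 1 mm³ tissue
   density assumption — extrapolates to a whole-heart retained count:

   retained = mean density / 0.0075 × heart mass (mg) for 7.5-µm sections.

## The generative model

The simulator is deliberately minimal: every mechanism it contains is
needed to produce one of the observables above, and nothing else.

**Diameters.** Cell diameters are lognormal. For BMMNC the median is
7.0 µm with log-scale sd 0.14, which reproduces the two facts known about
the population: mean ≈ median ≈ 7.0 µm and fewer than 1% of cells at or
above 10 µm. For MSC the median is 11.5 µm and the log-sd is pinned by the
median/mean pair via `mean = median × exp(σ²/2)`, giving σ ≈ 0.344 for a
mean of 12.2 µm. The true BMMNC distribution is described only
qualitatively (a left-skewed unimodal shape); lognormal is an assumption,
chosen as the standard two-parameter model for positive, right-tailed
size data.

**Entrapment.** A cell of diameter *d* is retained with probability

p(d) = p_max / (1 + exp(−k (d − d50))),

a three-parameter logistic — the minimal monotone, saturating model
consistent with the observed per-bin retention curves. Defaults d50 =
8.5 µm and k = 1 µm⁻¹ place the rise across the capillary calibre range
and the plateau at ≈ 9 µm. The ceiling p_max is not set by hand: it is
calibrated so that the population-average retention E[p(D)], computed by
numerical quadrature over the lognormal density (`expected_retention()`),
equals the target group mean — 0.201 for BMMNC, 0.775 for MSC. Because
E[p(D)] is linear in p_max the calibration is a one-line exact root:
p_max = target / E[logistic]. That yields p_max ≈ 0.874 (BMMNC) and
≈ 0.985 (MSC); a target that would need p_max > 1 is an error, not a
silent clamp. A per-bin lookup table can replace the logistic when a
non-parametric entrapment curve is wanted; `expected_retention()` then
integrates the piecewise-constant curve instead, and constant tables give
back the constant exactly.

**Washout.** Cells that are not entrapped exit with transit time
`U(0, T) + Exp(τ)`: a uniform draw over the T = 20 s injection window plus
a memoryless single-pass transit with mean τ = 15 s. The closed-form
fraction of exiting cells gone by 60 s is

F(60) = 1 − (τ/T) e^(−60/τ) (e^(T/τ) − 1) ≈ 96.2%,

comfortably above the >90% first-minute washout the effluent data show.
Exponential transit is the simplest kinetic consistent with that
observation; `washout_cdf()` exposes the full CDF so Monte-Carlo runs can
be checked against it at any time point.

**Flow.** BMMNC injections leave coronary flow at its baseline
(14 ml/min by default, a typical constant-pressure flow for a ~1.2 g rat
heart). With a non-zero obstruction fraction (the MSC default is 1), flow
drops immediately after injection by `obstruction × retained fraction` of
baseline and recovers exponentially with a 3-minute time constant, which
puts minute-1 flow below half of baseline and restores ≥95% of baseline by
minute 10. Obstruction scaled by the retained fraction is the simplest
quantitative reading of the embolism mechanism; the recorded minute-1
effluent *volume* additionally contains the 3 ml injectate, which the
simulator adds on top of coronary flow when it assembles the effluent
record.

**Measurement noise.** Each concentration is read `n_reads = 3` times
with multiplicative lognormal noise of CV 5% and mean exactly 1
(meanlog = −σ²/2), so the pipeline's retention estimator stays unbiased.
With noise switched off the pipeline recovers the simulator's ground
truth exactly — a property the test suite asserts to machine precision.

**Histology generator.** Given a known retained count, whole-section
counts at the base/mid/apex levels are Poisson with mean
`density × area`, which makes the stereological estimator exactly
unbiased under this sampling. Wall-layer densities are proportional to
the transmural weights 1:2:3 (epicardial : mid-myocardial : endocardial),
normalised to preserve the whole-section mean; the 3:1 endocardial :
epicardial gradient is therefore a model input, reproduced in expectation
by the generator and recovered by `transmural_gradient()`'s two-stage
averaging (within heart across levels, then across hearts). The wall is
treated as three equal-thickness layers, and the mid layer sits midway
between the outer two because only the end-point ratio and a
"progressive increase" are constrained.

## Conventions and numerical choices

* **Bins** are half-open 1-µm intervals [d, d+1) labelled by their lower
  edge; "5–6 µm" means the bin [5, 6). Binning uses `floor(d + 1e-9)` so a
  degenerate distribution at an integer diameter lands in its own bin
  despite `exp(log(7))` rounding just below 7.
* **Median of a binned histogram** is interpolated within the bin
  containing the 50th percentile: `d + (0.5 − F(d))/f`. This makes the
  binned median of the default BMMNC population equal 7.0 µm up to
  Monte-Carlo error, which a mid-point convention would not.
* **Clamping.** Counting noise can push the effluent total above the
  dose, making raw retention negative. Negative values are clamped to 0%
  with a warning, and the raw value is always kept (`retention_pct_raw`,
  attribute `raw`) so that conservation — retained + exited = injected —
  can be checked exactly on the unclamped scale. Per-bin retention clamps
  bin-wise under the same policy, flags zero-injected bins as missing
  rather than dividing by zero, and marks bins with fewer than 100
  injected cells as low-support.
* **Retention denominator.** Total injected cells, not viable cells only;
  viability is carried on `cell_population` as metadata. Background
  red-cell subtraction defaults to off for the same reason: injections
  happen only after background has decayed to negligible levels, and both
  choices keep the estimator free of extra assumptions.
* **Pooled tail retention** (`pooled_retention()`) pools counts before
  dividing; the mean of per-bin percentages would weight a 20-cell bin
  like a 200,000-cell bin.
* **Dose conversion** reports 2 significant figures per artery and 1 for
  the all-artery total (matching how such doses are quoted), with raw
  values alongside.
* **Chunked simulation.** `simulate_run()` processes cells in blocks of
  4×10⁶, accumulating bin and minute tallies, so a 4×10⁷-cell injection
  runs in bounded memory with per-cell semantics unchanged.
* **Seeds.** Every stochastic entry point takes an explicit seed;
  `run_report()` seeds once and draws sequentially, so identical
  configurations are bit-identical.

## What the tests do and do not show

The simulated study uses the original design sizes: 8 hearts per arm,
doses of 1, 8 and 40 ×10⁶ cells, a 5-minute window, 4 hearts in the
histology arm, and 10⁶-cell draws for size-distribution checks; stereology
unbiasedness uses 100 replicate section draws. Monte-Carlo agreement is
asserted within 3 standard errors of the analytic oracles (2 SE for the
stereology bias check), so a green suite means the estimators are
consistent with the generative model at study scale — it cannot certify
the model itself. In particular the generator does not emulate: cell
clumping feeding back into entrapment probability (MSC clumps affect flow
only), cell deformability, pulsatile flow or perfusion-pressure dynamics,
spatially explicit vascular networks, real microscopy images (sections
are count tables; the optional image stage was left out in favour of
exact count-level ground truth), or any biochemical adhesion — surface
markers, when enabled, are assigned independently of diameter precisely
to encode their observed irrelevance. Where a closed form exists (washout
CDF, expected retention, stereological identity) the Monte-Carlo paths are
tested against it rather than against themselves; the first-minute
agreement check uses ground-truth exit times because the measured
fraction is a ratio of noisy totals, whose O(CV²) bias, though far below
any tolerance used here, is not what the closed form describes.

## Limitations

The calibration targets tie p_max to group means measured in one ex-vivo
rat preparation; transferring the calibrated curve to other species,
perfusion pressures or diseased vasculature is an extrapolation. The
lognormal size model and logistic entrapment curve are parametric
conveniences — both can be overridden (any histogram can be analysed; a
retention table can replace the logistic) without touching the
estimators, which are model-free arithmetic on counts.
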