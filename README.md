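# icretention

Quantifying initial donor-cell retention in the heart after intracoronary
injection.

Intracoronary delivery of bone marrow mononuclear cells (BMMNC) or
mesenchymal stromal cells (MSC) is an experimental therapy for heart
failure whose efficacy is capped by how many cells the heart keeps in the
first few minutes. In an ex-vivo (Langendorff) perfused heart every
millilitre of coronary outflow can be collected, so retention is directly
measurable: with per-minute effluent volumes *V_m* (ml/min) and mean
cell-concentration reads *c_m* (cells/ml),

```
retention (%) = (N_inj − Σ_{m=1..5} c_m · V_m) / N_inj × 100
```

This package implements, as a reusable and fully tested R pipeline:

* **Effluent retention** — per-minute effluent cell numbers, 5-minute
  totals, retention rate with an explicit clamping policy, first-minute
  washout fraction, and allometric clinical-to-animal dose scaling
  (a 1×10⁹-cell, 75-kg human single-artery dose ≙ 2.7×10⁶ cells per rat
  coronary artery, 8×10⁶ over all three).
* **Size-stratified retention** — retention per 1-µm diameter bin from
  pre-injection vs effluent size histograms, interpolated medians, pooled
  tail retention.
* **Stereology** — whole-heart retained-cell estimates from labelled-cell
  densities on thin cryosections
  (`retained = density / thickness × heart mass`, 1 mg ≡ 1 mm³) and the
  transmural endocardium:epicardium density gradient.
* **Entrapment simulator** — a mechanistic generator in which lognormal
  cell diameters meet a logistic entrapment probability
  `p(d) = p_max / (1 + exp(−k(d − d50)))`, calibrated analytically so the
  population mean retention hits the observed group means (20.1% BMMNC,
  77.5% MSC); exponential washout (uniform 20-s injection + 15-s mean
  transit), coronary-flow obstruction with recovery for MSC, triplicate
  counter noise, and Poisson section counts with a 1:2:3 transmural
  gradient. Every estimator can be checked against its ground truth.

See `vignettes/entrapment-model.Rmd` for the model, its assumptions and
the numerical conventions.

## Worked example

```r
library(icretention)

# one simulated BMMNC heart at the clinical-equivalent dose
p   <- simulator_params("BMMNC")        # p_max calibrated to 20.1%
sim <- simulate_run(p, dose = 8e6, seed = 11)
analyze_run(sim$run)
#> Retention result (BMMNC, dose 8e+06 cells, 5-min window)
#>   total effluent : 6.147e+06 cells
#>   retention      : 23.2 %
#>   first-minute   : 95.9 % of exited cells

# the same numbers from the shipped CSV (same seed, schema-validated I/O)
csv  <- system.file("extdata", "synthetic_effluent.csv", package = "icretention")
runs <- as_perfusion_runs(read_effluent_csv(csv))
analyze_run(runs$heart1)$retention_pct
#> [1] 23.16488
```

Retention of 23.2% against the analytic expectation of 20.1% (single
hearts scatter by a few points; the 8-heart group mean in the analysis
scripts lands on 20.6 ± 0.8%): the heart
kept about one injected cell in five, and ~96% of the cells it lost were
already in the effluent during the first minute. The full study-scale
analysis lives in `analysis/01_simulate.R` … `05_report.R` — thin,
numbered drivers that write their tables under `results/`. Running them
prints, among other things:

```
BMMNC  retention 20.6 +/- 0.8 % (mean +/- SEM, n = 8); first minute 96.1 %
MSC    retention 77.4 +/- 0.1 % (mean +/- SEM, n = 8); first minute 96.1 %
MSC : BMMNC retention ratio = 3.76-fold
BMMNC  histology retention 21.0 +/- 0.7 % (n = 4 hearts); endo:epi ratio 2.90
```

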