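# Fixture builders shared across the suite.

# Per-minute series with a single exact read per minute (no replicates):
# cells_per_min = conc * flow, so `cells` below is reproduced exactly.
series_from_counts <- function(cells, flow = 10) {
  effluent_series(minute = seq_along(cells),
                  flow_ml_min = flow,
                  conc_cells_ml = cells / flow)
}

# The derived five-minute effluent series that inverts the 20.1% group mean
# at dose 8e6: per-minute cell numbers summing to 6,392,000.
derived_counts <- c(6.0e6, 3.0e5, 5.0e4, 3.0e4, 1.2e4)

make_run <- function(cells = derived_counts, dose = 8e6, type = "BMMNC") {
  perfusion_run(injected_dose = dose, cell_type = type,
                effluent = series_from_counts(cells))
}

# Small, noise-free simulator parameter sets for fast deterministic tests.
quiet_params <- function(cell_type = "BMMNC", ...) {
  simulator_params(cell_type, counter_cv = 0, ...)
}
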