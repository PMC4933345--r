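test_that("synthetic cell populations match the configured size model", {
  p <- simulator_params("BMMNC")
  pop <- sample_population(p, 2e5, seed = 101)
  s <- summarize_sizes(pop$size_histogram)
  expect_equal(s$median, 7.0, tolerance = 0.1 / 7.0)
  tail10 <- sum(pop$size_histogram$count[pop$size_histogram$bin_lower >= 10])
  expect_lt(tail10 / pop$total_count, 0.01)
  # degenerate sigma: every cell in the median's bin
  pd <- simulator_params("BMMNC", size_sigma = 0, entrap_pmax = 0.5)
  popd <- sample_population(pd, 1000, seed = 1)
  expect_equal(nrow(popd$size_histogram), 1L)
  expect_equal(popd$size_histogram$bin_lower, 7L)
  # MSC mean/median pair 12.2 / 11.5
  pm <- simulator_params("MSC")
  popm <- sample_population(pm, 2e5, seed = 102)
  sm <- summarize_sizes(popm$size_histogram)
  expect_equal(sm$mean / sm$median, 12.2 / 11.5, tolerance = 0.02)
})

test_that("quadrature oracle matches constant and simulated retention", {
  # constant entrapment probability via per-bin lookup -> returns it exactly
  pc <- simulator_params("BMMNC",
                         retention_table = data.frame(bin_lower = 0:40,
                                                      prob = 0.3))
  expect_equal(expected_retention(pc), 0.3, tolerance = 1e-9)
  # calibrated defaults hit the configured targets
  pb <- simulator_params("BMMNC")
  expect_equal(expected_retention(pb), 0.201, tolerance = 1e-8)
  pm <- simulator_params("MSC")
  expect_equal(expected_retention(pm), 0.775, tolerance = 1e-8)
  # brute-force Monte-Carlo average agrees with the quadrature within 3 SE
  set.seed(103)
  d <- rlnorm(1e6, log(pb$size_median_um), pb$size_sigma)
  pr <- entrapment_prob(pb, d)
  se <- sd(pr) / sqrt(length(pr))
  expect_lt(abs(mean(pr) - expected_retention(pb)), 3 * se)
})

test_that("entrapment ceiling calibration is exact and bounded", {
  pb <- simulator_params("BMMNC")
  expect_equal(calibrate_pmax(pb, 0.201), pb$entrap_pmax)
  expect_lte(simulator_params("MSC")$entrap_pmax, 1)
  expect_error(calibrate_pmax(pb, 0.5), "unreachable")
  expect_error(calibrate_pmax(pb, 1.2), "\\[0, 1\\]")
})

test_that("degenerate entrapment gives all-or-nothing retention", {
  nothing <- quiet_params(retention_table = data.frame(bin_lower = 0:40,
                                                       prob = 0))
  s0 <- simulate_run(nothing, 5e4, seed = 104)
  expect_equal(analyze_run(s0$run)$retention_pct, 0)
  everything <- quiet_params(retention_table = data.frame(bin_lower = 0:40,
                                                          prob = 1))
  s1 <- simulate_run(everything, 5e4, seed = 105)
  expect_equal(analyze_run(s1$run)$total_effluent, 0)
  expect_equal(analyze_run(s1$run)$retention_pct, 100)
})

test_that("simulated runs conserve cells and reproduce bit-identically", {
  p <- simulator_params("BMMNC")
  s <- simulate_run(p, 1e5, seed = 106)
  expect_identical(s$truth$retained_count + s$truth$exited_count,
                   s$truth$dose)
  expect_equal(sum(s$truth$retained_by_bin$count), s$truth$retained_count)
  expect_equal(sum(s$truth$pre_histogram$count), s$truth$dose)
  s2 <- simulate_run(p, 1e5, seed = 106)
  expect_identical(s, s2)
  rep1 <- run_report("BMMNC", dose = 5e4, n_hearts = 2, seed = 107)
  rep2 <- run_report("BMMNC", dose = 5e4, n_hearts = 2, seed = 107)
  expect_identical(rep1, rep2)
})

test_that("a noiseless pipeline recovers the ground truth exactly", {
  p <- quiet_params()
  s <- simulate_run(p, 2e5, seed = 108)
  res <- analyze_run(s$run)
  expect_equal(res$retention_pct, 100 * s$truth$retained_fraction,
               tolerance = 1e-12)
  expect_equal(res$total_effluent,
               sum(s$truth$exits_by_minute[1:5]), tolerance = 1e-9)
})

test_that("Monte-Carlo retention agrees with the analytic expectation", {
  p <- quiet_params()
  r <- vapply(1:20, function(i)
    analyze_run(simulate_run(p, 5e4, seed = 200 + i)$run)$retention_pct,
    numeric(1))
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 100 * expected_retention(p)), 3 * se)
})

test_that("washout kinetics follow the uniform-plus-exponential model", {
  p <- simulator_params("BMMNC")
  # closed form: > 90% of exiting cells leave within the first minute
  expect_gt(expected_first_minute_pct(p), 90)
  expect_equal(expected_first_minute_pct(p),
               100 * (1 - (15 / 20) * exp(-4) * (exp(20 / 15) - 1)))
  # CDF sanity: 0 at t=0, monotone, piecewise forms agree at t = T
  expect_equal(washout_cdf(0), 0)
  tt <- seq(0, 300, by = 5)
  expect_true(all(diff(washout_cdf(tt)) > 0))
  expect_equal(washout_cdf(20 - 1e-9), washout_cdf(20), tolerance = 1e-6)
  # Monte-Carlo agreement within 3 SE
  q <- quiet_params()
  f <- vapply(1:12, function(i)
    analyze_run(simulate_run(q, 5e4, seed = 300 + i)$run)$first_minute_pct,
    numeric(1))
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - expected_first_minute_pct(q)), 3 * se)
})

test_that("retained fraction is invariant to dose", {
  p <- quiet_params()
  fr <- vapply(c(2e4, 2e5), function(dose)
    simulate_run(p, dose, seed = 109)$truth$retained_fraction, numeric(1))
  expect_equal(fr[1], fr[2], tolerance = 0.05)
  expect_equal(mean(fr), expected_retention(p), tolerance = 0.05)
})

test_that("coronary flow stays at baseline unless cells obstruct it", {
  pb <- simulator_params("BMMNC")
  fb <- simulate_flow(pb, retained_fraction = 0.2)
  expect_true(all(fb$flow_ml_min == pb$baseline_flow_ml_min))
  pm <- simulator_params("MSC")
  fm <- simulate_flow(pm, retained_fraction = 0.775)
  expect_lt(fm$flow_ml_min[1], 0.5 * pm$baseline_flow_ml_min)
  expect_gte(fm$flow_ml_min[10], 0.95 * pm$baseline_flow_ml_min)
  expect_true(all(diff(fm$flow_ml_min) > 0))
  # zero obstruction reduces the MSC model to the BMMNC one
  pm0 <- simulator_params("MSC", obstruction_fraction = 0)
  fm0 <- simulate_flow(pm0, retained_fraction = 0.775)
  expect_true(all(fm0$flow_ml_min == pm0$baseline_flow_ml_min))
})

test_that("the minute-1 effluent volume carries the injectate", {
  p <- quiet_params()
  s <- simulate_run(p, 1e4, seed = 110)
  pm <- per_minute_cells(s$run$effluent)
  expect_equal(pm$flow_ml_min[1],
               p$baseline_flow_ml_min + p$injection_volume_ml)
  expect_true(all(pm$flow_ml_min[-1] == p$baseline_flow_ml_min))
})

test_that("simulated sections reflect the stereological identity", {
  p <- simulator_params("BMMNC")
  # zero retained cells -> all section counts zero
  h0 <- simulate_sections(p, 0, injected_dose = 8e6, seed = 111)
  expect_true(all(h0$sections$labeled_cells == 0))
  # retained 1.48e6 at 1242 mg -> expected density ~8.94 cells/mm2
  reps <- vapply(1:60, function(i) {
    h <- simulate_sections(p, 1.48e6, heart_mass_mg = 1242,
                           injected_dose = 8e6, seed = 400 + i)
    whole_heart_estimate(h)$mean_density
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 1.48e6 / 1242 * 0.0075), 3 * se)
  expect_error(simulate_sections(p, -5, injected_dose = 8e6), ">= 0")
  expect_error(simulate_sections(p, 10, heart_mass_mg = 0,
                                 injected_dose = 8e6), "> 0")
})

test_that("transmural weights set the expected layer gradient", {
  p <- simulator_params("BMMNC")
  sec <- do.call(rbind, lapply(1:80, function(i) {
    h <- simulate_sections(p, 5e5, injected_dose = 8e6, seed = 500 + i)
    df <- as.data.frame(h$sections)
    df$heart_id <- paste0("h", i)
    df
  }))
  g <- transmural_gradient(sec)
  expect_equal(as.numeric(g$endo_epi_ratio), 3.0, tolerance = 0.1)
})

test_that("surface-marker fractions are size-neutral in expectation", {
  mf <- c(pos = 0.3, neg = 0.7)
  p <- quiet_params(marker_fractions = mf)
  pre <- eff <- c(pos = 0, neg = 0)
  for (i in 1:30) {
    s <- simulate_run(p, 2e4, seed = 900 + i)
    pre <- pre + s$truth$marker_pre
    eff <- eff + s$truth$marker_effluent
  }
  expect_equal(pre / sum(pre), mf, tolerance = 0.02)
  expect_equal(eff / sum(eff), pre / sum(pre), tolerance = 0.02)
  # off by default
  expect_null(simulate_run(quiet_params(), 100, seed = 1)$truth$marker_pre)
  expect_error(quiet_params(marker_fractions = c(a = 0.5, b = 0.6)),
               "sum to 1")
})

test_that("invalid parameters are rejected", {
  expect_error(simulator_params("BMMNC", size_median_um = -1), "> 0")
  expect_error(simulator_params("BMMNC", entrap_pmax = 1.5), "\\[0, 1\\]")
  expect_error(simulator_params("BMMNC", transit_tau_s = 0), "> 0")
  expect_error(simulator_params("BMMNC", counter_cv = -0.1), ">= 0")
  expect_error(simulator_params("BMMNC", dead_cell_fraction = 2), "\\[0, 1\\]")
  expect_error(simulator_params("BMMNC",
                                retention_table = data.frame(bin_lower = 1:3,
                                                             prob = c(0.1, 2, 0.3))),
               "\\[0, 1\\]")
})
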