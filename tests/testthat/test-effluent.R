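test_that("effluent cell number combines reads, flow and background", {
  expect_equal(effluent_cell_number(c(1000, 1000, 1000), 10), 10000)
  expect_equal(effluent_cell_number(c(900, 1000, 1100), 10), 10000)
  expect_warning(
    v <- effluent_cell_number(5000, 12.5, background = 1e4),
    "background")
  expect_equal(as.numeric(v), 52500)
  # background subtraction floors at zero
  expect_warning(z <- effluent_cell_number(10, 1, background = 1e4))
  expect_equal(as.numeric(z), 0)
  # median aggregation resists one aberrant read
  expect_equal(effluent_cell_number(c(1000, 1000, 4000), 10,
                                    aggregate = "median"), 10000)
  expect_error(effluent_cell_number(numeric(0), 10), "at least one")
  expect_error(effluent_cell_number(c(-5, 10), 10), ">= 0")
})

test_that("windowed effluent totals demand a complete window", {
  const <- series_from_counts(rep(1e5, 5))
  expect_equal(total_effluent(per_minute_cells(const)), 5e5)
  pm <- per_minute_cells(series_from_counts(derived_counts))
  expect_equal(total_effluent(pm, 5), 6392000)
  expect_equal(total_effluent(per_minute_cells(series_from_counts(rep(0, 5)))), 0)
  gap <- pm[pm$minute != 3, ]
  expect_error(total_effluent(gap, 5), "minute\\(s\\) 3")
})

test_that("retention rate follows the effluent formula with clamping", {
  expect_equal(as.numeric(retention_rate(8e6, 6392000)), 20.1)
  expect_equal(as.numeric(retention_rate(5e6, 0)), 100)
  expect_equal(as.numeric(retention_rate(5e6, 5e6)), 0)
  expect_error(retention_rate(0, 100), "positive")
  # effluent above dose: clamped to 0 with a warning, raw value preserved
  expect_warning(r <- retention_rate(1e6, 1.2e6), "clamped")
  expect_equal(as.numeric(r), 0)
  expect_equal(attr(r, "raw"), -20)
  expect_true(attr(r, "clamped"))
  raw <- retention_rate(1e6, 1.2e6, clamp = FALSE)
  expect_equal(as.numeric(raw), -20)
})

test_that("first-minute fraction handles ordinary, total and empty washout", {
  pm <- per_minute_cells(series_from_counts(derived_counts))
  expect_equal(as.numeric(first_minute_fraction(pm)), 6.0e6 / 6.392e6 * 100)
  all1 <- per_minute_cells(series_from_counts(c(1e5, 0, 0, 0, 0)))
  expect_equal(as.numeric(first_minute_fraction(all1)), 100)
  unif <- per_minute_cells(series_from_counts(rep(2e4, 5)))
  expect_equal(as.numeric(first_minute_fraction(unif)), 20)
  none <- per_minute_cells(series_from_counts(rep(0, 5)))
  expect_true(is.na(first_minute_fraction(none)))
  expect_true(attr(first_minute_fraction(none), "undefined"))
})

test_that("conservation and monotonicity hold for arbitrary series", {
  set.seed(42)
  for (i in 1:25) {
    cells <- rexp(5, 1e-5) * c(20, 1, 0.3, 0.1, 0.05)
    dose <- sum(cells) * runif(1, 0.8, 2)
    pm <- per_minute_cells(series_from_counts(cells))
    tot <- total_effluent(pm)
    # retained (unclamped) + exited == injected, exactly
    raw <- attr(retention_rate(dose, tot, clamp = FALSE), "raw")
    expect_equal(dose * (1 - raw / 100), tot, tolerance = 1e-12)
    # antitone in the effluent total at fixed dose
    r2 <- retention_rate(dose, tot * 1.1, clamp = FALSE)
    expect_lt(as.numeric(r2), raw)
    # monotone-decreasing series exit at least 1/window of cells in minute 1
    dec <- sort(cells, decreasing = TRUE)
    f <- first_minute_fraction(per_minute_cells(series_from_counts(dec)))
    expect_gte(as.numeric(f), 100 / 5)
  }
})

test_that("analyze_run assembles the full retention result", {
  res <- analyze_run(make_run())
  expect_s3_class(res, "retention_result")
  expect_equal(res$retention_pct, 20.1)
  expect_equal(res$total_effluent, 6392000)
  expect_equal(res$first_minute_pct, 6.0e6 / 6.392e6 * 100)
  expect_false(res$clamped)
  expect_equal(res$retention_pct_raw, res$retention_pct)
})

test_that("clinical doses scale allometrically with reporting precision", {
  d <- convert_clinical_dose(1e9, 75, 0.2, 3)
  expect_equal(d$per_artery, 2.7e6)
  expect_equal(d$total, 8e6)
  expect_equal(d$per_artery_raw, 1e9 * 0.2 / 75)
  ident <- convert_clinical_dose(1e9, 70, 70, 1)
  expect_equal(ident$per_artery, 1e9)
  expect_equal(ident$total_raw, 1e9)
  d2 <- convert_clinical_dose(7.5e8, 75, 0.1, 2)
  expect_equal(d2$per_artery, 1.0e6)
  expect_equal(d2$total_raw, 2.0e6)
  expect_error(convert_clinical_dose(-1, 75, 0.2, 3), "> 0")
  expect_error(convert_clinical_dose(1e9, 0, 0.2, 3), "> 0")
})
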