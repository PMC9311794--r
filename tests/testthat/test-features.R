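baseline_phases <- list(baseline = c(0, 180), effort = c(180, 210))

test_that("baseline reference averages the final 30 s of the baseline", {
  tr <- short_trace(rep(10, 2100), phases = baseline_phases)
  expect_equal(baseline_reference(tr), 10)
  # linear ramp 0 -> 60 over the 180 s baseline at 10 Hz: the half-open
  # window [150, 180) holds samples 150.0..179.9 s, mean value 54.98333...
  t <- seq(0, 209.9, by = 0.1)
  ramp <- pmin(t, 180) / 3
  tr2 <- signal_trace(t, ramp, channel = "x", fs = 10,
                      phases = baseline_phases)
  expect_equal(baseline_reference(tr2), mean(seq(150, 179.9, by = 0.1)) / 3)
  expect_equal(baseline_reference(tr2), 54.98333, tolerance = 1e-6)
})

test_that("a 30 s baseline is averaged whole and shorter ones error", {
  tr <- signal_trace(seq(0, 29.9, by = 0.1), rep(3, 300), channel = "x",
                     phases = list(baseline = c(0, 30)))
  expect_equal(baseline_reference(tr), 3)
  tr_short <- signal_trace(seq(0, 19.9, by = 0.1), rep(3, 200),
                           channel = "x", phases = list(baseline = c(0, 20)))
  expect_error(baseline_reference(tr_short), "20.0 s")
  expect_error(baseline_reference(short_trace(1:10)), "no annotated baseline")
})

test_that("delta_series subtracts the baseline and marks the channel", {
  tr <- short_trace(c(1, 2, 3) * 1.0)
  expect_equal(delta_series(tr, 2)$value, c(-1, 0, 1))
  expect_equal(delta_series(tr, 0)$value, tr$value)
  expect_match(attr(delta_series(tr, 1), "channel"), "^D\\.")
  const <- short_trace(rep(4.5, 5))
  expect_true(all(delta_series(const, 4.5)$value == 0))
  expect_error(delta_series(tr, NaN), "finite")
})

test_that("phase_summary computes peak/mean/min/delta on half-open windows", {
  tr <- short_trace(c(-3, 0, 4), fs = 1, phases = list(eff = c(0, 3)))
  s <- phase_summary(tr, "eff")
  expect_equal(unlist(s), c(peak = 4, mean = 1 / 3, min = -3, delta = 7))
  const <- short_trace(rep(7, 10), fs = 1, phases = list(eff = c(0, 10)))
  expect_equal(unlist(phase_summary(const, "eff")),
               c(peak = 7, mean = 7, min = 7, delta = 0))
  single <- short_trace(c(1, 9, 1), fs = 1, phases = list(mid = c(1, 2)))
  expect_equal(unlist(phase_summary(single, "mid")),
               c(peak = 9, mean = 9, min = 9, delta = 0))
  expect_error(phase_summary(tr, "nope"), "no phase")
  empty <- short_trace(1:5, fs = 1, phases = list(gap = c(4.2, 4.8)))
  expect_error(phase_summary(empty, "gap"), "no samples")
})

test_that("min <= mean <= peak on arbitrary traces", {
  set.seed(3)
  for (i in 1:20) {
    tr <- short_trace(rnorm(50), fs = 1, phases = list(ph = c(0, 50)))
    s <- phase_summary(tr, "ph")
    expect_lte(s$min, s$mean)
    expect_lte(s$mean, s$peak)
  }
})

test_that("extract_features honours the catalogue and reports gaps", {
  cat1 <- tibble::tibble(
    scenario = "AO30", variable = "mTSI_BB", family = "NIRS", muscle = "BB",
    signal = "TSI", aggregation = "mean", phase = "effort")
  phases <- list(baseline = c(0, 180), effort = c(180, 210))
  tsi <- short_trace(rep(66.1, 2100), channel = "TSI_BB", phases = phases)
  expect_warning(row <- extract_features(list(TSI_BB = tsi), cat1),
                 "1 variables")
  expect_equal(row$mTSI_BB, 66.1, tolerance = 1e-9)
  # empty catalogue -> empty one-row table (with the deviation warning)
  expect_warning(empty <- extract_features(list(), cat1[0, ]),
                 "0 variables")
  expect_equal(dim(empty), c(1L, 0L))
  # missing channel named in the error
  expect_error(suppressWarnings(extract_features(list(), cat1)), "TSI_BB")
})

test_that("extraction is order-independent across channels", {
  spec <- tiny_spec(seed = 5)
  coh <- quiet_cohort(spec)
  tr <- generate_raw_traces(coh, subjects = "S01")[["S01"]]
  cat_ex <- scenario_catalogue("AO30")
  scal <- c(as.list(coh$subjects[1, -1]),
            list(RPE = coh$features$AO30$RPE[1]))
  a <- extract_features(tr, cat_ex, scalars = scal)
  b <- extract_features(rev(tr), cat_ex, scalars = scal)
  expect_identical(a, b)
})
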