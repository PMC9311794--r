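# trace synthesis and the round-trip contract with the extraction pipeline

coh1 <- quiet_cohort(tiny_spec(seed = 404, n_subjects = 3))
traces1 <- generate_raw_traces(coh1, subjects = "S02")

test_that("trace synthesis is deterministic and channel-complete", {
  again <- generate_raw_traces(coh1, subjects = "S02")
  expect_identical(traces1, again)
  expect_setequal(names(traces1$S02),
                  c(paste0(rep(c("O2Hb", "HHb", "tHb", "TSI"), 2), "_",
                           rep(c("BB", "VL"), each = 4)),
                    "HR", "SpO2", "lactate", "force", "velocity"))
  expect_error(generate_raw_traces(coh1, subjects = "S99"), "S99")
})

test_that("sampling rates and phase annotations follow the protocol", {
  tr <- traces1$S02
  expect_equal(attr(tr$O2Hb_BB, "fs"), 10)
  expect_equal(attr(tr$HR, "fs"), 1)
  expect_equal(attr(tr$force, "fs"), 1000)
  ph <- attr(tr$O2Hb_BB, "phases")
  expect_equal(ph$baseline, c(0, 180))
  expect_equal(ph$effort[2] - ph$effort[1], 30)
  expect_equal(ph$recovery[2] - ph$recovery[1], 1080)
  # 30 s of force at 1000 Hz
  expect_equal(nrow(tr$force), 30000L)
})

test_that("the lactate series has one rest sample and ten recovery samples", {
  lac <- traces1$S02$lactate
  expect_equal(nrow(lac), 11L)
  base_idx <- physiograph:::phase_index(lac, "baseline")
  rec_idx <- physiograph:::phase_index(lac, "recovery")
  expect_equal(sum(base_idx), 1L)
  expect_equal(sum(rec_idx), 10L)
  rec_t <- lac$time_s[rec_idx]
  expect_equal(diff(rec_t), rep(120, 9))  # every 2 min up to 18 min
})

test_that("force times velocity reproduces the designed power exactly", {
  tr <- traces1$S02
  pw <- power_trace(tr$force, tr$velocity)
  ps <- power_summary(pw, body_mass = coh1$subjects$BM[2])
  lat <- coh1$features$AO30[2, ]
  for (v in c("pP", "mP", "minP", "pP_rel", "mP_rel", "minP_rel", "FI")) {
    expect_equal(ps[[v]], lat[[v]], tolerance = 1e-9, label = v)
  }
})

test_that("zero-noise traces round-trip to the latent features within 1%", {
  # tolerance is 1% of the latent value, with the channel-phase dynamic
  # range as the scale floor for near-zero arbitrary-unit variables
  for (scen in c("AO30", "RECOVERY")) {
    cat_ <- scenario_catalogue(scen)
    feats <- extract_cohort_features(traces1, coh1, cat_)
    lat <- coh1$features[[scen]][2, ]
    for (ri in seq_len(nrow(cat_))) {
      v <- cat_$variable[ri]
      scale_floor <- if (cat_$family[ri] == "NIRS") {
        sig <- cat_$signal[ri]
        mus <- cat_$muscle[ri]
        lat[[paste0("p", sig, "_", mus)]] - lat[[paste0("min", sig, "_", mus)]]
      } else 0
      tol <- 0.01 * max(abs(lat[[v]]), scale_floor)
      expect_lt(abs(feats[[v]][1] - lat[[v]]), tol + 1e-12,
                label = paste(scen, v))
    }
  }
})

test_that("white trace noise perturbs extraction only mildly", {
  spec_noisy <- synthetic_spec(seed = 404, trace_noise_sd = 0.3,
                               n_subjects = 3)
  cohn <- quiet_cohort(spec_noisy)
  trn <- generate_raw_traces(cohn, subjects = "S02")
  cat_ <- scenario_catalogue("AO30")
  feats <- extract_cohort_features(trn, cohn, cat_)
  lat <- cohn$features$AO30[2, ]
  # the filter removes most of the white noise: TSI recovered to < 1%
  expect_lt(abs(feats$mTSI_VL[1] - lat$mTSI_VL) / abs(lat$mTSI_VL), 0.01)
  # raw noisy trace differs from its filtered version
  expect_gt(sd(trn$S02$TSI_VL$value -
                 lowpass_zero_phase(trn$S02$TSI_VL)$value), 0.1)
})

test_that("the pre-activation session realises the shifted mechanics", {
  tr_impa <- generate_raw_traces(coh1, session = "impa", subjects = "S02")
  pw <- power_trace(tr_impa$S02$force, tr_impa$S02$velocity)
  ps <- power_summary(pw, body_mass = coh1$subjects$BM[2])
  expect_equal(ps$mP, coh1$features$IMPA_AO30$mP[2], tolerance = 1e-9)
  expect_gt(ps$mP, coh1$features$AO30$mP[2] * 0.95)
})
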