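test_that("plant_covariance builds identity, blocks and closed hubs", {
  vars <- paste0("v", 1:5)
  spec0 <- synthetic_spec(seed = 1, correlation_blocks = list(),
                          hub_specs = list())
  expect_equal(plant_covariance(spec0, vars), diag(5),
               ignore_attr = TRUE)
  # hub with 3 spokes at r = 0.8, transitive closure: spoke pairs 0.64, PSD
  spec_h <- synthetic_spec(seed = 1, correlation_blocks = list(),
                           hub_specs = list(list(hub = "v1",
                                                 spokes = c("v2", "v3", "v4"),
                                                 r = 0.8)))
  C <- plant_covariance(spec_h, vars)
  expect_equal(C["v1", "v2"], 0.8)
  expect_equal(C["v2", "v3"], 0.64)
  expect_equal(C["v5", "v1"], 0)
  expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
  # block of 2 at r = 0.99
  spec_b <- synthetic_spec(seed = 1, hub_specs = list(),
                           correlation_blocks = list(
                             list(members = c("v1", "v2"), r = 0.99)))
  Cb <- plant_covariance(spec_b, vars)
  expect_equal(Cb["v1", "v2"], 0.99)
  expect_equal(diag(Cb), rep(1, 5), ignore_attr = TRUE)
})

test_that("plant_covariance rejects unknown members and hopeless structures", {
  vars <- paste0("v", 1:9)
  spec_bad <- synthetic_spec(seed = 1, correlation_blocks = list(
    list(members = c("v1", "nope"), r = 0.5)), hub_specs = list())
  expect_error(plant_covariance(spec_bad, vars), "nope")
  # 8 spokes at 0.8 with no closure: min eigenvalue 1 - 0.8*sqrt(8) << 0
  spec_np <- synthetic_spec(seed = 1, correlation_blocks = list(),
                            hub_specs = list(list(hub = "v1",
                                                  spokes = paste0("v", 2:9),
                                                  r = 0.8)))
  expect_error(plant_covariance(spec_np, vars, transitive = FALSE),
               "too far from PSD")
  expect_error(synthetic_spec(seed = 1, correlation_blocks = list(
    list(members = c("v1", "v2"), r = 1))), "\\[0, 1\\)")
  expect_error(synthetic_spec(seed = NULL), "seed")
  expect_error(synthetic_spec(seed = 1, n_subjects = 2), ">= 3")
})

test_that("a mildly non-PSD structure is repaired with a warning", {
  vars <- paste0("v", 1:4)
  spec <- synthetic_spec(seed = 1, correlation_blocks = list(),
                         hub_specs = list(list(hub = "v1",
                                               spokes = c("v2", "v3", "v4"),
                                               r = 0.59)))
  expect_warning(C <- plant_covariance(spec, vars, transitive = FALSE),
                 "repaired")
  expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
  expect_lt(max(abs(C["v1", c("v2", "v3", "v4")] - 0.59)), 0.05)
})

test_that("cohort generation is deterministic and respects the catalogue", {
  spec <- tiny_spec(seed = 101)
  a <- quiet_cohort(spec)
  b <- quiet_cohort(spec)
  expect_identical(a, b)
  expect_setequal(names(a$features),
                  c("AO30", "IMPA_AO30", "RECOVERY", "IMPA_RECOVERY"))
  expect_setequal(setdiff(names(a$features$AO30), "subject_id"),
                  scenario_catalogue("AO30")$variable)
  expect_setequal(setdiff(names(a$features$RECOVERY), "subject_id"),
                  scenario_catalogue("RECOVERY")$variable)
  # same subject ids, identical characteristics in every scenario
  for (scen in names(a$features)) {
    expect_identical(a$features[[scen]]$subject_id, a$subjects$subject_id)
    expect_identical(a$features[[scen]]$BM, a$subjects$BM)
  }
  expect_true(all(a$subjects$BM > 0 & a$subjects$MIP > 0))
  # changing the seed changes the draw
  expect_false(identical(a$features$AO30$mP,
                         quiet_cohort(tiny_spec(seed = 102))$features$AO30$mP))
})

test_that("subjects keep their draws when the cohort grows", {
  small <- quiet_cohort(tiny_spec(seed = 55, n_subjects = 5))
  large <- quiet_cohort(tiny_spec(seed = 55, n_subjects = 9))
  expect_equal(small$features$AO30[1:5, ], large$features$AO30[1:5, ])
})

test_that("cohort features honour the published group scales", {
  # replicate-mean of body mass within 3 SEM of 73.2 kg
  means <- vapply(1:60, function(i) {
    mean(quiet_cohort(tiny_spec(seed = 500 + i))$subjects$BM)
  }, numeric(1))
  expect_lt(abs(mean(means) - 73.2), 3 * 2.0)
  coh <- quiet_cohort(tiny_spec(seed = 77))
  f <- coh$features$AO30
  expect_true(all(f$minP <= f$mP & f$mP <= f$pP))
  expect_true(all(f$minTSI_BB <= f$mTSI_BB & f$mTSI_BB <= f$pTSI_BB))
  expect_equal(f$pP_rel, f$pP / f$BM)
  expect_equal(f$FI, (f$pP - f$minP) / f$pP * 100)
  expect_true(all(abs(f$DHR) <= f$pHR - f$minHR + 1e-9))
})

test_that("planted correlations are recovered at large n", {
  coh <- quiet_cohort(tiny_spec(seed = 31, n_subjects = 500))
  f <- coh$features$AO30
  # mechanical block planted at 0.85 (ordering enforcement perturbs only
  # the rare draws where the triple would invert)
  expect_lt(abs(cor(f$pP, f$mP) - 0.85), 0.05)
  # NIRS stat triple planted at 0.75
  expect_lt(abs(cor(f$pHHb_VL, f$mHHb_VL) - 0.75), 0.05)
  # unrelated variables stay near zero
  expect_lt(abs(cor(f$Age, f$mP)), 0.1)
})

test_that("independent noise dilutes planted correlations toward zero", {
  # a planted pair that no consistency enforcement touches
  blocks <- list(list(members = c("Age@scalar", "MIP@scalar"), r = 0.8))
  clean <- quiet_cohort(synthetic_spec(seed = 31, n_subjects = 300,
                                       correlation_blocks = blocks,
                                       hub_specs = list(),
                                       trace_noise_sd = 0))
  expect_lt(abs(cor(clean$subjects$Age, clean$subjects$MIP) - 0.8), 0.06)
  noisy <- quiet_cohort(synthetic_spec(seed = 31, n_subjects = 300,
                                       correlation_blocks = blocks,
                                       hub_specs = list(),
                                       noise_sd = 3, trace_noise_sd = 0))
  # attenuation by 1/(1 + noise_var) on the standardised scale: 0.8/10
  expect_lt(abs(cor(noisy$subjects$Age, noisy$subjects$MIP)), 0.25)
})

test_that("the IM_PA effect shifts named variables and nothing else", {
  tab <- tibble::tibble(subject_id = as.character(1:5),
                        mP = rep(1706.9, 5), other = rnorm(5))
  expect_identical(apply_impa_effect(tab, list()), tab)
  shifted <- apply_impa_effect(tab, c(mP = 1.11))
  expect_equal(shifted$mP, rep(1894.659, 5), tolerance = 1e-9)
  expect_identical(shifted$other, tab$other)
  expect_identical(shifted$subject_id, tab$subject_id)
  expect_error(apply_impa_effect(tab, c(mP = -1)), "positive")
  expect_error(apply_impa_effect(tab, c(zzz = 1.1)), "zzz")
  expect_error(apply_impa_effect(tab, c(mP = 1.1), noise_sd = 0.1), "seed")
})

test_that("the default effect reproduces the published power ratios", {
  eff <- impa_default_effect()
  expect_equal(unname(eff["mP"]), 1894.0 / 1706.9)
  coh <- quiet_cohort(tiny_spec(seed = 13))
  ctl <- coh$features$AO30
  pre <- coh$features$IMPA_AO30
  expect_gt(mean(pre$mP) / mean(ctl$mP), 1.05)
  # derived mechanics stay consistent after injection
  expect_equal(pre$mP_rel, pre$mP / pre$BM)
  expect_equal(pre$FI, (pre$pP - pre$minP) / pre$pP * 100)
  # untouched families are bit-identical
  expect_identical(pre$mTSI_VL, ctl$mTSI_VL)
  expect_identical(pre$pLac, ctl$pLac)
})
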