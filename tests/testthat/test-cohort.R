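test_that("cohort simulation is deterministic and labels conditions", {
  cfg <- cohort_config(preset = "sham", n_per_group = 2, seed = 7)
  a <- simulate_cohort(cfg, quick_protocol())
  b <- simulate_cohort(cfg, quick_protocol())
  expect_identical(a$truth, b$truth)
  expect_identical(a$sweep_sets[[1]]$voltage, b$sweep_sets[[1]]$voltage)
  expect_equal(nrow(a$truth), 4)
  expect_setequal(unique(a$truth$condition), c("minusMG", "plusMG"))
})

test_that("sham preset shifts the plusMG condition means as configured", {
  cfg <- cohort_config(preset = "sham", n_per_group = 40, seed = 11,
                       jitter_sd = list(Rin_MOhm = 0, tau_m_ms = 0,
                                        rest_mV = 0, Ra_MOhm = 0,
                                        rheobase_pA = 0, gain_hz_per_pA = 0,
                                        VT_mV = 0, peak_mV = 0,
                                        ahp_depth_mV = 0, adapt_rho = 0))
  sim <- simulate_cohort(cfg, quick_protocol())
  tr <- sim$truth
  vt_plus <- mean(tr$VT_mV[tr$condition == "plusMG"])
  vt_minus <- mean(tr$VT_mV[tr$condition == "minusMG"])
  expect_equal(vt_plus - vt_minus, 3)
  g_plus <- mean(tr$gain_hz_per_pA[tr$condition == "plusMG"])
  g_minus <- mean(tr$gain_hz_per_pA[tr$condition == "minusMG"])
  expect_equal(g_plus / g_minus, 0.6)
  d_plus <- mean(tr$ahp_depth_mV[tr$condition == "plusMG"])
  d_minus <- mean(tr$ahp_depth_mV[tr$condition == "minusMG"])
  expect_equal(d_plus - d_minus, 3)
  rh_plus <- mean(tr$rheobase_pA[tr$condition == "plusMG"])
  rh_minus <- mean(tr$rheobase_pA[tr$condition == "minusMG"])
  expect_equal(rh_plus - rh_minus, 25)
})

test_that("tbi preset plants no condition offsets", {
  zero <- list(Rin_MOhm = 0, tau_m_ms = 0, rest_mV = 0, Ra_MOhm = 0,
               rheobase_pA = 0, gain_hz_per_pA = 0, VT_mV = 0, peak_mV = 0,
               ahp_depth_mV = 0, adapt_rho = 0)
  cfg <- cohort_config(preset = "tbi", n_per_group = 3, seed = 1,
                       jitter_sd = zero)
  sim <- simulate_cohort(cfg, quick_protocol())
  tr <- sim$truth
  expect_equal(tr$VT_mV[tr$condition == "plusMG"],
               tr$VT_mV[tr$condition == "minusMG"])
  expect_equal(tr$gain_hz_per_pA[tr$condition == "plusMG"],
               tr$gain_hz_per_pA[tr$condition == "minusMG"])
})

test_that("jittered parameters always satisfy the model invariants", {
  cfg <- cohort_config(preset = "sham", n_per_group = 25, seed = 3)
  sim <- simulate_cohort(cfg, quick_protocol())
  tr <- sim$truth
  expect_true(all(tr$VT_mV < 0))
  expect_true(all(tr$peak_mV > 0))
  expect_true(all(tr$adapt_rho >= 1))
  expect_true(all(tr$gain_hz_per_pA > 0))
  expect_true(all(tr$rheobase_pA >= 50))
})

test_that("cohort_config validates its arguments", {
  expect_error(cohort_config(n_per_group = 0), "n_per_group")
  expect_error(cohort_config(preset = "bogus"))
})
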