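test_that("zero-noise simulation round-trips exactly through AQUA", {
  des <- tiny_design(timepoints_h = 0, sil = c(CYP1A2 = 1000))
  dp <- decay_params("CYP1A2", 20, 0, 0, 21)
  sim <- simulate_quant_experiment(des, dp, zero_noise(), seed = 1)
  q <- quantify_cyp(sim$peak_areas, sim$samples, sim$transitions,
                    des$sil_spike_fmol)
  expect_equal(q$conc_pmol_per_mg, 20, tolerance = 1e-12)
})

test_that("zero-noise decay levels match the closed form at every timepoint", {
  des <- tiny_design(livers = c("L1", "L2", "L3"),
                     timepoints_h = c(0, 24, 48), sil = c(CYP3A29 = 1000))
  # lag 6 h with 50% remaining at 24 h => k = ln2 / 18
  dp <- decay_params("CYP3A29", 30, lag_h = 6,
                     decay_rate_per_h = log(2) / 18, temperature_C = 21)
  sim <- simulate_quant_experiment(des, dp, zero_noise(), seed = 3)
  q <- quantify_cyp(sim$peak_areas, sim$samples, sim$transitions,
                    des$sil_spike_fmol)
  rel48 <- q$conc_pmol_per_mg[q$time_h == 48] / q$conc_pmol_per_mg[q$time_h == 0]
  expect_equal(unique(round(rel48, 12)),
               round(exp(-log(2) / 18 * 42), 12))
  expect_equal(unique(q$conc_pmol_per_mg[q$time_h == 24] /
                        q$conc_pmol_per_mg[q$time_h == 0]), 0.5,
               tolerance = 1e-12)
})

test_that("identical seeds give identical tables, different seeds differ", {
  des <- tiny_design(livers = c("L1", "L2"))
  dp <- decay_params("CYP1A2", 20, 24, 0.03, 21)
  nm <- noise_model(0.1, 0.1, 0.05)
  s1 <- simulate_quant_experiment(des, dp, nm, seed = 11)
  s2 <- simulate_quant_experiment(des, dp, nm, seed = 11)
  s3 <- simulate_quant_experiment(des, dp, nm, seed = 12)
  expect_identical(s1$peak_areas, s2$peak_areas)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$peak_areas$area, s3$peak_areas$area))

  v1 <- simulate_validation_experiment(10, 5, 3, 3, nm, seed = 2)
  v2 <- simulate_validation_experiment(10, 5, 3, 3, nm, seed = 2)
  expect_identical(v1, v2)

  a1 <- simulate_activity_experiment(des, decay_params("P", 1000, 0, 0.1, 21),
                                     nm, seed = 5, calib_top_uM = c(P = 20))
  a2 <- simulate_activity_experiment(des, decay_params("P", 1000, 0, 0.1, 21),
                                     nm, seed = 5, calib_top_uM = c(P = 20))
  expect_identical(a1, a2)
})

test_that("missing decay parameters are a configuration error", {
  des <- tiny_design(temperatures_C = c(4, 21))
  dp <- decay_params("CYP1A2", 20, 24, 0.03, 21)  # no 4 C entry
  expect_error(simulate_quant_experiment(des, dp, zero_noise(), seed = 1),
               "missing decay parameters")
})

test_that("heavy areas carry within-run noise only", {
  des <- tiny_design(livers = c("L1", "L2"), timepoints_h = c(0, 24))
  dp <- decay_params("CYP1A2", 20, 0, 0.05, 21)
  nm <- noise_model(between_liver_cv = 0.5, between_run_cv = 0.5,
                    within_run_cv = 0)
  sim <- simulate_quant_experiment(des, dp, nm, seed = 9)
  heavy <- sim$peak_areas$area[sim$peak_areas$label == "heavy"]
  # with zero within-run CV the heavy channel is exactly the base area
  expect_true(all(heavy == heavy[1]))
})

test_that("validation simulation realizes its variance components", {
  # zero noise: all replicates identical, estimated CVs zero
  v <- simulate_validation_experiment(50, n_days = 3, reps_per_day = 3,
                                      noise = zero_noise(), seed = 1)
  expect_true(all(v$value == 50))
  pc <- precision_components(v$value + c(0, 1e-9, rep(0, 7)), v$day_id)
  expect_lt(pc$within_run_cv_pct, 1e-6)

  # spiked condition shifts the pre-noise level by the spike
  v2 <- simulate_validation_experiment(50, spike_fmol = 10, n_days = 2,
                                       reps_per_day = 3,
                                       noise = zero_noise(), seed = 1)
  expect_equal(mean(v2$value[v2$condition == "spiked"]) -
                 mean(v2$value[v2$condition == "unspiked"]), 10)
  expect_equal(trueness_percent(v2$value[v2$condition == "spiked"],
                                v2$value[v2$condition == "unspiked"], 10), 100)
})

test_that("realized layer CVs match their specification over many replicates", {
  nm <- noise_model(between_run_cv = 0.1, within_run_cv = 0.05)
  # 1500 days x 2 reps in one simulated experiment: the within-run CV is
  # read from replicate differences, the between-run CV from day means
  v <- simulate_validation_experiment(100, n_days = 1500, reps_per_day = 2,
                                      noise = nm, seed = 42)
  pc <- precision_components(v$value, v$day_id)
  expect_equal(pc$within_run_cv_pct, 5, tolerance = 0.1)
  expect_equal(pc$between_run_cv_pct, 10, tolerance = 0.1)
})

test_that("activity simulation embeds the unit-faithful metabolite concentration", {
  # 3800 pmol/min/mg over 20 min at 1 mg/ml accumulates 76 uM metabolite
  des <- tiny_design(timepoints_h = 0)
  dp <- decay_params("CYP1A-phenacetin", 3800, 0, 0, 21)
  sim <- simulate_activity_experiment(des, dp, zero_noise(), seed = 1,
                                      calib_top_uM = c("CYP1A-phenacetin" = 20),
                                      response_slope = 0.1,
                                      response_intercept = 0,
                                      time_min = 20, plm_mg_per_ml = 1,
                                      dilution_factor = 15)
  smp <- sim$samples
  conc_diluted <- smp$analyte_area / smp$is_area / 0.1
  expect_equal(conc_diluted * 15, 76, tolerance = 1e-12)
  # and the full quantification recovers the rate exactly
  act <- quantify_activity(sim$calibrators, sim$samples)
  expect_equal(act$rate_pmol_min_mg, 3800, tolerance = 1e-9)
})

test_that("bradford simulation round-trips at zero noise", {
  bf <- simulate_bradford(c(prep1 = 27.25), slope = 0.5, intercept = 0.05,
                          cv = 0, dilution_factor = 30, seed = 1)
  est <- bradford_concentration(bf$samples$absorbance, bf$standards)
  expect_equal(est$conc_mg_ml * 30, 27.25, tolerance = 1e-9)
})
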