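test_that("par_response is the light/heavy area ratio", {
  expect_identical(par_response(1500, 1500), 1)
  expect_identical(par_response(0, 1500), 0)
  expect_equal(par_response(2903.4, 1000), 2.9034)
  expect_error(par_response(100, 0), "internal standard")
  expect_error(par_response(-1, 100), "non-negative")
})

make_single_sample <- function(light, heavy, plm_ug = 70, qual = NULL) {
  tr <- default_transitions()
  tr <- tr[tr$protein_id == "CYP1A2", ]
  areas <- tibble::tibble(
    sample_id = "s1",
    transition_id = c("CYP1A2_quant_light", "CYP1A2_quant_heavy"),
    area = c(light, heavy))
  samples <- tibble::tibble(sample_id = "s1", plm_mass_ug = plm_ug)
  list(areas = areas, samples = samples, transitions = tr)
}

test_that("quantify_cyp applies the AQUA equations", {
  # PAR 1.0 with 1000 fmol SIL in 70 ug: 1 pmol peptide, 14.29 pmol/mg
  d <- make_single_sample(1000, 1000)
  q <- quantify_cyp(d$areas, d$samples, d$transitions, c(CYP1A2 = 1000))
  expect_equal(q$signature_pmol, 1)
  expect_equal(q$conc_pmol_per_mg, 1 / 0.07)
  expect_equal(round(q$conc_pmol_per_mg, 2), 14.29)

  # PAR 1.512 reproduces the 21.6 pmol/mg magnitude
  d <- make_single_sample(1512, 1000)
  q <- quantify_cyp(d$areas, d$samples, d$transitions, c(CYP1A2 = 1000))
  expect_equal(round(q$conc_pmol_per_mg, 1), 21.6)

  # absent analyte: zero concentration, flagged below the detection limit
  d <- make_single_sample(0, 1000)
  q <- quantify_cyp(d$areas, d$samples, d$transitions, c(CYP1A2 = 1000))
  expect_equal(q$conc_pmol_per_mg, 0)
  expect_equal(q$flag, "below_lod")

  # lost internal standard invalidates AQUA: flagged, not silently zero
  d <- make_single_sample(500, 0)
  q <- quantify_cyp(d$areas, d$samples, d$transitions, c(CYP1A2 = 1000))
  expect_equal(q$flag, "missing_is")
  expect_true(is.na(q$conc_pmol_per_mg))
})

test_that("quantify_cyp is homogeneous in light area and SIL spike", {
  set.seed(31)
  for (i in 1:10) {
    light <- runif(1, 100, 5000)
    heavy <- runif(1, 500, 2000)
    sil <- runif(1, 200, 3000)
    c_scale <- runif(1, 0.1, 10)
    base <- quantify_cyp(make_single_sample(light, heavy)$areas,
                         make_single_sample(light, heavy)$samples,
                         default_transitions(), c(CYP1A2 = sil))
    d2 <- make_single_sample(light * c_scale, heavy)
    q2 <- quantify_cyp(d2$areas, d2$samples, default_transitions(),
                       c(CYP1A2 = sil))
    expect_equal(q2$conc_pmol_per_mg[q2$protein_id == "CYP1A2"],
                 c_scale * base$conc_pmol_per_mg[base$protein_id == "CYP1A2"])
    q3 <- quantify_cyp(make_single_sample(light, heavy)$areas,
                       make_single_sample(light, heavy)$samples,
                       default_transitions(), c(CYP1A2 = sil * c_scale))
    expect_equal(q3$conc_pmol_per_mg[q3$protein_id == "CYP1A2"],
                 c_scale * base$conc_pmol_per_mg[base$protein_id == "CYP1A2"])
  }
})

test_that("doubling the digested protein mass halves the concentration", {
  d1 <- make_single_sample(1500, 1000, plm_ug = 70)
  d2 <- make_single_sample(1500, 1000, plm_ug = 140)
  q1 <- quantify_cyp(d1$areas, d1$samples, d1$transitions, c(CYP1A2 = 1000))
  q2 <- quantify_cyp(d2$areas, d2$samples, d2$transitions, c(CYP1A2 = 1000))
  expect_equal(q1$conc_pmol_per_mg, 2 * q2$conc_pmol_per_mg)
})

test_that("replicate averaging is order-invariant", {
  des <- tiny_design(timepoints_h = c(0, 24), reps = 3)
  dp <- decay_params("CYP1A2", 20, 0, 0.03, 21)
  sim <- simulate_quant_experiment(des, dp, noise_model(0, 0.1, 0.1), seed = 4)
  q1 <- quantify_cyp(sim$peak_areas, sim$samples, sim$transitions,
                     des$sil_spike_fmol)
  shuffle <- sample(nrow(sim$peak_areas))
  q2 <- quantify_cyp(sim$peak_areas[shuffle, ], sim$samples, sim$transitions,
                     des$sil_spike_fmol)
  expect_equal(q1, q2)
  expect_true(all(q1$n_injections == 3))
})

test_that("bradford_concentration inverts the standard curve", {
  stds0 <- data.frame(conc_mg_ml = c(0.25, 0.5, 1, 2))
  # proportional curve A = 0.5 C
  stds <- transform(stds0, absorbance = 0.5 * conc_mg_ml)
  expect_equal(bradford_concentration(0.25, stds)$conc_mg_ml, 0.5)
  # curve with intercept A = 0.1 + 0.5 C
  stds <- transform(stds0, absorbance = 0.1 + 0.5 * conc_mg_ml)
  expect_equal(bradford_concentration(0.35, stds)$conc_mg_ml, 0.5)
  # replicate absorbances are averaged before inversion
  expect_equal(bradford_concentration(c(0.3, 0.4), stds)$conc_mg_ml, 0.5)
  # degenerate design: one distinct concentration only
  degen <- data.frame(conc_mg_ml = c(1, 1), absorbance = c(0.5, 0.6))
  expect_error(bradford_concentration(0.55, degen), "distinct")
  # out-of-range absorbance flags extrapolation
  expect_warning(out <- bradford_concentration(5, stds), "extrapolated")
  expect_true(out$extrapolated)
})

test_that("MPPGL is the uncorrected protein/tissue quotient", {
  expect_equal(compute_mppgl(5.45, 0.5), 10.9)
  expect_equal(compute_mppgl(7.3, 0.5), 14.6)
  expect_equal(compute_mppgl(0, 0.5), 0)
  expect_error(compute_mppgl(5, 0), "positive")
})

test_that("cross-liver means reproduce the reported averages", {
  expect_equal(round(mean_across_livers(c(21.6, 28.3, 19.9)), 1), 23.3)
  expect_equal(round(mean_across_livers(c(68.5, 50.3, 66.2)), 1), 61.7)
  expect_equal(round(mean_across_livers(c(143, 139, 133)), 1), 138.3)
  expect_error(mean_across_livers(numeric(0)), "non-empty")
})
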