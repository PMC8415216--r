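test_that("normalization divides by each liver's own t = 0 level", {
  d <- data.frame(liver_id = rep(c("L1", "L2"), each = 3),
                  time_h = rep(c(0, 24, 48), 2),
                  value = c(20, 20, 10, 21.6, 19.4, 10.8))
  out <- normalize_to_t0(d, "value", by = "liver_id")
  expect_equal(out$relative[out$liver_id == "L1"], c(1, 1, 0.5))
  expect_equal(out$relative[out$liver_id == "L2"][2], 19.4 / 21.6)
  expect_equal(round(out$relative[out$liver_id == "L2"][2], 3), 0.898)

  # idempotence: normalizing an already-relative series changes nothing
  out2 <- normalize_to_t0(out, "relative", by = "liver_id")
  expect_equal(out2$relative, out$relative)

  # missing or zero baseline is an error naming the series
  expect_error(normalize_to_t0(data.frame(liver_id = "L3", time_h = 24,
                                          value = 5),
                               "value", by = "liver_id"), "L3")
  expect_error(normalize_to_t0(data.frame(liver_id = "L3", time_h = c(0, 24),
                                          value = c(0, 5)),
                               "value", by = "liver_id"), "non-positive")
})

test_that("pooled within-group SD pools sums of squares over timepoints", {
  expect_equal(as.numeric(pooled_within_sd(c(1, 3, 5, 7),
                                           c("a", "a", "b", "b"))),
               sqrt(2))
  expect_equal(as.numeric(pooled_within_sd(c(2, 2, 5, 5),
                                           c("a", "a", "b", "b"))), 0)
  s <- pooled_within_sd(c(2, 4, 6), c("a", "a", "a"))
  expect_equal(as.numeric(s), 2)
  expect_equal(attr(s, "df"), 2)
  expect_error(pooled_within_sd(c(1, 2), c("a", "b")), ">= 2 members")
})

test_that("mean_ci95 uses the Student t quantile on pooled df", {
  # frozen from an independent distribution table: t(0.975, 22) = 2.0739
  ci <- mean_ci95(c(0.8, 0.8, 0.8), pooled_sd = 0.1, df_within = 22)
  expect_equal(round(ci$ci_low, 3), 0.680)
  expect_equal(round(ci$ci_high, 3), 0.920)
  # zero pooled SD collapses the interval onto the mean
  ci0 <- mean_ci95(c(0.7, 0.9), pooled_sd = 0, df_within = 5)
  expect_equal(ci0$ci_low, 0.8)
  expect_equal(ci0$ci_high, 0.8)
  # n = 1: half-width is t * sd
  ci1 <- mean_ci95(0.5, pooled_sd = 0.2, df_within = 10)
  expect_equal(ci1$ci_high - ci1$mean, qt(0.975, 10) * 0.2)
})

test_that("CI half-width shrinks with n and grows with the pooled SD", {
  for (n in 1:4) {
    w1 <- with(mean_ci95(rep(1, n), 0.1, 12), ci_high - ci_low)
    w2 <- with(mean_ci95(rep(1, n + 1), 0.1, 12), ci_high - ci_low)
    expect_lt(w2, w1)
    w3 <- with(mean_ci95(rep(1, n), 0.2, 12), ci_high - ci_low)
    expect_gt(w3, w1)
  }
})

test_that("profiles built from zero-noise decay match the closed form", {
  des <- tiny_design(livers = c("L1", "L2", "L3"),
                     timepoints_h = c(0, 6, 24, 48))
  dp <- decay_params("CYP1A2", 23.3, 0, log(2) / 24, 21)
  sim <- simulate_quant_experiment(des, dp, zero_noise(), seed = 2)
  q <- quantify_cyp(sim$peak_areas, sim$samples, sim$transitions,
                    des$sil_spike_fmol)
  pf <- build_profile(q, "CYP1A2", 21)
  expect_s3_class(pf, "stability_profile")
  expect_equal(pf$summary$mean_relative,
               decay_fraction(c(0, 6, 24, 48), 0, log(2) / 24),
               tolerance = 1e-12)
  expect_equal(pf$summary$mean_relative[pf$summary$time_h == 24], 0.5,
               tolerance = 1e-12)
  # identical livers: degenerate CIs
  expect_equal(pf$pooled_within_sd, 0, tolerance = 1e-12)
  expect_equal(pf$summary$ci_low, pf$summary$ci_high, tolerance = 1e-10)
})

test_that("liver filtering is explicit and recorded", {
  d <- expand.grid(liver_id = c("L1", "L2", "L3"), time_h = c(0, 24),
                   stringsAsFactors = FALSE)
  d$temperature_C <- 4
  d$protein_id <- "CYP2E1"
  d$conc_pmol_per_mg <- c(10, 12, 14, 9, 11, 13)
  pf <- build_profile(d, "CYP2E1", 4, livers = c("L2", "L3"))
  expect_equal(pf$included_livers, c("L2", "L3"))
  expect_equal(unique(pf$per_liver$liver_id), c("L2", "L3"))
  expect_error(build_profile(d, "CYP2E1", 4, livers = "L9"), "no data")
})

test_that("time_to_fraction interpolates the first downward crossing", {
  pf <- data.frame(time_h = c(0, 24, 48), mean_relative = c(1, 1, 0.5))
  expect_equal(time_to_fraction(pf, 0.75), 36)
  # exact hit returns the timepoint itself
  pf2 <- data.frame(time_h = c(0, 24, 48), mean_relative = c(1, 0.5, 0.2))
  expect_equal(time_to_fraction(pf2, 0.5), 24)
  # profiles that never cross are undefined
  pf3 <- data.frame(time_h = c(0, 24), mean_relative = c(1, 0.95))
  expect_true(is.na(time_to_fraction(pf3, 0.5)))
  # first crossing wins on non-monotone profiles
  pf4 <- data.frame(time_h = c(0, 10, 20, 30),
                    mean_relative = c(1, 0.4, 0.8, 0.3))
  expect_equal(time_to_fraction(pf4, 0.5), 10 * (1 - 0.5) / (1 - 0.4))
  expect_error(time_to_fraction(pf, 1.5), "\\(0, 1\\)")
})

test_that("protein and activity profiles compare on shared timepoints", {
  mk <- function(vals, times, analyte) {
    d <- expand.grid(liver_id = c("L1", "L2"), time_h = times,
                     stringsAsFactors = FALSE)
    d$temperature_C <- 21
    d$analyte_id <- analyte
    d$value <- rep(vals, each = 2) * c(1, 1.1)
    build_profile(d, analyte, 21, value_col = "value")
  }
  p <- mk(c(20, 12, 2), c(0, 24, 48), "protein")
  a <- mk(c(30, 15, 0.3), c(0, 24, 48), "activity")
  cmp <- compare_protein_vs_activity(p, a)
  expect_equal(cmp$time_h, c(0, 24, 48))
  expect_equal(cmp$difference, cmp$protein_fraction - cmp$activity_fraction)
  expect_equal(cmp$more_stable[1], "equal")
  # a protein fraction of 0.6 vs 0.02 activity mirrors the robustness gap
  expect_equal(cmp$more_stable[3], "protein")
  # disjoint timepoints cannot arise from build_profile (both series carry
  # t = 0), so exercise the error branch on hand-built profile stubs
  stub <- function(times) structure(
    list(summary = tibble::tibble(time_h = times,
                                  mean_relative = rep(1, length(times)))),
    class = "stability_profile")
  expect_error(compare_protein_vs_activity(stub(c(2, 4)), stub(c(6, 8))),
               "share no timepoints")
})

test_that("lagged-decay fits recover parameters from clean profiles", {
  t <- c(0, 2, 4, 6, 20, 24, 48, 72)
  truth <- decay_fraction(t, lag_h = 24, decay_rate_per_h = log(2) / 24)
  fit <- fit_decay_profile(data.frame(time_h = t, mean_relative = truth))
  expect_equal(fit$lag_h, 24, tolerance = 0.05)
  expect_equal(fit$decay_rate_per_h, log(2) / 24, tolerance = 0.05)
  expect_equal(fit$half_loss_h, 48, tolerance = 0.05)
})

test_that("stability_summary reports fractions and half-loss time", {
  d <- expand.grid(liver_id = c("L1", "L2"), time_h = c(0, 24, 48),
                   stringsAsFactors = FALSE)
  d$temperature_C <- 21
  d$protein_id <- "X"
  d$conc_pmol_per_mg <- rep(c(10, 8, 4), each = 2)
  sm <- stability_summary(build_profile(d, "X", 21))
  expect_equal(sm$fraction_at$fraction, c(1, 0.8, 0.4))
  expect_equal(sm$time_to_half_h, 24 + 24 * (0.8 - 0.5) / (0.8 - 0.4))
})
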