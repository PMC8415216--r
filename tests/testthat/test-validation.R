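test_that("precision components match the hand-computed ANOVA", {
  # day1 = {9, 11}, day2 = {19, 21}: MS_within = 2, MS_between = 100,
  # between-run variance (100 - 2)/2 = 49, total 51, grand mean 15
  pc <- precision_components(c(9, 11, 19, 21), c("d1", "d1", "d2", "d2"))
  expect_equal(pc$grand_mean, 15)
  expect_equal(pc$within_run_cv_pct, 100 * sqrt(2) / 15, tolerance = 1e-12)
  expect_equal(round(pc$within_run_cv_pct, 2), 9.43)
  expect_equal(pc$total_cv_pct, 100 * sqrt(51) / 15, tolerance = 1e-12)
  expect_equal(round(pc$total_cv_pct, 2), 47.61)

  # identical replicates: all CVs zero
  pc0 <- precision_components(rep(5, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(pc0$within_run_cv_pct, 0)
  expect_equal(pc0$total_cv_pct, 0)

  # MS_between < MS_within: between-run variance clamps to zero
  pc_neg <- precision_components(c(10, 20, 14, 16), c("a", "a", "b", "b"))
  expect_equal(pc_neg$between_run_var, 0)
  expect_equal(pc_neg$total_cv_pct, pc_neg$within_run_cv_pct)
})

test_that("precision errors and edge designs behave as specified", {
  expect_error(precision_components(5, "a"), "equal length|two finite")
  # single run: within-run computed, between-run not estimable
  pc1 <- precision_components(c(9, 11, 10), c("a", "a", "a"))
  expect_gt(pc1$within_run_cv_pct, 0)
  expect_true(is.na(pc1$between_run_cv_pct))
  # unbalanced designs use the method-of-moments effective replicate count
  pcu <- precision_components(c(9, 11, 19, 21, 20), c("a", "a", "b", "b", "b"))
  expect_false(pcu$balanced)
  expect_true(is.finite(pcu$total_cv_pct))
})

test_that("precision agrees with a brute-force sums-of-squares oracle", {
  set.seed(123)
  worst <- 0
  for (i in 1:100) {
    a <- sample(2:8, 1)
    n <- sample(2:5, 1)
    vals <- rnorm(a * n, mean = runif(1, 10, 100), sd = runif(1, 0.5, 10))
    run <- rep(paste0("r", seq_len(a)), each = n)
    got <- precision_components(vals, run)
    want <- oracle_anova(vals, run)
    for (pair in list(c(got$within_run_cv_pct, want$within_cv),
                      c(got$between_run_cv_pct, want$between_cv),
                      c(got$total_cv_pct, want$total_cv))) {
      if (pair[2] != 0)
        worst <- max(worst, abs(pair[1] - pair[2]) / abs(pair[2]))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("CV estimates are scale-equivariant, SD-based limits scale", {
  set.seed(5)
  vals <- rnorm(12, 50, 4)
  run <- rep(c("a", "b", "c", "d"), each = 3)
  pc <- precision_components(vals, run)
  pc_scaled <- precision_components(vals * 7, run)
  expect_equal(pc$within_run_cv_pct, pc_scaled$within_run_cv_pct)
  expect_equal(pc$total_cv_pct, pc_scaled$total_cv_pct)

  s <- lod_lloq(vals, 25)
  s_scaled <- lod_lloq(vals * 7, 25)
  expect_equal(s_scaled$sd_fmol, 7 * s$sd_fmol)
  expect_equal(s_scaled$lod_fmol_per_ug, 7 * s$lod_fmol_per_ug)
  expect_equal(s_scaled$replicate_cv_pct, s$replicate_cv_pct)
})

test_that("trueness is recovery relative to the nominal spike", {
  expect_equal(trueness_percent(30, 20, 10), 100)
  expect_equal(trueness_percent(29, 20, 10), 90)
  expect_equal(trueness_percent(31.98, 20, 10), 119.8)
  expect_equal(trueness_percent(c(29, 30, 31), c(19, 20, 21), 10), 100)
  expect_error(trueness_percent(30, 20, 0), "positive")
})

test_that("one-point calibration is proportional through the reference", {
  expect_equal(one_point_calibration(1000, 1000, 17), 17)
  expect_equal(one_point_calibration(500, 1000, 17), 8.5)
  expect_equal(one_point_calibration(0, 1000, 17), 0)
  expect_error(one_point_calibration(100, 0, 17), "positive")
})

test_that("LOD/LLOQ come from the replicate SD with a fixed 10/3 ratio", {
  # identical replicates: zero SD, zero limits
  s0 <- lod_lloq(rep(17, 9), 25)
  expect_equal(s0$lod_fmol_per_ug, 0)
  expect_equal(s0$lloq_fmol_per_ug, 0)

  # sd = 0.7 fmol in 25 ug: LOD 0.084, LLOQ 0.28 fmol/ug
  vals <- 17 + 0.7 * scale(rnorm(9))[, 1]  # exact sample SD 0.7
  s <- lod_lloq(vals, 25)
  expect_equal(s$sd_fmol, 0.7, tolerance = 1e-12)
  expect_equal(s$lod_fmol_per_ug, 0.084, tolerance = 1e-12)
  expect_equal(s$lloq_fmol_per_ug, 0.28, tolerance = 1e-12)

  # the definitional LLOQ/LOD ratio is exactly 10/3
  set.seed(99)
  for (i in 1:20) {
    v <- rnorm(9, 20, runif(1, 0.1, 3))
    r <- lod_lloq(v, runif(1, 5, 100))
    expect_equal(r$lloq_fmol_per_ug / r$lod_fmol_per_ug, 10 / 3)
  }

  # high replicate scatter fails the 20% CV acceptance but is still reported
  noisy <- c(1, 10, 20, 2, 15, 8, 30, 5, 12)
  r <- lod_lloq(noisy, 25)
  expect_false(r$cv_acceptable)
  expect_true(is.finite(r$lod_fmol_per_ug))
  expect_error(lod_lloq(c(1, 2), 25), "at least 3")
})

test_that("day-stratified LOD uses the pooled within-day SD", {
  vals <- c(9, 11, 19, 21)
  day <- c("d1", "d1", "d2", "d2")
  r <- lod_lloq(vals, 10, day = day, stratify_by_day = TRUE)
  expect_equal(r$sd_fmol, sqrt(2), tolerance = 1e-12)
  r_pooled <- lod_lloq(vals, 10)
  expect_gt(r_pooled$sd_fmol, r$sd_fmol)  # day shifts inflate the plain SD
})
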