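# Independent brute-force oracles used to cross-check the package's
# closed-form implementations. These deliberately share no code with the
# functions they verify.

# one-way ANOVA variance components by explicit two-pass sums of squares
# (balanced designs)
oracle_anova <- function(values, run) {
  run <- as.character(run)
  runs <- unique(run)
  a <- length(runs)
  n <- length(values) / a
  grand <- sum(values) / length(values)
  ss_within <- 0
  ss_between <- 0
  for (r in runs) {
    v <- values[run == r]
    m <- sum(v) / length(v)
    ss_within <- ss_within + sum((v - m)^2)
    ss_between <- ss_between + length(v) * (m - grand)^2
  }
  ms_within <- ss_within / (length(values) - a)
  ms_between <- ss_between / (a - 1)
  var_between <- max(0, (ms_between - ms_within) / n)
  list(grand_mean = grand,
       within_cv = 100 * sqrt(ms_within) / grand,
       between_cv = 100 * sqrt(var_between) / grand,
       total_cv = 100 * sqrt(ms_within + var_between) / grand)
}

# weighted least squares line by explicit normal equations
oracle_wls <- function(x, y, w) {
  sw <- sum(w)
  sx <- sum(w * x)
  sy <- sum(w * y)
  sxx <- sum(w * x^2)
  sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / det
  intercept <- (sxx * sy - sx * sxy) / det
  list(slope = slope, intercept = intercept)
}

# zero-noise model shared across round-trip tests
zero_noise <- function() noise_model(0, 0, 0)

# a compact pipeline configuration: fewer timepoints, same structure
small_config <- function(seed = 1, zero_noise = FALSE) {
  cfg <- demo_config(seed = seed)
  cfg$timepoints_h <- list("4" = c(0, 24, 96, 168), "21" = c(0, 24, 48, 72))
  if (zero_noise) {
    cfg$noise <- list(between_liver_cv = 0, between_run_cv = 0,
                      within_run_cv = 0, law = "lognormal")
    cfg$bradford$cv <- 0
  }
  cfg
}

# one-analyte design for compact simulations
tiny_design <- function(livers = "liver1", temperatures_C = 21,
                        timepoints_h = c(0, 24, 48), reps = 2,
                        sil = c(CYP1A2 = 1000)) {
  experiment_design(livers = livers, temperatures_C = temperatures_C,
                    timepoints_h = timepoints_h,
                    technical_replicates = reps,
                    sil_spike_fmol = sil)
}
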