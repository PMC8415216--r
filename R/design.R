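#' Decay parameters for one analyte at one storage temperature
#'
#' Postmortem degradation is modelled as a plateau followed by first-order
#' loss: the analyte is fully stable for `lag_h` hours, after which it decays
#' exponentially at `decay_rate_per_h`. One parameter set describes one
#' analyte (a CYP isoform, an activity pathway, or total microsomal protein)
#' at one storage temperature.
#'
#' @param analyte_id Character, analyte identifier(s) (e.g. `"CYP1A2"`).
#' @param baseline_level Positive numeric, the nondegraded (t = 0) level.
#'   Units are pmol/mg microsomal protein for CYP isoforms,
#'   pmol/min/mg for activity pathways, mg/g liver for MPPGL.
#' @param lag_h Non-negative numeric, hours of full stability before decay
#'   begins.
#' @param decay_rate_per_h Non-negative numeric, first-order rate constant
#'   (per hour) applied after the lag.
#' @param temperature_C Numeric storage temperature in degrees Celsius.
#'
#' @return A tibble with one row per (analyte, temperature) and columns
#'   `analyte_id`, `temperature_C`, `baseline_level`, `lag_h`,
#'   `decay_rate_per_h`. Rows from several calls can be combined with
#'   [dplyr::bind_rows()].
#' @examples
#' decay_params("CYP1A2", baseline_level = 23.3, lag_h = 24,
#'              decay_rate_per_h = log(2) / 24, temperature_C = 21)
#' @export
decay_params <- function(analyte_id, baseline_level, lag_h = 0,
                         decay_rate_per_h = 0, temperature_C = 21) {
  params <- tibble(
    analyte_id = as.character(analyte_id),
    temperature_C = as.numeric(temperature_C),
    baseline_level = as.numeric(baseline_level),
    lag_h = as.numeric(lag_h),
    decay_rate_per_h = as.numeric(decay_rate_per_h)
  )
  if (any(!is.finite(params$baseline_level)) || any(params$baseline_level <= 0))
    stop("`baseline_level` must be positive and finite", call. = FALSE)
  if (any(params$lag_h < 0))
    stop("`lag_h` must be non-negative", call. = FALSE)
  if (any(params$decay_rate_per_h < 0))
    stop("`decay_rate_per_h` must be non-negative", call. = FALSE)
  if (anyDuplicated(params[, c("analyte_id", "temperature_C")]))
    stop("one decay parameter set per (analyte, temperature) is allowed",
         call. = FALSE)
  params
}

#' Fraction of an analyte remaining after postmortem storage
#'
#' Lagged first-order decay: the fraction remaining is 1 up to `lag_h`
#' hours, then `exp(-decay_rate_per_h * (t_h - lag_h))`. The function is
#' continuous in time, non-increasing in time and non-decreasing in the lag.
#'
#' @param t_h Non-negative numeric vector of storage times in hours.
#' @param lag_h Non-negative scalar, hours of full stability.
#' @param decay_rate_per_h Non-negative scalar rate constant (per hour).
#' @return Numeric vector of fractions in (0, 1].
#' @examples
#' decay_fraction(c(0, 24, 48), lag_h = 0, decay_rate_per_h = log(2) / 24)
#' @export
decay_fraction <- function(t_h, lag_h = 0, decay_rate_per_h = 0) {
  if (any(!is.finite(t_h)) || any(t_h < 0))
    stop("`t_h` must be non-negative and finite", call. = FALSE)
  if (length(lag_h) != 1 || lag_h < 0)
    stop("`lag_h` must be a non-negative scalar", call. = FALSE)
  if (length(decay_rate_per_h) != 1 || decay_rate_per_h < 0)
    stop("`decay_rate_per_h` must be a non-negative scalar", call. = FALSE)
  ifelse(t_h <= lag_h, 1, exp(-decay_rate_per_h * (t_h - lag_h)))
}

#' Hierarchical multiplicative noise model
#'
#' Three variance layers mirror the structure of a multi-liver degradation
#' experiment: biological variation between livers, run-to-run (between-day
#' preparation and analysis) variation, and within-run (injection) variation.
#' All layers act multiplicatively on the true level. Under the lognormal
#' law the draw is parameterised so its mean is exactly 1 and its realized
#' coefficient of variation equals the specified CV
#' (`sdlog^2 = log(1 + CV^2)`); under the normal law draws are
#' `Normal(1, CV)`.
#'
#' @param between_liver_cv,between_run_cv,within_run_cv Non-negative
#'   coefficients of variation expressed as fractions (0.07 = 7%). Must lie
#'   in \[0, 5\].
#' @param law `"lognormal"` (default; positive, right-skewed, natural for
#'   peak areas) or `"normal"` multiplicative noise.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(between_liver_cv = 0.15, between_run_cv = 0.12,
#'             within_run_cv = 0.07)
#' zero_noise <- noise_model()
#' @export
noise_model <- function(between_liver_cv = 0, between_run_cv = 0,
                        within_run_cv = 0, law = c("lognormal", "normal")) {
  law <- match.arg(law)
  cvs <- c(between_liver = between_liver_cv, between_run = between_run_cv,
           within_run = within_run_cv)
  if (any(!is.finite(cvs)) || any(cvs < 0) || any(cvs > 5))
    stop("all CVs must be finite fractions in [0, 5]", call. = FALSE)
  structure(
    list(between_liver_cv = between_liver_cv, between_run_cv = between_run_cv,
         within_run_cv = within_run_cv, law = law),
    class = "noise_model"
  )
}

#' @export
print.noise_model <- function(x, ...) {
  cat("<noise_model> law:", x$law, "\n",
      sprintf("  between-liver CV %.1f%%, between-run CV %.1f%%, within-run CV %.1f%%\n",
              100 * x$between_liver_cv, 100 * x$between_run_cv,
              100 * x$within_run_cv))
  invisible(x)
}

# n multiplicative noise draws with mean 1 and coefficient of variation cv
mult_noise <- function(n, cv, law = "lognormal") {
  if (cv == 0) return(rep(1, n))
  if (law == "lognormal") {
    sdlog <- sqrt(log1p(cv^2))
    rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    rnorm(n, mean = 1, sd = cv)
  }
}

#' Layout of a degradation experiment
#'
#' Describes the sampling design: which livers, which storage temperatures,
#' which postmortem timepoints, how many technical replicate injections per
#' digest, how much microsomal protein is digested, and how much of each
#' stable-isotope-labelled internal-standard (SIL-IS) peptide is spiked per
#' digest.
#'
#' Defaults mirror a three-liver design with digests of 70 ug microsomal
#' protein, SIL-IS spikes of 1000 fmol (CYP1A2, CYP2D25, CYP3A29) and
#' 3000 fmol (CYP2E1) per digest, technical duplicate injections, and
#' sampling at t = 0, 2, 4, 6, 20, 24, 48, 72, 96, 120, 144, 168 h.
#'
#' @param livers Character vector of liver identifiers.
#' @param temperatures_C Numeric storage temperatures.
#' @param timepoints_h Non-negative numeric timepoints in hours; must
#'   include 0 and be sorted ascending.
#' @param technical_replicates Positive integer, injections per digest.
#' @param plm_mass_ug_per_digest Positive scalar, microsomal protein (ug)
#'   per digest.
#' @param sil_spike_fmol Named positive numeric vector, SIL-IS spike (fmol)
#'   per quantified protein.
#' @return An object of class `experiment_design`.
#' @examples
#' experiment_design(livers = c("liver1", "liver2"), temperatures_C = 21,
#'                   timepoints_h = c(0, 24, 48))
#' @export
experiment_design <- function(livers = c("liver1", "liver2", "liver3"),
                              temperatures_C = c(4, 21),
                              timepoints_h = c(0, 2, 4, 6, 20, 24, 48, 72,
                                               96, 120, 144, 168),
                              technical_replicates = 2,
                              plm_mass_ug_per_digest = 70,
                              sil_spike_fmol = c(CYP1A2 = 1000, CYP2D25 = 1000,
                                                 CYP2E1 = 3000, CYP3A29 = 1000)) {
  if (length(livers) < 1) stop("at least one liver is required", call. = FALSE)
  if (any(timepoints_h < 0)) stop("timepoints must be non-negative", call. = FALSE)
  if (!0 %in% timepoints_h) stop("timepoints must include t = 0", call. = FALSE)
  if (is.unsorted(timepoints_h, strictly = TRUE))
    stop("timepoints must be sorted ascending without duplicates", call. = FALSE)
  if (technical_replicates < 1 || technical_replicates != round(technical_replicates))
    stop("`technical_replicates` must be a positive integer", call. = FALSE)
  if (plm_mass_ug_per_digest <= 0)
    stop("`plm_mass_ug_per_digest` must be positive", call. = FALSE)
  if (is.null(names(sil_spike_fmol)) || any(names(sil_spike_fmol) == ""))
    stop("`sil_spike_fmol` must be a named vector (one entry per protein)",
         call. = FALSE)
  if (any(sil_spike_fmol <= 0))
    stop("SIL-IS spikes must be positive", call. = FALSE)
  structure(
    list(livers = as.character(livers),
         temperatures_C = as.numeric(temperatures_C),
         timepoints_h = as.numeric(timepoints_h),
         technical_replicates = as.integer(technical_replicates),
         plm_mass_ug_per_digest = as.numeric(plm_mass_ug_per_digest),
         sil_spike_fmol = sil_spike_fmol),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design>\n",
      " livers:", paste(x$livers, collapse = ", "), "\n",
      " temperatures (C):", paste(x$temperatures_C, collapse = ", "), "\n",
      " timepoints (h):", paste(x$timepoints_h, collapse = ", "), "\n",
      " technical replicates:", x$technical_replicates, "\n",
      " PLM per digest (ug):", x$plm_mass_ug_per_digest, "\n",
      " SIL-IS spikes (fmol):",
      paste(names(x$sil_spike_fmol), x$sil_spike_fmol, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
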