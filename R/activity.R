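#' Serial-dilution calibrator concentrations
#'
#' Concentration levels obtained by repeated dilution from a top
#' calibrator: level i (1-based) is `top_uM / factor^(i - 1)`.
#'
#' @param top_uM Positive scalar, highest calibrator concentration (uM).
#' @param n_levels Positive integer number of levels.
#' @param factor Dilution factor per step, > 1 (2 for twofold dilutions).
#' @return Descending numeric vector of length `n_levels`.
#' @examples
#' serial_dilution_levels(20, 15, 2)
#' @export
serial_dilution_levels <- function(top_uM, n_levels, factor = 2) {
  if (!is.finite(top_uM) || top_uM <= 0)
    stop("`top_uM` must be positive", call. = FALSE)
  if (n_levels < 1 || n_levels != round(n_levels))
    stop("`n_levels` must be a positive integer", call. = FALSE)
  if (!is.finite(factor) || factor <= 1)
    stop("`factor` must be > 1", call. = FALSE)
  top_uM / factor^(seq_len(n_levels) - 1)
}

#' Fit a linear calibration curve in response-ratio space
#'
#' Weighted least-squares line of internal-standard response ratio against
#' nominal calibrator concentration. Under `weighting = "1/x"` each point
#' is weighted by the reciprocal of its concentration — the standard choice
#' for calibration ranges spanning several orders of magnitude, where
#' response variance grows with concentration — and zero-concentration
#' points are excluded (their weight is undefined). `weighting = "none"`
#' gives the ordinary unweighted fit.
#'
#' @param levels Data frame with columns `conc_uM` and `response_ratio`
#'   (analyte area / internal-standard area).
#' @param weighting `"1/x"` (default) or `"none"`.
#' @return An object of class `calibration_curve`: a list with `slope`,
#'   `intercept`, `weighting`, `levels` (retained points) and
#'   `excluded` (excluded points, e.g. zeros under 1/x).
#' @examples
#' lv <- data.frame(conc_uM = c(0.5, 1, 2, 4), response_ratio = c(1, 2, 4, 8) / 10)
#' fit_calibration(lv)
#' @export
fit_calibration <- function(levels, weighting = c("1/x", "none")) {
  weighting <- match.arg(weighting)
  levels <- as.data.frame(levels)
  if (!all(c("conc_uM", "response_ratio") %in% names(levels)))
    stop("`levels` needs columns conc_uM and response_ratio", call. = FALSE)
  if (any(!is.finite(levels$conc_uM)) || any(levels$conc_uM < 0))
    stop("calibrator concentrations must be non-negative and finite",
         call. = FALSE)
  excluded <- levels[0, ]
  if (weighting == "1/x") {
    excluded <- levels[levels$conc_uM == 0, ]
    levels <- levels[levels$conc_uM > 0, ]
  }
  if (length(unique(levels$conc_uM)) < 2)
    stop("at least two distinct retained concentrations are required",
         call. = FALSE)
  w <- if (weighting == "1/x") 1 / levels$conc_uM else rep(1, nrow(levels))
  fit <- lm(response_ratio ~ conc_uM, data = levels, weights = w)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         weighting = weighting, levels = as_tibble(levels),
         excluded = as_tibble(excluded)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> response = %.6g + %.6g * conc (weighting: %s, %d levels%s)\n",
              x$intercept, x$slope, x$weighting, nrow(x$levels),
              if (nrow(x$excluded)) paste0(", ", nrow(x$excluded), " excluded")
              else ""))
  invisible(x)
}

#' Back-calculate a metabolite concentration from a calibration curve
#'
#' Inverts the calibration line at the observed response ratio and applies
#' the sample dilution factor:
#' `conc = (response_ratio - intercept) / slope * dilution_factor`.
#' Negative back-calculated concentrations (responses below the intercept,
#' expected from low-end noise) are floored at zero and flagged.
#'
#' @param response_ratio Non-negative numeric vector.
#' @param curve A [fit_calibration()] result (nonzero slope).
#' @param dilution_factor Positive scalar fold-dilution applied to the
#'   sample before measurement.
#' @return A tibble with columns `conc_uM` (in the undiluted reaction
#'   mixture) and `below_range` (`TRUE` where floored).
#' @examples
#' curve <- fit_calibration(data.frame(conc_uM = c(1, 2, 4),
#'                                     response_ratio = c(1, 2, 4)))
#' metabolite_concentration(0.5, curve, dilution_factor = 15)
#' @export
metabolite_concentration <- function(response_ratio, curve, dilution_factor = 1) {
  if (!inherits(curve, "calibration_curve"))
    stop("`curve` must be a calibration_curve", call. = FALSE)
  if (!is.finite(curve$slope) || curve$slope == 0)
    stop("calibration curve has zero slope; cannot invert", call. = FALSE)
  if (!is.finite(dilution_factor) || dilution_factor <= 0)
    stop("`dilution_factor` must be positive", call. = FALSE)
  conc <- (response_ratio - curve$intercept) / curve$slope * dilution_factor
  below <- conc < 0
  conc[below] <- 0
  tibble(conc_uM = conc, below_range = below)
}

#' Metabolite formation rate
#'
#' Converts the metabolite concentration accumulated in the reaction
#' mixture into a specific formation rate:
#' `rate = conc_uM * 1000 / (time_min * plm_mg_per_ml)` in
#' pmol/min/mg microsomal protein, using 1 uM = 1 nmol/ml = 1000 pmol/ml.
#'
#' @param conc_uM Non-negative numeric vector, metabolite concentration in
#'   the (undiluted) reaction mixture.
#' @param time_min Positive scalar reaction time (min).
#' @param plm_mg_per_ml Positive scalar microsomal protein concentration
#'   in the reaction (mg/ml).
#' @return Rates in pmol/min/mg, vectorized over `conc_uM`.
#' @examples
#' formation_rate(76, time_min = 20, plm_mg_per_ml = 1)
#' @export
formation_rate <- function(conc_uM, time_min, plm_mg_per_ml) {
  if (any(!is.finite(conc_uM)) || any(conc_uM < 0))
    stop("`conc_uM` must be non-negative", call. = FALSE)
  if (!is.finite(time_min) || time_min <= 0)
    stop("`time_min` must be positive", call. = FALSE)
  if (!is.finite(plm_mg_per_ml) || plm_mg_per_ml <= 0)
    stop("`plm_mg_per_ml` must be positive", call. = FALSE)
  conc_uM * 1000 / (time_min * plm_mg_per_ml)
}

#' Quantify activity rates from calibrator and sample tables
#'
#' End-to-end probe-substrate activity quantification: fits one
#' calibration curve per analyte from the calibrator table, back-calculates
#' each sample's metabolite concentration (applying its dilution factor),
#' and converts to formation rates.
#'
#' @param calibrators Tibble with columns `analyte_id`, `level_conc_uM`,
#'   `analyte_area`, `is_area`.
#' @param samples Tibble with columns `sample_id`, `analyte_id`,
#'   `analyte_area`, `is_area`, `time_min`, `plm_mg_per_ml`,
#'   `dilution_factor`; extra metadata columns are carried through.
#' @param weighting Calibration weighting, `"1/x"` (default) or `"none"`.
#' @return A tibble with the sample metadata plus `response_ratio`,
#'   `conc_uM`, `below_range` and `rate_pmol_min_mg`.
#' @examples
#' des <- experiment_design(livers = "liver1", temperatures_C = 21,
#'                          timepoints_h = c(0, 24))
#' dp <- decay_params("CYP1A-phenacetin", 3800, 19, 0.13, 21)
#' sim <- simulate_activity_experiment(des, dp, noise_model(), seed = 1,
#'   calib_top_uM = c("CYP1A-phenacetin" = 20))
#' quantify_activity(sim$calibrators, sim$samples)
#' @export
quantify_activity <- function(calibrators, samples,
                              weighting = c("1/x", "none")) {
  weighting <- match.arg(weighting)
  calibrators <- as_tibble(calibrators)
  samples <- as_tibble(samples)
  req_c <- c("analyte_id", "level_conc_uM", "analyte_area", "is_area")
  if (!all(req_c %in% names(calibrators)))
    stop("`calibrators` needs columns: ", paste(req_c, collapse = ", "),
         call. = FALSE)
  req_s <- c("sample_id", "analyte_id", "analyte_area", "is_area", "time_min",
             "plm_mg_per_ml", "dilution_factor")
  if (!all(req_s %in% names(samples)))
    stop("`samples` needs columns: ", paste(req_s, collapse = ", "),
         call. = FALSE)

  out <- lapply(split(samples, samples$analyte_id), function(smp) {
    analyte <- smp$analyte_id[1]
    cal <- calibrators[calibrators$analyte_id == analyte, ]
    if (nrow(cal) < 2)
      stop("no calibrators for analyte ", analyte, call. = FALSE)
    curve <- fit_calibration(
      data.frame(conc_uM = cal$level_conc_uM,
                 response_ratio = cal$analyte_area / cal$is_area),
      weighting = weighting)
    ratio <- par_response(smp$analyte_area, smp$is_area)
    bc <- metabolite_concentration(ratio, curve, dilution_factor = 1)
    conc <- bc$conc_uM * smp$dilution_factor
    smp$response_ratio <- ratio
    smp$conc_uM <- conc
    smp$below_range <- bc$below_range
    smp$rate_pmol_min_mg <- mapply(formation_rate, conc, smp$time_min,
                                   smp$plm_mg_per_ml)
    smp
  })
  arrange(bind_rows(out), .data$analyte_id, .data$sample_id)
}
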