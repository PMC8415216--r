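#' Within-run and between-run precision by one-way ANOVA
#'
#' Variance-component decomposition of replicate measurements grouped by
#' run (day). The within-run variance is the pooled within-run mean square;
#' the between-run variance is `max(0, (MS_between - MS_within) / n0)`
#' where `n0` is the replicates per run (balanced design) or the standard
#' method-of-moments effective replicate count
#' `(N - sum(n_i^2)/N) / (a - 1)` for unbalanced designs. The total
#' variance is their sum, and all components are reported as coefficients
#' of variation relative to the grand mean.
#'
#' A negative moment estimate of the between-run variance (when
#' `MS_between < MS_within`) is clamped to zero, standard
#' variance-components practice. With a single run the between-run and
#' total components are not estimable and are returned as `NA`.
#'
#' @param values Numeric vector of measurements.
#' @param run Vector (same length) identifying the run/day of each value.
#' @return A one-row tibble: `grand_mean`, `within_run_cv_pct`,
#'   `between_run_cv_pct`, `total_cv_pct`, `within_run_var`,
#'   `between_run_var`, `n_runs`, `reps_per_run` (`NA` when unbalanced),
#'   `balanced`.
#' @examples
#' precision_components(c(9, 11, 19, 21), c("d1", "d1", "d2", "d2"))
#' @export
precision_components <- function(values, run) {
  if (length(values) != length(run))
    stop("`values` and `run` must have equal length", call. = FALSE)
  if (length(values) < 2 || any(!is.finite(values)))
    stop("at least two finite measurements are required", call. = FALSE)
  run <- as.character(run)
  ni <- table(run)
  a <- length(ni)
  n_total <- length(values)
  if (all(ni < 2))
    stop("at least one run needs >= 2 replicates to estimate within-run variance",
         call. = FALSE)

  grand_mean <- mean(values)
  run_means <- tapply(values, run, mean)
  ss_within <- sum((values - run_means[run])^2)
  ms_within <- ss_within / (n_total - a)

  balanced <- length(unique(ni)) == 1
  if (a >= 2) {
    ss_between <- sum(ni * (run_means - grand_mean)^2)
    ms_between <- ss_between / (a - 1)
    n0 <- if (balanced) unname(ni[1]) else
      (n_total - sum(ni^2) / n_total) / (a - 1)
    var_between <- max(0, (ms_between - ms_within) / n0)
    var_total <- ms_within + var_between
  } else {
    var_between <- NA_real_
    var_total <- NA_real_
  }

  tibble(
    grand_mean = grand_mean,
    within_run_cv_pct = 100 * sqrt(ms_within) / grand_mean,
    between_run_cv_pct = 100 * sqrt(var_between) / grand_mean,
    total_cv_pct = 100 * sqrt(var_total) / grand_mean,
    within_run_var = ms_within,
    between_run_var = var_between,
    n_runs = a,
    reps_per_run = if (balanced) unname(ni[1]) else NA_integer_,
    balanced = balanced
  )
}

#' Spike-recovery trueness
#'
#' Closeness of agreement between spiked and unspiked replicate
#' measurements, as a percentage of the nominal spike:
#' `100 * (mean(spiked) - mean(unspiked)) / spike_amount`.
#'
#' @param spiked_values,unspiked_values Numeric vectors (>= 1 value each).
#' @param spike_amount Positive scalar, the nominal spiked amount in the
#'   same units as the measurements.
#' @return Trueness in percent (100 = perfect recovery).
#' @examples
#' trueness_percent(c(29, 30, 31), c(19, 20, 21), 10)
#' @export
trueness_percent <- function(spiked_values, unspiked_values, spike_amount) {
  if (length(spiked_values) < 1 || length(unspiked_values) < 1)
    stop("spiked and unspiked values must be non-empty", call. = FALSE)
  if (!is.finite(spike_amount) || spike_amount <= 0)
    stop("`spike_amount` must be positive", call. = FALSE)
  100 * (mean(spiked_values) - mean(unspiked_values)) / spike_amount
}

#' One-point calibration of a peak area
#'
#' Converts a peak area to an amount by proportionality against the mean
#' reference peak area of a known amount:
#' `area / mean_ref_area * ref_amount_fmol`.
#'
#' @param area Non-negative numeric vector of areas to convert.
#' @param mean_ref_area Positive scalar, mean reference peak area.
#' @param ref_amount_fmol Positive scalar, the amount (fmol) the reference
#'   area corresponds to.
#' @return Amounts in fmol, vectorized over `area`.
#' @examples
#' one_point_calibration(500, 1000, 17)
#' @export
one_point_calibration <- function(area, mean_ref_area, ref_amount_fmol) {
  if (any(!is.finite(area)) || any(area < 0))
    stop("`area` must be non-negative", call. = FALSE)
  if (!is.finite(mean_ref_area) || mean_ref_area <= 0)
    stop("`mean_ref_area` must be positive", call. = FALSE)
  if (!is.finite(ref_amount_fmol) || ref_amount_fmol <= 0)
    stop("`ref_amount_fmol` must be positive", call. = FALSE)
  area / mean_ref_area * ref_amount_fmol
}

#' LOD and LLOQ from replicate reactions
#'
#' Estimates the limit of detection as three times, and the lower limit of
#' quantification as ten times, the sample standard deviation of replicate
#' low-level reactions, normalized to the digested microsomal protein mass
#' (fmol per ug). By default the SD pools all replicates regardless of day;
#' `stratify_by_day = TRUE` instead uses the pooled within-day SD (the
#' square root of the pooled within-day mean square).
#'
#' The replicate CV is reported and compared against the 20% acceptance
#' limit; a failing CV flags the result but the estimates are still
#' returned.
#'
#' @param replicate_fmol Numeric vector (>= 3) of replicate amounts (fmol).
#' @param plm_mass_ug Positive scalar, microsomal protein per reaction (ug).
#' @param day Optional vector of day labels (required when
#'   `stratify_by_day = TRUE`).
#' @param stratify_by_day Use the pooled within-day SD instead of the
#'   overall SD.
#' @return A one-row tibble: `sd_fmol`, `lod_fmol_per_ug`,
#'   `lloq_fmol_per_ug`, `replicate_cv_pct`, `cv_acceptable`
#'   (`replicate_cv_pct < 20`), `n_replicates`.
#' @examples
#' lod_lloq(c(16.2, 17.1, 16.8, 17.4, 16.5, 17.0, 16.9, 17.2, 16.6), 25)
#' @export
lod_lloq <- function(replicate_fmol, plm_mass_ug, day = NULL,
                     stratify_by_day = FALSE) {
  if (length(replicate_fmol) < 3 || any(!is.finite(replicate_fmol)))
    stop("at least 3 finite replicate values are required", call. = FALSE)
  if (!is.finite(plm_mass_ug) || plm_mass_ug <= 0)
    stop("`plm_mass_ug` must be positive", call. = FALSE)
  if (stratify_by_day) {
    if (is.null(day) || length(day) != length(replicate_fmol))
      stop("`day` labels are required when `stratify_by_day = TRUE`",
           call. = FALSE)
    s <- as.numeric(pooled_within_sd(replicate_fmol, day))
  } else {
    s <- sd(replicate_fmol)
  }
  cv <- 100 * s / mean(replicate_fmol)
  lod <- 3 * s / plm_mass_ug
  tibble(
    sd_fmol = s,
    lod_fmol_per_ug = lod,
    # defined from the LOD so the 10/3 ratio holds exactly in floating point
    lloq_fmol_per_ug = lod * (10 / 3),
    replicate_cv_pct = cv,
    cv_acceptable = cv < 20,
    n_replicates = length(replicate_fmol)
  )
}
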