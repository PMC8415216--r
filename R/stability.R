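#' Normalize a degradation time series to its t = 0 level
#'
#' Divides each liver's series by that liver's own t = 0 value, giving the
#' fraction of the nondegraded level remaining at each timepoint. When a
#' liver has several t = 0 measurements their mean is used. A liver with a
#' missing or non-positive t = 0 value is an error: without a baseline the
#' relative level is undefined.
#'
#' @param data Data frame with a time column, a value column, and optional
#'   grouping columns (typically the liver id).
#' @param value_col Name of the value column.
#' @param time_col Name of the time column (default `"time_h"`).
#' @param by Character vector of grouping columns (default none: the whole
#'   table is one series).
#' @return The input with an added `relative` column.
#' @examples
#' d <- data.frame(liver_id = "liver1", time_h = c(0, 24, 48),
#'                 conc = c(20, 15, 10))
#' normalize_to_t0(d, "conc", by = "liver_id")
#' @export
normalize_to_t0 <- function(data, value_col, time_col = "time_h", by = NULL) {
  data <- as_tibble(data)
  for (col in c(value_col, time_col, by))
    if (!col %in% names(data))
      stop("column `", col, "` not found", call. = FALSE)
  split_keys <- if (is.null(by)) rep("all", nrow(data)) else
    do.call(paste, c(data[by], sep = "\r"))
  parts <- lapply(split(seq_len(nrow(data)), split_keys), function(idx) {
    chunk <- data[idx, ]
    t0 <- chunk[[value_col]][chunk[[time_col]] == 0]
    label <- if (is.null(by)) "series" else
      paste(unlist(chunk[1, by]), collapse = "/")
    if (length(t0) == 0)
      stop("no t = 0 measurement for ", label, call. = FALSE)
    base <- mean(t0)
    if (!is.finite(base) || base <= 0)
      stop("non-positive t = 0 level for ", label, call. = FALSE)
    chunk$relative <- chunk[[value_col]] / base
    chunk
  })
  out <- bind_rows(parts)
  out[order(match(do.call(paste, c(out[c(by, time_col)], sep = "\r")),
                  do.call(paste, c(data[c(by, time_col)], sep = "\r")))), ]
}

#' Pooled within-group standard deviation (one-way ANOVA)
#'
#' The square root of the pooled within-group mean square,
#' `sqrt(sum(SS_within) / sum(n_i - 1))`, computed over groups (timepoints)
#' under the assumption of equal variance across groups. At least one group
#' must have two or more members.
#'
#' @param values Numeric vector.
#' @param group Vector (same length) of group labels.
#' @return The pooled SD, with the pooled degrees of freedom attached as
#'   attribute `"df"`.
#' @examples
#' pooled_within_sd(c(1, 3, 5, 7), c("a", "a", "b", "b"))
#' @export
pooled_within_sd <- function(values, group) {
  if (length(values) != length(group))
    stop("`values` and `group` must have equal length", call. = FALSE)
  group <- as.character(group)
  ni <- table(group)
  if (all(ni < 2))
    stop("at least one group with >= 2 members is required", call. = FALSE)
  means <- tapply(values, group, mean)
  ss <- sum((values - means[group])^2)
  df <- sum(ni - 1)
  structure(sqrt(ss / df), df = df)
}

#' Mean and ANOVA-pooled 95% confidence interval at one timepoint
#'
#' The 95% CI of the mean of `n` livers at a timepoint,
#' `mean +/- t(0.975, df_within) * pooled_sd / sqrt(n)`, using the pooled
#' within-timepoint SD and its degrees of freedom under the equal-variance
#' assumption. A Student t quantile is used (conservative and standard for
#' n = 2-3 livers).
#'
#' @param group_values Numeric vector of per-liver values at one timepoint.
#' @param pooled_sd Non-negative scalar pooled within-group SD.
#' @param df_within Positive integer degrees of freedom of `pooled_sd`.
#' @return A one-row tibble: `mean`, `ci_low`, `ci_high`.
#' @examples
#' mean_ci95(c(0.7, 0.8, 0.9), pooled_sd = 0.1, df_within = 22)
#' @export
mean_ci95 <- function(group_values, pooled_sd, df_within) {
  if (length(group_values) < 1)
    stop("`group_values` must be non-empty", call. = FALSE)
  if (!is.finite(pooled_sd) || pooled_sd < 0)
    stop("`pooled_sd` must be non-negative", call. = FALSE)
  if (!is.finite(df_within) || df_within < 1)
    stop("`df_within` must be >= 1", call. = FALSE)
  m <- mean(group_values)
  half <- qt(0.975, df_within) * pooled_sd / sqrt(length(group_values))
  tibble(mean = m, ci_low = m - half, ci_high = m + half)
}

#' Build a degradation profile for one analyte at one temperature
#'
#' Composes the relative-to-t0 normalization, the pooled within-timepoint
#' SD, and the ANOVA-pooled 95% CI into a stability profile across livers.
#' Liver inclusion is an explicit caller decision (`livers`), recorded in
#' the result — e.g. excluding a liver whose degradation profile differs
#' from the others — never an automatic outlier rule.
#'
#' Because normalization pins every liver to exactly 1 at t = 0, the t = 0
#' group carries no within-group variance; by default it is therefore
#' excluded from the SD pooling (`include_t0_in_pooling = FALSE`) so that
#' its zero contribution does not deflate the pooled SD.
#'
#' @param data Per-digest results: a tibble with columns `liver_id`,
#'   `temperature_C`, `time_h`, an analyte column (`protein_id`,
#'   `analyte_id` or `pathway`), and the value column.
#' @param analyte Analyte to profile.
#' @param temperature_C Storage temperature to profile.
#' @param value_col Value column; defaults to `conc_pmol_per_mg` when
#'   present, else `rate_pmol_min_mg`, else `value`.
#' @param livers Optional character vector of livers to include (default:
#'   all present).
#' @param include_t0_in_pooling Include the (degenerate) t = 0 groups in
#'   the SD pooling.
#' @return An object of class `stability_profile`: a list with
#'   `analyte_id`, `temperature_C`, `included_livers`, `per_liver` (tibble
#'   of relative values), `summary` (tibble `time_h`, `n`, `mean_relative`,
#'   `ci_low`, `ci_high`), `pooled_within_sd`, `df_within`.
#' @examples
#' d <- expand.grid(liver_id = c("L1", "L2"), time_h = c(0, 24, 48))
#' d$temperature_C <- 21
#' d$protein_id <- "CYP1A2"
#' d$conc_pmol_per_mg <- c(20, 24, 15, 17, 10, 13)
#' build_profile(d, "CYP1A2", 21)
#' @export
build_profile <- function(data, analyte, temperature_C, value_col = NULL,
                          livers = NULL, include_t0_in_pooling = FALSE) {
  data <- as_tibble(data)
  analyte_col <- intersect(c("protein_id", "analyte_id", "pathway"),
                           names(data))[1]
  if (is.na(analyte_col))
    stop("`data` needs an analyte column (protein_id, analyte_id or pathway)",
         call. = FALSE)
  if (is.null(value_col))
    value_col <- intersect(c("conc_pmol_per_mg", "rate_pmol_min_mg", "value"),
                           names(data))[1]
  if (is.na(value_col) || !value_col %in% names(data))
    stop("no value column found", call. = FALSE)
  for (col in c("liver_id", "temperature_C", "time_h"))
    if (!col %in% names(data))
      stop("`data` needs column ", col, call. = FALSE)

  d <- data[data[[analyte_col]] == analyte &
              data$temperature_C == temperature_C, ]
  if (!is.null(livers)) d <- d[d$liver_id %in% livers, ]
  if (nrow(d) == 0)
    stop("no data for ", analyte, " at ", temperature_C,
         "C after liver filtering", call. = FALSE)
  included <- sort(unique(d$liver_id))

  # one value per liver x timepoint (average residual replicates)
  d <- d |>
    group_by(.data$liver_id, .data$time_h) |>
    summarise(value = mean(.data[[value_col]]), .groups = "drop")

  rel <- normalize_to_t0(d, "value", by = "liver_id")

  pool <- if (include_t0_in_pooling) rel else rel[rel$time_h > 0, ]
  psd <- pooled_within_sd(pool$relative, pool$time_h)
  df <- attr(psd, "df")

  summary <- rel |>
    group_by(.data$time_h) |>
    summarise(n = n(), mean_relative = mean(.data$relative),
              .groups = "drop") |>
    arrange(.data$time_h)
  half <- qt(0.975, df) * as.numeric(psd) / sqrt(summary$n)
  summary$ci_low <- summary$mean_relative - half
  summary$ci_high <- summary$mean_relative + half

  structure(
    list(analyte_id = analyte, temperature_C = temperature_C,
         included_livers = included,
         per_liver = rel[, c("liver_id", "time_h", "value", "relative")],
         summary = summary,
         pooled_within_sd = as.numeric(psd), df_within = df),
    class = "stability_profile"
  )
}

#' @export
print.stability_profile <- function(x, ...) {
  cat(sprintf("<stability_profile> %s at %g C (livers: %s)\n", x$analyte_id,
              x$temperature_C, paste(x$included_livers, collapse = ", ")))
  cat(sprintf("  pooled within-timepoint SD %.4g on %d df\n",
              x$pooled_within_sd, x$df_within))
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' Interpolated time to reach a target fraction of the t = 0 level
#'
#' Scans the mean relative profile for the first downward crossing of the
#' target fraction and interpolates linearly between the bracketing
#' timepoints; an exact hit returns that timepoint. Returns `NA` when the
#' profile never reaches the target.
#'
#' @param profile A [build_profile()] result, or a data frame with columns
#'   `time_h` and `mean_relative`.
#' @param target_fraction Scalar in (0, 1), e.g. 0.5 for the half-loss
#'   time.
#' @return Time in hours, or `NA_real_`.
#' @examples
#' time_to_fraction(data.frame(time_h = c(0, 24, 48),
#'                             mean_relative = c(1, 1, 0.5)), 0.75)
#' @export
time_to_fraction <- function(profile, target_fraction) {
  if (!is.finite(target_fraction) || target_fraction <= 0 ||
      target_fraction >= 1)
    stop("`target_fraction` must lie in (0, 1)", call. = FALSE)
  s <- if (inherits(profile, "stability_profile")) profile$summary else
    as.data.frame(profile)
  if (!all(c("time_h", "mean_relative") %in% names(s)))
    stop("profile needs `time_h` and `mean_relative`", call. = FALSE)
  s <- s[order(s$time_h), ]
  t <- s$time_h
  f <- s$mean_relative
  for (i in seq_along(t)) {
    if (f[i] == target_fraction) return(t[i])
    if (i < length(t) && f[i] > target_fraction && f[i + 1] < target_fraction) {
      return(t[i] + (f[i] - target_fraction) / (f[i] - f[i + 1]) *
               (t[i + 1] - t[i]))
    }
  }
  NA_real_
}

#' Summarize a stability profile
#'
#' Fraction of the t = 0 level remaining at selected timepoints, plus the
#' interpolated half-loss time (when the profile crosses 0.5).
#'
#' @param profile A [build_profile()] result.
#' @param at_times Timepoints to report (default: all profiled ones).
#' @return A list with `analyte_id`, `temperature_C`, `fraction_at`
#'   (tibble `time_h`, `fraction`), `time_to_half_h`.
#' @export
stability_summary <- function(profile, at_times = NULL) {
  stopifnot(inherits(profile, "stability_profile"))
  s <- profile$summary
  if (!is.null(at_times)) s <- s[s$time_h %in% at_times, ]
  list(analyte_id = profile$analyte_id,
       temperature_C = profile$temperature_C,
       fraction_at = tibble(time_h = s$time_h, fraction = s$mean_relative),
       time_to_half_h = time_to_fraction(profile, 0.5))
}

#' Compare protein-level and activity-level degradation profiles
#'
#' Joins two stability profiles on their shared timepoints and reports the
#' per-timepoint difference in remaining fraction, flagging which modality
#' retains more signal. Used to contrast LC-MS/MS protein quantification
#' (robust to partial degradation: it needs only an intact signature
#' peptide) with activity assays (which need a fully functional enzyme).
#'
#' @param protein_profile,activity_profile [build_profile()] results.
#' @return A tibble: `time_h`, `protein_fraction`, `activity_fraction`,
#'   `difference` (protein minus activity), `more_stable`.
#' @export
compare_protein_vs_activity <- function(protein_profile, activity_profile) {
  stopifnot(inherits(protein_profile, "stability_profile"),
            inherits(activity_profile, "stability_profile"))
  p <- protein_profile$summary[, c("time_h", "mean_relative")]
  a <- activity_profile$summary[, c("time_h", "mean_relative")]
  names(p)[2] <- "protein_fraction"
  names(a)[2] <- "activity_fraction"
  out <- inner_join(p, a, by = "time_h")
  if (nrow(out) == 0)
    stop("profiles share no timepoints", call. = FALSE)
  out$difference <- out$protein_fraction - out$activity_fraction
  out$more_stable <- ifelse(out$difference > 0, "protein",
                            ifelse(out$difference < 0, "activity", "equal"))
  arrange(out, .data$time_h)
}

#' Fit a lagged exponential decay to a mean profile
#'
#' Least-squares fit of the plateau-then-first-order decay model (see
#' [decay_fraction()]) to a mean relative profile, by box-constrained
#' optimization over the lag and the decay rate. Returns the fitted
#' parameters and the implied half-loss time `lag + log(2)/rate`.
#'
#' @param profile A [build_profile()] result or data frame with `time_h`
#'   and `mean_relative`.
#' @return A list with `lag_h`, `decay_rate_per_h`, `half_loss_h`, `sse`.
#' @examples
#' pf <- data.frame(time_h = c(0, 6, 24, 48),
#'                  mean_relative = decay_fraction(c(0, 6, 24, 48), 6, 0.03))
#' fit_decay_profile(pf)
#' @export
fit_decay_profile <- function(profile) {
  s <- if (inherits(profile, "stability_profile")) profile$summary else
    as.data.frame(profile)
  if (!all(c("time_h", "mean_relative") %in% names(s)))
    stop("profile needs `time_h` and `mean_relative`", call. = FALSE)
  s <- s[order(s$time_h), ]
  t <- s$time_h
  f <- s$mean_relative
  sse <- function(par) sum((f - decay_fraction(t, par[1], par[2]))^2)
  # initialize lag at the last timepoint still >= 95% and the rate from the
  # overall drop
  lag0 <- if (any(f < 0.95)) max(0, t[max(1, which(f < 0.95)[1] - 1)]) else 0
  drop <- max(1e-6, 1 - min(f))
  k0 <- max(1e-4, -log(max(min(f), 1e-6)) / max(max(t) - lag0, 1))
  fit <- optim(c(lag0, k0), sse, method = "L-BFGS-B",
               lower = c(0, 1e-8), upper = c(max(t), 10))
  list(lag_h = fit$par[1], decay_rate_per_h = fit$par[2],
       half_loss_h = fit$par[1] + log(2) / fit$par[2], sse = fit$value)
}

#' Plot a stability profile
#'
#' Relative level versus postmortem time with the ANOVA-pooled 95% CI as a
#' ribbon and the individual livers as thin lines.
#'
#' @param profile A [build_profile()] result.
#' @return A ggplot object.
#' @export
plot_stability_profile <- function(profile) {
  stopifnot(inherits(profile, "stability_profile"))
  s <- profile$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time_h, y = .data$mean_relative)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(data = profile$per_liver,
                       ggplot2::aes(y = .data$relative,
                                    group = .data$liver_id),
                       colour = "grey55", linewidth = 0.3) +
    ggplot2::geom_line(colour = "steelblue4", linewidth = 0.8) +
    ggplot2::geom_point(colour = "steelblue4") +
    ggplot2::labs(
      x = "Postmortem time (h)",
      y = "Fraction of t = 0 level",
      title = sprintf("%s at %g°C", profile$analyte_id,
                      profile$temperature_C),
      subtitle = sprintf("Mean of livers %s with ANOVA-pooled 95%% CI",
                         paste(profile$included_livers, collapse = ", "))
    ) +
    ggplot2::theme_minimal()
}
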