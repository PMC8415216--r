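#' Peak area response (light/heavy ratio)
#'
#' The peak area response (PAR) is the ratio of the endogenous (light)
#' signature-peptide peak area to the spiked stable-isotope-labelled
#' internal-standard (heavy) peak area. It is the dimensionless core of
#' AQUA quantification: `pmol signature peptide = PAR x pmol SIL-IS
#' peptide`.
#'
#' @param light_area Non-negative numeric vector.
#' @param heavy_area Positive numeric vector; a missing or zero internal
#'   standard invalidates the measurement and raises an error rather than
#'   returning zero.
#' @return `light_area / heavy_area`, vectorized.
#' @examples
#' par_response(2903.4, 1000)
#' @export
par_response <- function(light_area, heavy_area) {
  if (any(!is.finite(light_area)) || any(light_area < 0))
    stop("`light_area` must be non-negative and finite", call. = FALSE)
  if (any(!is.finite(heavy_area)) || any(heavy_area <= 0))
    stop("`heavy_area` must be positive: a zero/missing internal standard ",
         "invalidates AQUA quantification", call. = FALSE)
  light_area / heavy_area
}

#' AQUA quantification of CYP isoforms from peak-area tables
#'
#' Converts light/heavy quantifier peak areas to absolute protein
#' concentrations: `PAR = light area / heavy area`,
#' `signature pmol = PAR x SIL-IS pmol`, and
#' `pmol/mg = signature pmol / mg microsomal protein digested`.
#' Concentrations are computed per injection from the quantifier peptide
#' only; when the sample table carries a `prep_id` column and
#' `average_technical = TRUE`, technical replicate injections of a digest
#' are averaged at the concentration level. Qualifier transitions, when
#' present, yield a light-channel qualifier/quantifier area ratio reported
#' for QC and never averaged into the concentration.
#'
#' Samples whose heavy quantifier area is missing or zero are flagged
#' `"missing_is"` with `NA` concentration (the internal standard is lost,
#' AQUA is invalid); a zero light area gives a zero concentration flagged
#' `"below_lod"`.
#'
#' @param peak_areas Tibble with columns `sample_id`, `transition_id`,
#'   `area`.
#' @param samples Tibble with columns `sample_id`, `plm_mass_ug` and
#'   optionally `prep_id`, `liver_id`, `temperature_C`, `time_h`,
#'   `replicate_id`.
#' @param transitions Transition table (see [default_transitions()]).
#' @param sil_spike_fmol Named positive vector, SIL-IS spike (fmol) per
#'   protein per digest.
#' @param average_technical Average technical replicate injections per
#'   `prep_id` (default `TRUE`; requires a `prep_id` column to have any
#'   effect).
#' @return A tibble with one row per (sample or prep) x protein:
#'   `sample_id`, grouping metadata when present, `protein_id`,
#'   `par_response`, `signature_pmol`, `conc_pmol_per_mg`,
#'   `qualifier_ratio`, `flag`, `n_injections`.
#' @examples
#' des <- experiment_design(livers = "liver1", temperatures_C = 21,
#'                          timepoints_h = c(0, 24),
#'                          sil_spike_fmol = c(CYP1A2 = 1000))
#' dp <- decay_params("CYP1A2", 23.3, 24, log(2) / 24, 21)
#' sim <- simulate_quant_experiment(des, dp, noise_model(), seed = 1)
#' quantify_cyp(sim$peak_areas, sim$samples, sim$transitions,
#'              des$sil_spike_fmol)
#' @export
quantify_cyp <- function(peak_areas, samples, transitions = default_transitions(),
                         sil_spike_fmol, average_technical = TRUE) {
  peak_areas <- as_tibble(peak_areas)
  samples <- as_tibble(samples)
  transitions <- validate_transitions(transitions)
  req_a <- c("sample_id", "transition_id", "area")
  if (!all(req_a %in% names(peak_areas)))
    stop("`peak_areas` needs columns: ", paste(req_a, collapse = ", "),
         call. = FALSE)
  if (!all(c("sample_id", "plm_mass_ug") %in% names(samples)))
    stop("`samples` needs columns sample_id and plm_mass_ug", call. = FALSE)
  if (any(samples$plm_mass_ug <= 0))
    stop("`plm_mass_ug` must be positive", call. = FALSE)
  if (any(peak_areas$area < 0))
    stop("peak areas must be non-negative", call. = FALSE)

  x <- inner_join(peak_areas[, setdiff(names(peak_areas), c("label", "role", "protein_id"))],
                  transitions[, c("transition_id", "protein_id", "role", "label")],
                  by = "transition_id")
  wide <- x |>
    mutate(channel = paste(.data$role, .data$label, sep = "_")) |>
    select("sample_id", "protein_id", "channel", "area") |>
    pivot_wider(names_from = "channel", values_from = "area")
  for (col in c("quantifier_light", "quantifier_heavy"))
    if (!col %in% names(wide)) wide[[col]] <- NA_real_

  proteins <- unique(wide$protein_id)
  sil <- sil_spike_fmol[proteins]
  if (any(is.na(sil)))
    stop("`sil_spike_fmol` missing for: ",
         paste(proteins[is.na(sil)], collapse = ", "), call. = FALSE)

  res <- wide |>
    inner_join(samples, by = "sample_id") |>
    mutate(
      flag = case_when(
        is.na(.data$quantifier_light) | is.na(.data$quantifier_heavy) ~ "unquantified",
        .data$quantifier_heavy <= 0 ~ "missing_is",
        .data$quantifier_light == 0 ~ "below_lod",
        TRUE ~ "ok"
      ),
      par_response = ifelse(.data$flag %in% c("ok", "below_lod"),
                            .data$quantifier_light / .data$quantifier_heavy,
                            NA_real_),
      signature_pmol = .data$par_response *
        unname(sil_spike_fmol[.data$protein_id]) / 1000,
      conc_pmol_per_mg = .data$signature_pmol / (.data$plm_mass_ug / 1000),
      qualifier_ratio = if ("qualifier_light" %in% names(wide))
        .data$qualifier_light / .data$quantifier_light else NA_real_
    )

  meta_cols <- intersect(c("prep_id", "liver_id", "temperature_C", "time_h"),
                         names(samples))
  keep <- c("sample_id", meta_cols, "protein_id", "par_response",
            "signature_pmol", "conc_pmol_per_mg", "qualifier_ratio", "flag")
  res <- res[, keep]

  if (average_technical && "prep_id" %in% names(res)) {
    res <- res |>
      group_by(across(all_of(c(setdiff(meta_cols, character(0)), "protein_id")))) |>
      summarise(
        par_response = mean(.data$par_response),
        signature_pmol = mean(.data$signature_pmol),
        conc_pmol_per_mg = mean(.data$conc_pmol_per_mg),
        qualifier_ratio = mean(.data$qualifier_ratio),
        flag = if (all(.data$flag == "ok")) "ok" else
          paste(unique(.data$flag[.data$flag != "ok"]), collapse = ";"),
        n_injections = n(),
        .groups = "drop"
      ) |>
      rename(sample_id = "prep_id") |>
      arrange(.data$sample_id, .data$protein_id)
  } else {
    res$n_injections <- 1L
    res <- arrange(res, .data$sample_id, .data$protein_id)
  }
  res
}

#' Total protein concentration from a Bradford/BSA standard curve
#'
#' Fits an ordinary (unweighted) least-squares line of absorbance against
#' BSA standard concentration and inverts it at the mean of the sample
#' replicate absorbances.
#'
#' @param sample_absorbances Numeric vector of replicate absorbances for
#'   one sample.
#' @param standards Data frame with columns `conc_mg_ml` and `absorbance`
#'   (at least two distinct concentrations).
#' @return A list with `conc_mg_ml` (the interpolated concentration),
#'   `extrapolated` (`TRUE` when the mean absorbance lies outside the
#'   standard absorbance range, reported with a warning), `slope` and
#'   `intercept`.
#' @examples
#' stds <- data.frame(conc_mg_ml = c(0.25, 0.5, 1, 2),
#'                    absorbance = 0.1 + 0.5 * c(0.25, 0.5, 1, 2))
#' bradford_concentration(c(0.34, 0.36), stds)$conc_mg_ml
#' @export
bradford_concentration <- function(sample_absorbances, standards) {
  standards <- as.data.frame(standards)
  if (!all(c("conc_mg_ml", "absorbance") %in% names(standards)))
    stop("`standards` needs columns conc_mg_ml and absorbance", call. = FALSE)
  if (length(unique(standards$conc_mg_ml)) < 2)
    stop("at least two distinct standard concentrations are required",
         call. = FALSE)
  if (length(sample_absorbances) < 1 || any(!is.finite(sample_absorbances)))
    stop("`sample_absorbances` must be finite and non-empty", call. = FALSE)
  fit <- lm(absorbance ~ conc_mg_ml, data = standards)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope == 0)
    stop("standard curve has zero slope; cannot invert", call. = FALSE)
  a_bar <- mean(sample_absorbances)
  extrapolated <- a_bar < min(standards$absorbance) ||
    a_bar > max(standards$absorbance)
  if (extrapolated)
    warning("sample absorbance outside the standard range; ",
            "concentration is extrapolated", call. = FALSE)
  list(conc_mg_ml = (a_bar - intercept) / slope,
       extrapolated = extrapolated, slope = slope, intercept = intercept)
}

#' Microsomal protein per gram of liver (MPPGL)
#'
#' The yield of microsomal protein per gram of liver tissue used in the
#' preparation, a standard scaling factor in physiologically based
#' pharmacokinetic modelling. The quotient is not corrected for protein
#' loss during microsome isolation.
#'
#' @param microsomal_protein_mg Non-negative numeric, total microsomal
#'   protein recovered (mg).
#' @param liver_mass_g Positive numeric, liver tissue used (g).
#' @return `microsomal_protein_mg / liver_mass_g` in mg/g, vectorized.
#' @examples
#' compute_mppgl(5.45, 0.5)
#' @export
compute_mppgl <- function(microsomal_protein_mg, liver_mass_g) {
  if (any(!is.finite(microsomal_protein_mg)) || any(microsomal_protein_mg < 0))
    stop("`microsomal_protein_mg` must be non-negative", call. = FALSE)
  if (any(!is.finite(liver_mass_g)) || any(liver_mass_g <= 0))
    stop("`liver_mass_g` must be positive", call. = FALSE)
  microsomal_protein_mg / liver_mass_g
}

#' Mean level across livers
#'
#' Arithmetic mean of per-liver levels, kept at full precision; reports
#' conventionally round to one decimal.
#'
#' @param values Non-empty numeric vector of per-liver levels.
#' @return The arithmetic mean (full precision).
#' @examples
#' round(mean_across_livers(c(21.6, 28.3, 19.9)), 1)
#' @export
mean_across_livers <- function(values) {
  if (length(values) < 1 || any(!is.finite(values)))
    stop("`values` must be a non-empty finite numeric vector", call. = FALSE)
  mean(values)
}
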