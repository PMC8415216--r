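#' Simulate a multi-liver CYP degradation experiment
#'
#' Generates the three tables the AQUA quantification pipeline consumes —
#' integrated peak areas, sample metadata, and the ground truth used to
#' produce them — for a liver x temperature x timepoint design. Each digest
#' ("prep") of each liver at each storage condition is measured by
#' `technical_replicates` injections.
#'
#' The generative model is hierarchical and multiplicative. The true
#' concentration of analyte a in liver l at time t is
#' `baseline(a) * scaling(l, a) * liver_effect(l, a) * decay_fraction(t)`,
#' where `liver_effect` is a random between-liver draw and `scaling` an
#' optional deterministic per-liver multiplier. Measured concentrations add
#' a between-run draw per digest and a within-run draw per injection. Heavy
#' (SIL-IS) peak areas carry within-run noise only: the internal standard is
#' spiked at digestion, after any degradation in the tissue, so the
#' light/heavy area ratio carries exactly the liver, run, and within-run
#' draws of the light channel.
#'
#' @param design An [experiment_design()]. The analytes simulated are the
#'   names of `design$sil_spike_fmol`.
#' @param decay A tibble from [decay_params()] with one row per
#'   (analyte, temperature) covering every analyte and temperature in the
#'   design.
#' @param noise A [noise_model()].
#' @param seed Integer seed; identical inputs and seed give identical
#'   tables.
#' @param liver_scaling Optional deterministic per-liver multipliers:
#'   either a named numeric vector (one multiplier per liver, applied to
#'   all analytes) or a data frame with columns `liver_id`, `analyte_id`,
#'   `scaling`. Used to give each liver its own baseline, e.g. to emulate
#'   observed between-animal differences.
#' @param heavy_base_area Positive scalar, nominal heavy-channel peak area
#'   in arbitrary units.
#'
#' @return A list with tibbles `peak_areas` (`sample_id`, `transition_id`,
#'   `label`, `area`), `samples` (`sample_id`, `prep_id`, `liver_id`,
#'   `temperature_C`, `time_h`, `plm_mass_ug`, `run_id`, `replicate_id`),
#'   `truth` (`liver_id`, `temperature_C`, `time_h`, `analyte_id`,
#'   `decay_fraction`, `true_conc_pmol_per_mg`), and the `transitions`
#'   table used.
#' @examples
#' des <- experiment_design(livers = "liver1", temperatures_C = 21,
#'                          timepoints_h = c(0, 24, 48),
#'                          sil_spike_fmol = c(CYP1A2 = 1000))
#' dp <- decay_params("CYP1A2", 23.3, lag_h = 24,
#'                    decay_rate_per_h = log(2) / 24, temperature_C = 21)
#' sim <- simulate_quant_experiment(des, dp, noise_model(), seed = 1)
#' head(sim$peak_areas)
#' @export
simulate_quant_experiment <- function(design, decay, noise = noise_model(),
                                      seed, liver_scaling = NULL,
                                      heavy_base_area = 1e5) {
  stopifnot(inherits(design, "experiment_design"), inherits(noise, "noise_model"))
  analytes <- names(design$sil_spike_fmol)
  decay <- as_tibble(decay)
  need <- expand.grid(analyte_id = analytes,
                      temperature_C = design$temperatures_C,
                      stringsAsFactors = FALSE)
  have <- paste(decay$analyte_id, decay$temperature_C)
  missing <- need[!paste(need$analyte_id, need$temperature_C) %in% have, ]
  if (nrow(missing))
    stop("missing decay parameters for: ",
         paste(missing$analyte_id, missing$temperature_C, sep = "@",
               collapse = ", "), call. = FALSE)

  scaling_tbl <- resolve_liver_scaling(liver_scaling, design$livers, analytes)

  set.seed(as.integer(seed))

  # between-liver biological effects, one per (liver, analyte)
  liver_grid <- expand.grid(liver_id = design$livers, analyte_id = analytes,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  liver_grid$liver_effect <- mult_noise(nrow(liver_grid),
                                        noise$between_liver_cv, noise$law)

  # one prep (digest) per liver x temperature x timepoint
  preps <- expand.grid(time_h = design$timepoints_h,
                       temperature_C = design$temperatures_C,
                       liver_id = design$livers,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  preps$prep_id <- sprintf("%s_%gC_%gh", preps$liver_id, preps$temperature_C,
                           preps$time_h)
  preps$run_id <- paste0("run_", seq_len(nrow(preps)))

  # between-run effects per (prep, analyte)
  run_grid <- merge(preps["prep_id"],
                    data.frame(analyte_id = analytes), by = NULL)
  run_grid$run_effect <- mult_noise(nrow(run_grid), noise$between_run_cv,
                                    noise$law)

  truth <- merge(merge(preps, liver_grid, by = "liver_id"), decay,
                 by = c("analyte_id", "temperature_C"))
  truth <- merge(truth, scaling_tbl, by = c("liver_id", "analyte_id"))
  truth$decay_fraction <- ifelse(
    truth$time_h <= truth$lag_h, 1,
    exp(-truth$decay_rate_per_h * (truth$time_h - truth$lag_h)))
  truth$true_conc_pmol_per_mg <- truth$baseline_level * truth$scaling *
    truth$liver_effect * truth$decay_fraction

  # injections
  inj <- merge(preps, data.frame(replicate_id = seq_len(design$technical_replicates)),
               by = NULL)
  inj$sample_id <- paste0(inj$prep_id, "_r", inj$replicate_id)
  inj <- inj[order(inj$prep_id, inj$replicate_id), ]

  meas <- merge(inj, data.frame(analyte_id = analytes), by = NULL)
  meas <- meas[order(meas$prep_id, meas$replicate_id, meas$analyte_id), ]
  meas$within_effect <- mult_noise(nrow(meas), noise$within_run_cv, noise$law)
  meas$heavy_within_effect <- mult_noise(nrow(meas), noise$within_run_cv,
                                         noise$law)
  meas <- merge(meas, run_grid, by = c("prep_id", "analyte_id"))
  meas <- merge(meas,
                truth[, c("prep_id", "analyte_id", "true_conc_pmol_per_mg")],
                by = c("prep_id", "analyte_id"))

  plm_mg <- design$plm_mass_ug_per_digest / 1000
  sil_pmol <- design$sil_spike_fmol[meas$analyte_id] / 1000
  conc_meas <- meas$true_conc_pmol_per_mg * meas$run_effect * meas$within_effect
  par_meas <- conc_meas * plm_mg / sil_pmol
  heavy_area <- heavy_base_area * meas$heavy_within_effect
  light_area <- par_meas * heavy_area

  transitions <- transitions_for(analytes)
  quant_light <- transitions$transition_id[transitions$role == "quantifier" &
                                             transitions$label == "light"]
  names(quant_light) <- transitions$protein_id[transitions$role == "quantifier" &
                                                 transitions$label == "light"]
  quant_heavy <- transitions$transition_id[transitions$role == "quantifier" &
                                             transitions$label == "heavy"]
  names(quant_heavy) <- transitions$protein_id[transitions$role == "quantifier" &
                                                 transitions$label == "heavy"]

  peak_areas <- tibble(
    sample_id = rep(meas$sample_id, 2),
    transition_id = c(quant_light[meas$analyte_id], quant_heavy[meas$analyte_id]),
    label = rep(c("light", "heavy"), each = nrow(meas)),
    area = c(light_area, heavy_area)
  )
  peak_areas <- arrange(peak_areas, .data$sample_id, .data$transition_id)

  samples <- as_tibble(inj[, c("sample_id", "prep_id", "liver_id",
                               "temperature_C", "time_h", "run_id",
                               "replicate_id")])
  samples$plm_mass_ug <- design$plm_mass_ug_per_digest
  samples <- samples[, c("sample_id", "prep_id", "liver_id", "temperature_C",
                         "time_h", "plm_mass_ug", "run_id", "replicate_id")]
  samples <- arrange(samples, .data$sample_id)

  truth_out <- as_tibble(truth[, c("liver_id", "temperature_C", "time_h",
                                   "analyte_id", "baseline_level", "scaling",
                                   "liver_effect", "decay_fraction",
                                   "true_conc_pmol_per_mg")])
  truth_out <- arrange(truth_out, .data$analyte_id, .data$liver_id,
                       .data$temperature_C, .data$time_h)

  list(peak_areas = peak_areas, samples = samples, truth = truth_out,
       transitions = transitions)
}

# normalize the liver_scaling argument to a (liver_id, analyte_id, scaling) table
resolve_liver_scaling <- function(liver_scaling, livers, analytes) {
  base <- expand.grid(liver_id = livers, analyte_id = analytes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (is.null(liver_scaling)) {
    base$scaling <- 1
    return(base)
  }
  if (is.numeric(liver_scaling)) {
    if (is.null(names(liver_scaling)) ||
        !all(livers %in% names(liver_scaling)))
      stop("`liver_scaling` vector must be named with every liver id",
           call. = FALSE)
    base$scaling <- unname(liver_scaling[base$liver_id])
    return(base)
  }
  ls <- as.data.frame(liver_scaling)
  if (!all(c("liver_id", "analyte_id", "scaling") %in% names(ls)))
    stop("`liver_scaling` data frame needs columns liver_id, analyte_id, scaling",
         call. = FALSE)
  out <- merge(base, ls, by = c("liver_id", "analyte_id"), all.x = TRUE)
  out$scaling[is.na(out$scaling)] <- 1
  out
}

# transition table for an analyte set: the validated CYP transitions where
# available, generic placeholders otherwise
transitions_for <- function(analytes) {
  def <- default_transitions()
  known <- def[def$protein_id %in% analytes, ]
  unknown <- setdiff(analytes, def$protein_id)
  if (length(unknown)) {
    idx <- seq_along(unknown)
    extra <- tibble(
      protein_id = rep(unknown, each = 2),
      peptide_seq = rep(paste0("PEPTIDE", idx, "K"), each = 2),
      role = "quantifier",
      label = rep(c("light", "heavy"), times = length(unknown)),
      precursor_mz = rep(500 + idx, each = 2) + rep(c(0, 4), length(unknown)),
      product_mz = rep(600 + idx, each = 2) + rep(c(0, 8), length(unknown)),
      cone_voltage_V = 35,
      collision_energy_eV = 20
    )
    extra$transition_id <- paste(extra$protein_id, "quant", extra$label,
                                 sep = "_")
    known <- bind_rows(known, extra)
  }
  validate_transitions(known)
}

#' Simulate a method-validation replicate experiment
#'
#' Emits day-labelled replicate measurements of a single analyte with
#' between-run (day) and within-run variance components, as used for
#' precision estimation, spike-recovery trueness, and replicate-based
#' LOD/LLOQ determination. When `spike_fmol > 0`, spiked samples contain
#' `true_level + spike_fmol` before noise and share each day's run effect
#' with the unspiked samples of that day.
#'
#' @param true_level Positive scalar, the endogenous level (units free:
#'   fmol, pmol/mg, ...).
#' @param spike_fmol Non-negative scalar added to spiked samples (same
#'   units as `true_level`); 0 means unspiked samples only.
#' @param n_days,reps_per_day Positive integers, the run structure.
#' @param noise A [noise_model()]; `between_run_cv` acts per day,
#'   `within_run_cv` per replicate (`between_liver_cv` is not used here).
#' @param seed Integer seed.
#' @return A tibble with columns `day_id`, `replicate_id`, `condition`
#'   (`"unspiked"`/`"spiked"`), `value`.
#' @examples
#' simulate_validation_experiment(100, n_days = 7, reps_per_day = 3,
#'   noise = noise_model(between_run_cv = 0.1, within_run_cv = 0.05),
#'   seed = 1)
#' @export
simulate_validation_experiment <- function(true_level, spike_fmol = 0,
                                           n_days, reps_per_day,
                                           noise = noise_model(), seed) {
  stopifnot(inherits(noise, "noise_model"))
  if (true_level <= 0) stop("`true_level` must be positive", call. = FALSE)
  if (spike_fmol < 0) stop("`spike_fmol` must be non-negative", call. = FALSE)
  if (n_days < 1 || reps_per_day < 1)
    stop("`n_days` and `reps_per_day` must be >= 1", call. = FALSE)

  set.seed(as.integer(seed))
  day_effect <- mult_noise(n_days, noise$between_run_cv, noise$law)

  grid <- expand.grid(replicate_id = seq_len(reps_per_day),
                      day_id = paste0("day", seq_len(n_days)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$day_id, grid$replicate_id), c("day_id", "replicate_id")]
  day_idx <- as.integer(sub("day", "", grid$day_id))

  out <- tibble(
    day_id = grid$day_id, replicate_id = grid$replicate_id,
    condition = "unspiked",
    value = true_level * day_effect[day_idx] *
      mult_noise(nrow(grid), noise$within_run_cv, noise$law)
  )
  if (spike_fmol > 0) {
    spiked <- tibble(
      day_id = grid$day_id, replicate_id = grid$replicate_id,
      condition = "spiked",
      value = (true_level + spike_fmol) * day_effect[day_idx] *
        mult_noise(nrow(grid), noise$within_run_cv, noise$law)
    )
    out <- bind_rows(out, spiked)
  }
  as_tibble(out)
}

#' Simulate a probe-substrate activity experiment
#'
#' Generates internal-standard calibrator series and per-digest assay
#' responses for probe-substrate metabolite formation (e.g. paracetamol
#' from phenacetin for CYP1A, alpha-hydroxymidazolam from midazolam for
#' CYP3A). The true formation rate of pathway p in liver l at time t is
#' `baseline(p) * scaling * liver_effect(l, p) * decay_fraction(t)`; it is
#' converted to the metabolite concentration accumulated over the reaction
#' (`rate * time_min * plm_mg_per_ml / 1000` uM), diluted, and mapped
#' through a linear response law (response ratio = slope * conc +
#' intercept) with noise applied multiplicatively to the measured
#' concentration. Calibrators follow twofold serial dilutions from a top
#' concentration and carry within-run noise.
#'
#' @param design An [experiment_design()] supplying livers, temperatures
#'   and timepoints (SIL spikes are not used by the activity assay).
#' @param decay A [decay_params()] tibble, one row per
#'   (pathway, temperature); pathways are taken from `calib_top_uM` names.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param calib_top_uM Named positive vector: top calibrator concentration
#'   (uM) per pathway.
#' @param calib_levels Number of twofold serial-dilution calibrator levels
#'   (>= 2).
#' @param response_slope,response_intercept Linear response law of the
#'   instrument (response ratio per uM, and its intercept).
#' @param time_min,plm_mg_per_ml Reaction time (min) and microsomal protein
#'   concentration in the reaction (mg/ml).
#' @param dilution_factor Fold dilution of the stopped reaction before
#'   LC-MS/MS.
#' @param is_area_base Nominal internal-standard peak area.
#' @param liver_scaling Optional per-liver multipliers, as in
#'   [simulate_quant_experiment()].
#' @return A list of tibbles: `calibrators` (`analyte_id`, `level_conc_uM`,
#'   `analyte_area`, `is_area`), `samples` (`sample_id`, `liver_id`,
#'   `temperature_C`, `time_h`, `analyte_id`, `analyte_area`, `is_area`,
#'   `time_min`, `plm_mg_per_ml`, `dilution_factor`), and `truth`
#'   (`liver_id`, `temperature_C`, `time_h`, `analyte_id`,
#'   `decay_fraction`, `true_rate_pmol_min_mg`).
#' @examples
#' des <- experiment_design(livers = "liver1", temperatures_C = 21,
#'                          timepoints_h = c(0, 24))
#' dp <- decay_params("CYP1A-phenacetin", 3800, lag_h = 19,
#'                    decay_rate_per_h = 0.13, temperature_C = 21)
#' sim <- simulate_activity_experiment(des, dp, noise_model(), seed = 1,
#'   calib_top_uM = c("CYP1A-phenacetin" = 20))
#' @export
simulate_activity_experiment <- function(design, decay, noise = noise_model(),
                                         seed,
                                         calib_top_uM = c("CYP1A-phenacetin" = 20,
                                                          "CYP3A-midazolam" = 7.5),
                                         calib_levels = 15,
                                         response_slope = 0.1,
                                         response_intercept = 0,
                                         time_min = 20, plm_mg_per_ml = 1,
                                         dilution_factor = 15,
                                         is_area_base = 1e5,
                                         liver_scaling = NULL) {
  stopifnot(inherits(design, "experiment_design"), inherits(noise, "noise_model"))
  if (calib_levels < 2) stop("`calib_levels` must be >= 2", call. = FALSE)
  if (is.null(names(calib_top_uM)))
    stop("`calib_top_uM` must be named by pathway", call. = FALSE)
  pathways <- names(calib_top_uM)
  decay <- as_tibble(decay)
  need <- expand.grid(analyte_id = pathways,
                      temperature_C = design$temperatures_C,
                      stringsAsFactors = FALSE)
  have <- paste(decay$analyte_id, decay$temperature_C)
  if (!all(paste(need$analyte_id, need$temperature_C) %in% have))
    stop("missing decay parameters for a pathway/temperature combination",
         call. = FALSE)
  scaling_tbl <- resolve_liver_scaling(liver_scaling, design$livers, pathways)

  set.seed(as.integer(seed))

  # calibrators
  calib <- bind_rows(lapply(pathways, function(p) {
    tibble(analyte_id = p,
           level_conc_uM = serial_dilution_levels(calib_top_uM[[p]],
                                                  calib_levels, 2))
  }))
  calib$is_area <- is_area_base * mult_noise(nrow(calib), noise$within_run_cv,
                                             noise$law)
  ratio_true <- response_slope * calib$level_conc_uM + response_intercept
  calib$analyte_area <- ratio_true *
    mult_noise(nrow(calib), noise$within_run_cv, noise$law) * calib$is_area
  calib <- calib[, c("analyte_id", "level_conc_uM", "analyte_area", "is_area")]

  # liver effects and truth
  liver_grid <- expand.grid(liver_id = design$livers, analyte_id = pathways,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  liver_grid$liver_effect <- mult_noise(nrow(liver_grid),
                                        noise$between_liver_cv, noise$law)
  preps <- expand.grid(time_h = design$timepoints_h,
                       temperature_C = design$temperatures_C,
                       liver_id = design$livers,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth <- merge(merge(preps, liver_grid, by = "liver_id"), decay,
                 by.x = c("analyte_id", "temperature_C"),
                 by.y = c("analyte_id", "temperature_C"))
  truth <- merge(truth, scaling_tbl, by = c("liver_id", "analyte_id"))
  truth$decay_fraction <- ifelse(
    truth$time_h <= truth$lag_h, 1,
    exp(-truth$decay_rate_per_h * (truth$time_h - truth$lag_h)))
  truth$true_rate_pmol_min_mg <- truth$baseline_level * truth$scaling *
    truth$liver_effect * truth$decay_fraction
  truth <- truth[order(truth$analyte_id, truth$liver_id, truth$temperature_C,
                       truth$time_h), ]

  # assay samples: one measurement per prep x pathway
  truth$sample_id <- sprintf("%s_%gC_%gh", truth$liver_id,
                             truth$temperature_C, truth$time_h)
  run_eff <- mult_noise(nrow(truth), noise$between_run_cv, noise$law)
  within_eff <- mult_noise(nrow(truth), noise$within_run_cv, noise$law)
  conc_true_uM <- truth$true_rate_pmol_min_mg * time_min * plm_mg_per_ml / 1000
  conc_meas_uM <- conc_true_uM * run_eff * within_eff
  ratio <- response_slope * (conc_meas_uM / dilution_factor) + response_intercept
  is_area <- is_area_base * mult_noise(nrow(truth), noise$within_run_cv,
                                       noise$law)
  samples <- tibble(
    sample_id = truth$sample_id, liver_id = truth$liver_id,
    temperature_C = truth$temperature_C, time_h = truth$time_h,
    analyte_id = truth$analyte_id,
    analyte_area = ratio * is_area, is_area = is_area,
    time_min = time_min, plm_mg_per_ml = plm_mg_per_ml,
    dilution_factor = dilution_factor
  )

  truth_out <- as_tibble(truth[, c("liver_id", "temperature_C", "time_h",
                                   "analyte_id", "decay_fraction",
                                   "true_rate_pmol_min_mg")])
  list(calibrators = as_tibble(calib), samples = samples, truth = truth_out)
}

#' Simulate a Bradford total-protein assay plate
#'
#' Generates absorbances for a bovine serum albumin (BSA) standard series
#' and for unknown samples following a linear response
#' `A = intercept + slope * conc` with multiplicative noise. Samples are
#' read after `dilution_factor`-fold dilution into the assay range.
#'
#' @param true_mg_ml Named positive vector of true sample protein
#'   concentrations (mg/ml) before dilution; names become sample ids.
#' @param standards_mg_ml BSA standard concentrations (mg/ml).
#' @param slope,intercept Linear response of the assay (absorbance per
#'   mg/ml, and blank absorbance).
#' @param n_replicates Replicate absorbance readings per sample.
#' @param cv Within-assay coefficient of variation (fraction).
#' @param law Noise law, `"lognormal"` or `"normal"`.
#' @param dilution_factor Fold dilution applied to samples before reading.
#' @param seed Integer seed.
#' @return A list with tibbles `standards` (`conc_mg_ml`, `absorbance`) and
#'   `samples` (`sample_id`, `replicate_id`, `absorbance`,
#'   `dilution_factor`).
#' @examples
#' simulate_bradford(c(prep1 = 27.3), seed = 1)
#' @export
simulate_bradford <- function(true_mg_ml,
                              standards_mg_ml = c(0.125, 0.25, 0.5, 0.75, 1, 1.5, 2),
                              slope = 0.5, intercept = 0.05,
                              n_replicates = 2, cv = 0, law = "lognormal",
                              dilution_factor = 30, seed = 1) {
  if (is.null(names(true_mg_ml)))
    names(true_mg_ml) <- paste0("sample", seq_along(true_mg_ml))
  if (any(true_mg_ml <= 0)) stop("`true_mg_ml` must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  standards <- tibble(
    conc_mg_ml = standards_mg_ml,
    absorbance = (intercept + slope * standards_mg_ml) *
      mult_noise(length(standards_mg_ml), cv, law)
  )
  grid <- expand.grid(replicate_id = seq_len(n_replicates),
                      sample_id = names(true_mg_ml),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$sample_id, grid$replicate_id),
               c("sample_id", "replicate_id")]
  diluted <- true_mg_ml[grid$sample_id] / dilution_factor
  samples <- tibble(
    sample_id = grid$sample_id, replicate_id = grid$replicate_id,
    absorbance = (intercept + slope * unname(diluted)) *
      mult_noise(nrow(grid), cv, law),
    dilution_factor = dilution_factor
  )
  list(standards = standards, samples = samples)
}
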