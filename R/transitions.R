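#' Default MRM transition list for the four porcine CYP isoforms
#'
#' Quantifier signature peptides and their stable-isotope-labelled
#' internal-standard (SIL-IS) analogues monitored on a triple-quadrupole
#' instrument. The heavy peptides carry a C-terminal labelled Arg (+10 Da)
#' or Lys (+8 Da). Precursor/product m/z values are those of the validated
#' quantifier transitions:
#'
#' * CYP1A2  YLPSPTLQR        537.8 > 798.4 (heavy 542.8 > 808.5)
#' * CYP2D25 DLAQPPR          398.7 > 369.2 (heavy 403.7 > 379.2)
#' * CYP2E1  FIDLIPSNLPHEATR  862.0 > 489.3 (heavy 867.0 > 489.3)
#' * CYP3A29 SSVNFFTK         465.2 > 755.4 (heavy 469.2 > 763.4)
#'
#' Cone voltage and collision energy are nominal instrument settings; they
#' are carried as metadata and play no role in any computation.
#'
#' @return A tibble with columns `transition_id`, `protein_id`,
#'   `peptide_seq`, `role` (`"quantifier"`/`"qualifier"`), `label`
#'   (`"light"`/`"heavy"`), `precursor_mz`, `product_mz`, `cone_voltage_V`,
#'   `collision_energy_eV`.
#' @examples
#' default_transitions()
#' @export
default_transitions <- function() {
  quant <- tibble(
    protein_id = rep(c("CYP1A2", "CYP2D25", "CYP2E1", "CYP3A29"), each = 2),
    peptide_seq = rep(c("YLPSPTLQR", "DLAQPPR", "FIDLIPSNLPHEATR",
                        "SSVNFFTK"), each = 2),
    role = "quantifier",
    label = rep(c("light", "heavy"), times = 4),
    precursor_mz = c(537.8, 542.8, 398.7, 403.7, 862.0, 867.0, 465.2, 469.2),
    product_mz = c(798.4, 808.5, 369.2, 379.2, 489.3, 489.3, 755.4, 763.4),
    cone_voltage_V = 35,
    collision_energy_eV = c(18, 18, 14, 14, 24, 24, 16, 16)
  )
  quant$transition_id <- paste(quant$protein_id, "quant", quant$label, sep = "_")
  validate_transitions(quant)
}

# check the structural invariants of a transition table
validate_transitions <- function(transitions) {
  transitions <- as_tibble(transitions)
  required <- c("transition_id", "protein_id", "peptide_seq", "role", "label",
                "precursor_mz", "product_mz")
  missing <- setdiff(required, names(transitions))
  if (length(missing))
    stop("transition table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!all(transitions$role %in% c("quantifier", "qualifier")))
    stop("`role` must be 'quantifier' or 'qualifier'", call. = FALSE)
  if (!all(transitions$label %in% c("light", "heavy")))
    stop("`label` must be 'light' or 'heavy'", call. = FALSE)
  if (anyDuplicated(transitions[, c("protein_id", "role", "label")]))
    stop("each (protein, role, label) combination must be unique", call. = FALSE)
  key <- paste(transitions$protein_id, transitions$role)
  for (k in unique(key)) {
    seqs <- unique(transitions$peptide_seq[key == k])
    if (length(seqs) > 1)
      stop("light and heavy forms of ", k, " must share a peptide sequence",
           call. = FALSE)
  }
  transitions[, c("transition_id", setdiff(names(transitions), "transition_id"))]
}
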