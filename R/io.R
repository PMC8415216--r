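#' Column schemas for the pipeline's tabular interchange formats
#'
#' Each table the pipeline reads or writes has a named schema: required
#' columns and their types. Unknown extra columns are always preserved
#' verbatim. Units are encoded in column names (`conc_pmol_per_mg`,
#' `time_h`, ...); CSV files use a dot decimal separator, UTF-8, and a
#' mandatory header row.
#'
#' @param name One of `"peak_areas"`, `"samples"`, `"truth"`,
#'   `"transitions"`, `"cyp_quant"`, `"validation_runs"`,
#'   `"activity_calibrators"`, `"activity_samples"`, `"activity_rates"`,
#'   `"bradford_standards"`, `"bradford_samples"`.
#' @return A named character vector mapping required column names to types
#'   (`"character"` or `"numeric"`).
#' @examples
#' cypstab_schema("peak_areas")
#' @export
cypstab_schema <- function(name) {
  schemas <- list(
    peak_areas = c(sample_id = "character", transition_id = "character",
                   label = "character", area = "numeric"),
    samples = c(sample_id = "character", prep_id = "character",
                liver_id = "character", temperature_C = "numeric",
                time_h = "numeric", plm_mass_ug = "numeric",
                run_id = "character", replicate_id = "numeric"),
    truth = c(liver_id = "character", temperature_C = "numeric",
              time_h = "numeric", analyte_id = "character",
              true_conc_pmol_per_mg = "numeric"),
    transitions = c(transition_id = "character", protein_id = "character",
                    peptide_seq = "character", role = "character",
                    label = "character", precursor_mz = "numeric",
                    product_mz = "numeric"),
    cyp_quant = c(sample_id = "character", protein_id = "character",
                  par_response = "numeric", signature_pmol = "numeric",
                  conc_pmol_per_mg = "numeric", flag = "character"),
    validation_runs = c(analyte_id = "character", day_id = "character",
                        replicate_id = "numeric", condition = "character",
                        value = "numeric"),
    activity_calibrators = c(analyte_id = "character",
                             level_conc_uM = "numeric",
                             analyte_area = "numeric", is_area = "numeric"),
    activity_samples = c(sample_id = "character", analyte_id = "character",
                         analyte_area = "numeric", is_area = "numeric",
                         time_min = "numeric", plm_mg_per_ml = "numeric",
                         dilution_factor = "numeric"),
    activity_rates = c(sample_id = "character", analyte_id = "character",
                       conc_uM = "numeric", rate_pmol_min_mg = "numeric"),
    bradford_standards = c(conc_mg_ml = "numeric", absorbance = "numeric"),
    bradford_samples = c(sample_id = "character", replicate_id = "numeric",
                         absorbance = "numeric", dilution_factor = "numeric")
  )
  if (!name %in% names(schemas))
    stop("unknown schema: ", name, call. = FALSE)
  schemas[[name]]
}

#' Read a schema-validated CSV table
#'
#' Reads a CSV file, checks that every required column of the schema is
#' present, and converts typed columns, reporting the file, row and column
#' of the first malformed value. Unknown columns are preserved as
#' character.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema A schema name (see [cypstab_schema()]) or a named type
#'   vector.
#' @return A tibble.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (is.character(schema) && length(schema) == 1 && is.null(names(schema)))
    schema <- cypstab_schema(schema)
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(names(schema), names(raw))
  if (length(missing))
    stop(path, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      parsed <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(parsed) & !is.na(raw[[col]]) & raw[[col]] != "NA")
      if (length(bad))
        stop(path, ": non-numeric value '", raw[[col]][bad[1]],
             "' in column '", col, "', row ", bad[1], call. = FALSE)
      raw[[col]] <- parsed
    }
  }
  raw
}

#' Write a table as CSV
#'
#' Writes a data frame as UTF-8 CSV with a header row and full-precision
#' (round-trip safe) numeric formatting, so `write_table()` followed by
#' [read_table()] is the identity on the typed columns.
#'
#' @param data A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path) {
  readr::write_csv(as.data.frame(data), path, progress = FALSE)
  invisible(path)
}

#' Reference nondegraded porcine liver levels
#'
#' The package's reference table of measured levels in nondegraded
#' (t = 0) porcine liver: microsomal protein yield (MPPGL), absolute CYP
#' isoform concentrations, and probe-substrate metabolite formation rates
#' for three livers. Shipped in `inst/extdata` and used to anchor the
#' demo configuration's ground truth.
#'
#' @return A tibble with one row per liver: `liver_id`, `mppgl_mg_per_g`,
#'   `CYP1A2`, `CYP2D25`, `CYP2E1`, `CYP3A29` (pmol/mg PLM),
#'   `phenacetin_rate_pmol_min_mg`, `midazolam_rate_pmol_min_mg`.
#' @examples
#' reference_liver_levels()
#' @export
reference_liver_levels <- function() {
  path <- system.file("extdata", "nondegraded_liver_levels.csv",
                      package = "cypstab", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    liver_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
}
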