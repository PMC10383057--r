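# Column alias map: Skyline-style exports vary in header spelling, so the
# readers normalise names case-insensitively (spaces and dots to underscores)
# and then apply these aliases.
TRANSITION_ALIASES <- c(
  "molecule"            = "name",
  "molecule_name"       = "name",
  "precursor_name"      = "name",
  "molecular_formula"   = "formula",
  "precursor_adduct"    = "adduct",
  "precursor_mz"        = "theoretical_mz",
  "mz"                  = "theoretical_mz",
  "retention_time"      = "expected_rt",
  "rt"                  = "expected_rt",
  "explicit_retention_time" = "expected_rt",
  "internal_standard"   = "is_internal_standard"
)

MEASUREMENT_ALIASES <- c(
  "replicate"                 = "replicate_index",
  "replicate_name"            = "replicate_index",
  "area"                      = "peak_area",
  "total_area"                = "peak_area",
  "nominal_concentration_um"  = "nominal_concentration",
  "analyte_concentration"     = "nominal_concentration",
  "observed_retention_time"   = "observed_rt"
)

TRANSITION_COLUMNS <- c("metabolite_id", "name", "formula", "adduct",
                        "polarity", "theoretical_mz", "expected_rt",
                        "is_internal_standard")

MEASUREMENT_COLUMNS <- c("metabolite_id", "sample_id", "replicate_index",
                         "sample_type", "polarity", "peak_area",
                         "observed_mz", "observed_rt",
                         "nominal_concentration")

SAMPLE_TYPES <- c("standard", "blank", "qc", "matrix", "solvent_reference")

normalize_columns <- function(df, aliases) {
  nm <- tolower(gsub("[ .]+", "_", names(df)))
  hit <- nm %in% names(aliases)
  nm[hit] <- unname(aliases[nm[hit]])
  names(df) <- nm
  df
}

require_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rrfq_abort(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      "rrfq_schema_error"
    )
  }
  invisible(df)
}

#' Read a targeted transition list
#'
#' Reads the CSV of targeted precursors (one row per metabolite and
#' polarity): id, display name, molecular formula, adduct, polarity,
#' theoretical m/z, expected retention time, and an internal-standard flag.
#' Column names are matched case-insensitively with common Skyline-export
#' aliases. When `theoretical_mz` is absent it is computed from the formula
#' and adduct.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble with columns
#'   `metabolite_id, name, formula, adduct, polarity, theoretical_mz,
#'   expected_rt, is_internal_standard`.
#' @export
read_transition_list <- function(path) {
  if (!file.exists(path)) {
    rrfq_abort(sprintf("Transition list not found: %s", path), "rrfq_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- normalize_columns(df, TRANSITION_ALIASES)
  if (!"theoretical_mz" %in% names(df) &&
      all(c("formula", "adduct") %in% names(df))) {
    df$theoretical_mz <- NA_real_
  }
  require_columns(df, setdiff(TRANSITION_COLUMNS, "name"), "Transition list")
  if (!"name" %in% names(df)) df$name <- df$metabolite_id
  df <- tibble::as_tibble(df)[, TRANSITION_COLUMNS]

  df$adduct <- normalize_adduct(as.character(df$adduct))
  df$polarity <- tolower(as.character(df$polarity))
  df$is_internal_standard <- parse_logical_column(df$is_internal_standard,
                                                  "is_internal_standard")
  validate_transitions(df)
}

parse_logical_column <- function(x, what) {
  if (is.logical(x)) return(x)
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(lx))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) {
    rrfq_abort(
      sprintf("Column '%s' has unparsable logical value(s) at row(s): %s",
              what, paste(which(is.na(out)), collapse = ", ")),
      "rrfq_schema_error"
    )
  }
  out
}

validate_transitions <- function(df) {
  bad_adduct <- !df$adduct %in% SUPPORTED_ADDUCTS
  if (any(bad_adduct)) {
    rrfq_abort(
      sprintf("Unsupported adduct(s) at row(s) %s (only %s are accepted).",
              paste(which(bad_adduct), collapse = ", "),
              paste(SUPPORTED_ADDUCTS, collapse = ", ")),
      "rrfq_schema_error"
    )
  }
  bad_pol <- df$polarity != adduct_polarity(df$adduct)
  if (any(bad_pol)) {
    rrfq_abort(
      sprintf("Polarity inconsistent with adduct sign at row(s): %s",
              paste(which(bad_pol), collapse = ", ")),
      "rrfq_schema_error"
    )
  }
  # Fill m/z from the formula where missing; validate parseability row-wise.
  for (i in which(is.na(df$theoretical_mz))) {
    df$theoretical_mz[i] <- tryCatch(
      compute_theoretical_mz(df$formula[i], df$adduct[i]),
      rrfq_error = function(e) {
        rrfq_abort(
          sprintf("Row %d ('%s'): %s", i, df$metabolite_id[i],
                  conditionMessage(e)),
          "rrfq_schema_error"
        )
      }
    )
  }
  if (any(df$theoretical_mz <= 0)) {
    rrfq_abort("theoretical_mz must be positive.", "rrfq_schema_error")
  }
  if (any(df$expected_rt < 0)) {
    rrfq_abort("expected_rt must be non-negative.", "rrfq_schema_error")
  }
  key <- paste(df$metabolite_id, df$polarity)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    rrfq_abort(
      sprintf("Duplicate (metabolite_id, polarity) key(s): %s",
              paste(dup, collapse = "; ")),
      "rrfq_duplicate_key_error"
    )
  }
  df
}

#' Read a long-format peak-area table
#'
#' Reads a Skyline-export-like long table: one row per metabolite, sample and
#' replicate with the integrated peak area, optional observed m/z and RT,
#' the sample type, and the nominal concentration for standards. Every
#' `metabolite_id` must resolve against the transition list.
#'
#' @param path Path to a CSV file.
#' @param transitions Transition tibble from [read_transition_list()].
#' @return A tibble of measurements (`MEASUREMENT` columns); absent optional
#'   columns are filled with `NA`.
#' @export
read_peak_areas <- function(path, transitions) {
  if (!file.exists(path)) {
    rrfq_abort(sprintf("Peak-area table not found: %s", path), "rrfq_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- normalize_columns(df, MEASUREMENT_ALIASES)
  require_columns(df, c("metabolite_id", "sample_id", "replicate_index",
                        "sample_type", "polarity", "peak_area"),
                  "Peak-area table")
  for (opt in c("observed_mz", "observed_rt", "nominal_concentration")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_real_
  }
  df <- tibble::as_tibble(df)[, MEASUREMENT_COLUMNS]
  df$polarity <- tolower(as.character(df$polarity))
  df$sample_type <- tolower(as.character(df$sample_type))
  df$replicate_index <- as.integer(df$replicate_index)
  validate_measurements(df, transitions)
}

validate_measurements <- function(df, transitions) {
  bad_type <- !df$sample_type %in% SAMPLE_TYPES
  if (any(bad_type)) {
    rrfq_abort(
      sprintf("Unknown sample_type value(s): %s (allowed: %s)",
              paste(unique(df$sample_type[bad_type]), collapse = ", "),
              paste(SAMPLE_TYPES, collapse = ", ")),
      "rrfq_schema_error"
    )
  }
  known <- paste(transitions$metabolite_id, transitions$polarity)
  seen <- paste(df$metabolite_id, df$polarity)
  unresolved <- unique(df$metabolite_id[!seen %in% known])
  if (length(unresolved) > 0) {
    rrfq_abort(
      sprintf("metabolite_id(s) absent from the transition list: %s",
              paste(unresolved, collapse = ", ")),
      "rrfq_unresolved_reference_error"
    )
  }
  if (any(df$peak_area < 0, na.rm = TRUE)) {
    rrfq_abort("Negative peak_area values are not allowed.",
               "rrfq_validation_error")
  }
  if (any(!is.na(df$nominal_concentration) & df$nominal_concentration <= 0)) {
    rrfq_abort("nominal_concentration must be positive when present.",
               "rrfq_validation_error")
  }
  is_ids <- transitions$metabolite_id[transitions$is_internal_standard]
  needs_conc <- df$sample_type == "standard" & !df$metabolite_id %in% is_ids
  if (any(needs_conc & is.na(df$nominal_concentration))) {
    bad <- unique(df$metabolite_id[needs_conc & is.na(df$nominal_concentration)])
    rrfq_abort(
      sprintf("Standard rows lack nominal_concentration for: %s",
              paste(bad, collapse = ", ")),
      "rrfq_validation_error"
    )
  }
  key <- paste(df$metabolite_id, df$sample_id, df$replicate_index, df$polarity)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    rrfq_abort(
      sprintf("Duplicate measurement key(s) (metabolite, sample, replicate, polarity): %s",
              paste(head(dup, 5), collapse = "; ")),
      "rrfq_duplicate_key_error"
    )
  }
  df
}

#' Write a transition list CSV
#'
#' @param transitions Transition tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transition_list <- function(transitions, path) {
  readr::write_csv(transitions[, TRANSITION_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Write a long-format peak-area CSV
#'
#' Emits the same dialect [read_peak_areas()] consumes (the
#' `nominal_concentration` column is written as `nominal_concentration_uM`).
#'
#' @param measurements Measurement tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_areas <- function(measurements, path) {
  out <- measurements[, MEASUREMENT_COLUMNS]
  names(out)[names(out) == "replicate_index"] <- "replicate"
  names(out)[names(out) == "nominal_concentration"] <- "nominal_concentration_uM"
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a set of result tables plus a JSON summary
#'
#' Each named element of `results` is written as `<name>.csv` with a fixed
#' column order (as given) and full float precision; a machine-readable
#' `summary.json` records the table names and dimensions. Output is
#' deterministic: identical inputs produce byte-identical files.
#'
#' @param results Named list of data frames (may include empty tables).
#' @param path Output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
write_report <- function(results, path) {
  if (length(results) == 0) {
    rrfq_abort("`results` must contain at least one table.",
               "rrfq_validation_error")
  }
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    rrfq_abort("`results` must be a fully named list.", "rrfq_validation_error")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) {
    rrfq_abort(sprintf("Cannot create output directory: %s", path),
               "rrfq_io_error")
  }
  files <- character(0)
  for (nm in names(results)) {
    f <- file.path(path, paste0(nm, ".csv"))
    readr::write_csv(tibble::as_tibble(results[[nm]]), f, progress = FALSE)
    files <- c(files, f)
  }
  summary <- lapply(results, function(tb) {
    list(rows = nrow(tb), columns = names(tb))
  })
  jf <- file.path(path, "summary.json")
  jsonlite::write_json(summary, jf, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, jf))
}
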