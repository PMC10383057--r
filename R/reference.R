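cv_percent <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || m == 0) return(NA_real_)
  100 * stats::sd(x) / m
}

#' Summarise one internal standard into a reference-compound candidate
#'
#' Averages the peak area of a stable-isotope-labeled internal standard
#' across all its replicate injections (per polarity), computes the
#' coefficient of variation (sample SD, n-1), and derives the response
#' factor RF as the single-point ratio mean area / spike concentration.
#'
#' @param areas Numeric vector of peak areas for one internal standard in
#'   one polarity (at least 2 values).
#' @param spike_concentration Spike level in uM (default 1.25).
#' @param is_id,polarity Identifiers recorded on the result.
#' @return A one-row tibble: `is_id, polarity, n, mean_peak_area,
#'   cv_percent, concentration, rf`.
#' @examples
#' summarize_internal_standard(c(800, 1200), 1.25, "is_ala", "positive")
#' @export
summarize_internal_standard <- function(areas, spike_concentration = 1.25,
                                        is_id = NA_character_,
                                        polarity = NA_character_) {
  areas <- areas[is.finite(areas)]
  if (length(areas) < 2) {
    rrfq_abort("Need at least 2 measurements to summarise an internal standard.",
               "rrfq_value_error")
  }
  m <- mean(areas)
  if (m == 0) {
    rrfq_abort(sprintf("Internal standard '%s' has zero mean peak area.",
                       is_id), "rrfq_degenerate_reference_error")
  }
  tibble::tibble(
    is_id = is_id, polarity = polarity, n = length(areas),
    mean_peak_area = m, cv_percent = cv_percent(areas),
    concentration = spike_concentration, rf = m / spike_concentration
  )
}

#' Summarise all internal standards in a run
#'
#' Applies [summarize_internal_standard()] to every internal standard per
#' polarity. The CV is computed over the runs selected by
#' `config$reference_scope` (standard-series injections by default, where
#' the spike is the only analyte source), excluding blanks. With
#' `config$rf_from_slope = TRUE` the RF is instead the slope of a
#' one-level regression through the origin (areas vs the spike level).
#'
#' @param measurements Measurement tibble.
#' @param transitions Transition tibble (supplies `is_internal_standard`).
#' @param config A [run_config()].
#' @return Tibble of reference-compound candidates.
#' @export
summarize_references <- function(measurements, transitions,
                                 config = run_config()) {
  is_ids <- transitions$metabolite_id[transitions$is_internal_standard]
  scope_types <- switch(config$reference_scope,
                        standard = "standard",
                        matrix = "matrix",
                        all = setdiff(SAMPLE_TYPES, "blank"))
  sel <- measurements[measurements$metabolite_id %in% is_ids &
                        measurements$sample_type %in% scope_types, ]
  keys <- unique(sel[, c("metabolite_id", "polarity")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    areas <- sel$peak_area[sel$metabolite_id == keys$metabolite_id[i] &
                             sel$polarity == keys$polarity[i]]
    out <- summarize_internal_standard(areas, config$is_spike_concentration,
                                       keys$metabolite_id[i],
                                       keys$polarity[i])
    if (isTRUE(config$rf_from_slope)) {
      # One spike level only: least-squares through the origin reduces to
      # mean(area)/c, so this differs from the single-point RF only when a
      # nominal_concentration column carries per-sample spike levels.
      conc <- sel$nominal_concentration[sel$metabolite_id == keys$metabolite_id[i] &
                                          sel$polarity == keys$polarity[i]]
      conc[is.na(conc)] <- config$is_spike_concentration
      out$rf <- sum(conc * areas) / sum(conc^2)
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Select reference compounds by lowest peak-area CV
#'
#' Orders the internal-standard candidates by ascending coefficient of
#' variation and returns the `k` most stable ones per polarity. Ties on CV
#' break lexicographically by `is_id` so output is reproducible. If fewer
#' than `k` candidates exist, all are returned with a warning.
#'
#' @param candidates Tibble from [summarize_references()].
#' @param k Number of references to select (default 6).
#' @return The selected candidates, ascending CV within polarity.
#' @export
select_references <- function(candidates, k = 6) {
  if (nrow(candidates) == 0) {
    rrfq_abort("No internal-standard candidates to select from.",
               "rrfq_configuration_error")
  }
  picked <- candidates |>
    dplyr::group_by(.data$polarity) |>
    dplyr::arrange(.data$cv_percent, .data$is_id, .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup()
  short <- picked |>
    dplyr::count(.data$polarity) |>
    dplyr::filter(.data$n < k)
  if (nrow(short) > 0) {
    rrfq_warn(sprintf(
      "Fewer than %d internal standards available in polarity: %s",
      k, paste(short$polarity, collapse = ", ")),
      "rrfq_reference_shortage_warning")
  }
  picked
}

#' Relative response factor of one metabolite against one reference
#'
#' The RRF is the dimensionless ratio of the metabolite's calibration slope
#' (area per uM) to the reference compound's response factor (area per uM):
#' `RRF = slope / RF`. It captures the metabolite's ionization efficiency
#' relative to the reference and is the portable quantity that enables
#' single-point quantification.
#'
#' @param curve A quantifiable `calibration_curve`.
#' @param reference One-row tibble (or list) with `is_id`, `polarity`, `rf`.
#' @return One-row tibble: `metabolite_id, reference_id, polarity, rrf`.
#' @export
compute_rrf <- function(curve, reference) {
  if (!isTRUE(curve$quantifiable)) {
    rrfq_abort(sprintf("Curve for '%s' is not quantifiable (%s).",
                       curve$metabolite_id, curve$reason),
               "rrfq_contract_error")
  }
  if (!identical(curve$polarity, reference$polarity)) {
    rrfq_abort(sprintf("Polarity mismatch: curve %s vs reference %s.",
                       curve$polarity, reference$polarity),
               "rrfq_contract_error")
  }
  if (!is.finite(reference$rf) || reference$rf <= 0) {
    rrfq_abort(sprintf("Reference '%s' has non-positive RF.",
                       reference$is_id),
               "rrfq_degenerate_reference_error")
  }
  tibble::tibble(
    metabolite_id = curve$metabolite_id,
    reference_id = reference$is_id,
    polarity = curve$polarity,
    rrf = curve$slope / reference$rf
  )
}

#' Build the full RRF table
#'
#' One RRF per (quantifiable metabolite, reference) pair within each
#' polarity. Non-quantifiable metabolites are skipped (their ids and
#' reasons are attached as the `skipped` attribute). This table, together
#' with the calibration report, is the portable quantitative-library
#' payload.
#'
#' @param curves Named list of `calibration_curve` objects (from
#'   [calibrate_run()]).
#' @param references Selected reference tibble from [select_references()].
#' @return Tibble `metabolite_id, reference_id, polarity, rrf` with
#'   attribute `skipped`.
#' @export
build_rrf_table <- function(curves, references) {
  if (nrow(references) == 0) {
    rrfq_abort("Empty reference table.", "rrfq_configuration_error")
  }
  rows <- list(); skipped <- list()
  for (cv in curves) {
    if (!isTRUE(cv$quantifiable)) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        metabolite_id = cv$metabolite_id, polarity = cv$polarity,
        reason = cv$reason)
      next
    }
    refs <- references[references$polarity == cv$polarity, ]
    for (j in seq_len(nrow(refs))) {
      rows[[length(rows) + 1]] <- compute_rrf(cv, refs[j, ])
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    rrfq_warn("No quantifiable metabolites: RRF table is empty.",
              "rrfq_empty_table_warning")
    out <- tibble::tibble(metabolite_id = character(0),
                          reference_id = character(0),
                          polarity = character(0), rrf = numeric(0))
  }
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}
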