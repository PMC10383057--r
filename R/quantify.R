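#' Quantify a peak area by external calibration
#'
#' Inverts the fitted standard curve: `c = (area - intercept) / slope`.
#' Negative results are returned as-is (flagging, not clamping, keeps CV
#' summaries unbiased).
#'
#' @param peak_area Observed peak area(s).
#' @param curve A quantifiable `calibration_curve`.
#' @return Concentration(s) in uM.
#' @export
quantify_ec <- function(peak_area, curve) {
  if (!isTRUE(curve$quantifiable)) {
    rrfq_abort(sprintf("Curve for '%s' is not quantifiable (%s).",
                       curve$metabolite_id, curve$reason),
               "rrfq_contract_error")
  }
  (peak_area - curve$intercept) / curve$slope
}

#' Quantify a peak area by single-point RRF calibration
#'
#' The internal-calibration estimate
#' `c = (area_compound * c_reference) / (area_reference * RRF)`:
#' the analyte area is scaled to concentration via the co-injected
#' reference compound measured in the same sample, corrected by the
#' analyte's relative response factor. Any response attenuation shared by
#' analyte and reference (matrix suppression, drift) cancels in the area
#' ratio.
#'
#' @param peak_area Analyte peak area(s).
#' @param reference_area Reference-compound peak area(s) from the same
#'   injection; must be positive.
#' @param reference_concentration Reference spike concentration in uM.
#' @param rrf The analyte's RRF against this reference (dimensionless).
#' @return Concentration(s) in uM.
#' @examples
#' quantify_rrf(500, 1000, 1.25, 0.5) # 1.25
#' @export
quantify_rrf <- function(peak_area, reference_area, reference_concentration,
                         rrf) {
  if (any(!is.finite(reference_area) | reference_area <= 0)) {
    rrfq_abort("Reference peak area must be positive for RRF quantification.",
               "rrfq_undefined_quantification_error")
  }
  if (any(!is.finite(rrf) | rrf <= 0)) {
    rrfq_abort("RRF must be positive.", "rrfq_value_error")
  }
  (peak_area * reference_concentration) / (reference_area * rrf)
}

#' Replicate coefficient of variation of quantified concentrations
#'
#' @param concentrations Numeric vector (>= 2 replicates) of concentration
#'   estimates for one metabolite, sample and method.
#' @return CV in percent; `NA_real_` (flagged undefined) when the mean is 0.
#' @export
replicate_cv <- function(concentrations) {
  if (length(concentrations) < 2) {
    rrfq_abort("Need at least 2 replicates for a CV.", "rrfq_value_error")
  }
  cv_percent(concentrations)
}

#' Ion suppression of a compound in matrix versus pure solvent
#'
#' `suppression = 100 * (1 - area_matrix / area_solvent)` percent: the
#' fraction of ESI response lost in the biological matrix relative to neat
#' solvent. Negative values indicate ionization enhancement and are
#' flagged, not dropped.
#'
#' @param area_matrix Mean peak area(s) in the matrix sample.
#' @param area_solvent Mean peak area(s) in pure solvent (must be positive).
#' @return A tibble: `suppression_percent`, `enhancement` flag (one row per
#'   input pair).
#' @examples
#' ion_suppression(250, 1000) # 75 percent suppression
#' @export
ion_suppression <- function(area_matrix, area_solvent) {
  if (any(!is.finite(area_solvent) | area_solvent <= 0)) {
    rrfq_abort("Solvent reference area must be positive.",
               "rrfq_undefined_quantification_error")
  }
  s <- 100 * (1 - area_matrix / area_solvent)
  tibble::tibble(suppression_percent = s, enhancement = s < 0)
}

#' Ion-suppression table for a measurement set
#'
#' Compares each compound's mean area in `matrix` samples with its mean
#' area in paired `solvent_reference` samples, per polarity.
#'
#' @param measurements Measurement tibble containing both sample types.
#' @param compound_ids Optional subset of compounds (default: all present
#'   in both sample types).
#' @return Tibble `compound_id, polarity, area_matrix, area_solvent,
#'   suppression_percent, enhancement`.
#' @export
ion_suppression_table <- function(measurements, compound_ids = NULL) {
  mm <- measurements[measurements$sample_type %in%
                       c("matrix", "solvent_reference"), ]
  if (!is.null(compound_ids)) {
    mm <- mm[mm$metabolite_id %in% compound_ids, ]
  }
  means <- mm |>
    dplyr::group_by(.data$metabolite_id, .data$polarity, .data$sample_type) |>
    dplyr::summarise(area = mean(.data$peak_area), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample_type", values_from = "area")
  if (!all(c("matrix", "solvent_reference") %in% names(means))) {
    rrfq_warn("Need both matrix and solvent_reference samples for suppression.",
              "rrfq_empty_table_warning")
    return(tibble::tibble(compound_id = character(0), polarity = character(0),
                          area_matrix = numeric(0), area_solvent = numeric(0),
                          suppression_percent = numeric(0),
                          enhancement = logical(0)))
  }
  means <- means[is.finite(means$matrix) & is.finite(means$solvent_reference), ]
  sup <- ion_suppression(means$matrix, means$solvent_reference)
  tibble::tibble(
    compound_id = means$metabolite_id, polarity = means$polarity,
    area_matrix = means$matrix, area_solvent = means$solvent_reference,
    suppression_percent = sup$suppression_percent,
    enhancement = sup$enhancement
  )
}

#' Quantify every sample by external calibration and by RRF
#'
#' For each measurement of a quantifiable metabolite in the selected sample
#' types, produces one `EC` record (curve inversion) and one
#' `RRF:<reference_id>` record per reference whose area is available in the
#' same sample. Reference areas are paired per injection
#' (`sample_id`, `replicate_index`) by default, or per-sample mean with
#' `config$rrf_reference_area = "mean"`. When the analyte's own heavy-
#' labeled form is among the references, that record is additionally tagged
#' `isotope_matched`.
#'
#' Truth for accuracy comes from `nominal_concentration` (standards) or an
#' optional `truth` table (`metabolite_id, sample_id, true_concentration`).
#'
#' @param measurements Measurement tibble.
#' @param curves Named list of `calibration_curve` objects.
#' @param references Selected reference tibble.
#' @param rrf_table RRF tibble from [build_rrf_table()].
#' @param config A [run_config()].
#' @param sample_types Sample types to quantify (default `standard` and
#'   `matrix`).
#' @param truth Optional truth table for synthetic/known samples.
#' @return Tibble of quantification records: `metabolite_id, sample_id,
#'   replicate_index, polarity, method, reference_id, isotope_matched,
#'   concentration, truth, accuracy_percent, below_zero`.
#' @export
quantify_run <- function(measurements, curves, references, rrf_table,
                         config = run_config(),
                         sample_types = c("standard", "matrix"),
                         truth = NULL) {
  is_ids <- unique(references$is_id)
  target <- measurements[measurements$sample_type %in% sample_types &
                           !measurements$metabolite_id %in% is_ids, ]
  ref_meas <- measurements[measurements$metabolite_id %in% is_ids &
                             measurements$sample_type %in% sample_types, ]
  if (identical(config$rrf_reference_area, "mean")) {
    ref_meas <- ref_meas |>
      dplyr::group_by(.data$metabolite_id, .data$sample_id, .data$polarity) |>
      dplyr::summarise(peak_area = mean(.data$peak_area), .groups = "drop")
  }
  rows <- list()
  for (i in seq_len(nrow(target))) {
    m <- target[i, ]
    key <- paste(m$metabolite_id, m$polarity, sep = "|")
    cv <- curves[[key]]
    if (is.null(cv) || !isTRUE(cv$quantifiable)) next
    tr <- if (m$sample_type == "standard") {
      m$nominal_concentration
    } else if (!is.null(truth)) {
      hit <- truth$true_concentration[
        truth$metabolite_id == m$metabolite_id &
          truth$sample_id == m$sample_id]
      if (length(hit) == 1) hit else NA_real_
    } else NA_real_

    conc_ec <- quantify_ec(m$peak_area, cv)
    rows[[length(rows) + 1]] <- tibble::tibble(
      metabolite_id = m$metabolite_id, sample_id = m$sample_id,
      replicate_index = m$replicate_index, polarity = m$polarity,
      method = "EC", reference_id = NA_character_,
      isotope_matched = FALSE, concentration = conc_ec, truth = tr,
      accuracy_percent = ifelse(is.na(tr), NA_real_, 100 * conc_ec / tr),
      below_zero = conc_ec < 0
    )

    entries <- rrf_table[rrf_table$metabolite_id == m$metabolite_id &
                           rrf_table$polarity == m$polarity, ]
    for (j in seq_len(nrow(entries))) {
      e <- entries[j, ]
      ref <- references[references$is_id == e$reference_id &
                          references$polarity == e$polarity, ]
      ra <- if (identical(config$rrf_reference_area, "mean")) {
        ref_meas$peak_area[ref_meas$metabolite_id == e$reference_id &
                             ref_meas$sample_id == m$sample_id &
                             ref_meas$polarity == m$polarity]
      } else {
        ref_meas$peak_area[ref_meas$metabolite_id == e$reference_id &
                             ref_meas$sample_id == m$sample_id &
                             ref_meas$replicate_index == m$replicate_index &
                             ref_meas$polarity == m$polarity]
      }
      if (length(ra) != 1 || !is.finite(ra) || ra <= 0) next
      conc <- quantify_rrf(m$peak_area, ra, ref$concentration[1], e$rrf)
      rows[[length(rows) + 1]] <- tibble::tibble(
        metabolite_id = m$metabolite_id, sample_id = m$sample_id,
        replicate_index = m$replicate_index, polarity = m$polarity,
        method = paste0("RRF:", e$reference_id),
        reference_id = e$reference_id,
        isotope_matched = is_isotope_match(m$metabolite_id, e$reference_id),
        concentration = conc, truth = tr,
        accuracy_percent = ifelse(is.na(tr), NA_real_, 100 * conc / tr),
        below_zero = conc < 0
      )
    }
  }
  dplyr::bind_rows(rows)
}

# A reference is "isotope-matched" to an analyte when its id is the analyte
# id plus a stable-isotope label suffix/prefix (is_<id>, <id>_13c, <id>_d<n>,
# <id>_15n), the convention used by the synthetic generator and typical
# heavy-standard naming.
is_isotope_match <- function(metabolite_id, reference_id) {
  ref <- tolower(reference_id); met <- tolower(metabolite_id)
  stripped <- sub("^is_", "", ref)
  stripped <- sub("_(13c|15n|d[0-9]+|heavy)$", "", stripped)
  identical(stripped, met)
}

#' Per-group replicate CV of quantified concentrations
#'
#' @param quant Quantification tibble from [quantify_run()].
#' @return Tibble `metabolite_id, sample_id, polarity, method, n,
#'   cv_percent` for groups with >= 2 replicates.
#' @export
replicate_cv_table <- function(quant) {
  quant |>
    dplyr::add_count(.data$metabolite_id, .data$sample_id, .data$polarity,
                     .data$method) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::select(-"n") |>
    dplyr::group_by(.data$metabolite_id, .data$sample_id, .data$polarity,
                    .data$method) |>
    dplyr::summarise(n = dplyr::n(),
                     cv_percent = cv_percent(.data$concentration),
                     .groups = "drop")
}

#' Compare external-calibration and RRF quantification
#'
#' Summarises the accuracy distribution of each method (median accuracy and
#' the fraction of records within the reporting band, default 80--120
#' percent, where truth is known) and the per-metabolite concentration
#' ratio RRF/EC.
#'
#' @param quant Quantification tibble from [quantify_run()] (EC and RRF
#'   records together).
#' @param accuracy_band Two-element percent band (default `c(80, 120)`).
#' @return List with `method_summary` and `ratio_table` tibbles.
#' @export
compare_methods <- function(quant, accuracy_band = c(80, 120)) {
  if (nrow(quant) == 0 || dplyr::n_distinct(quant$method) < 2) {
    rrfq_warn("Method comparison needs both EC and RRF records.",
              "rrfq_empty_table_warning")
    return(list(method_summary = tibble::tibble(), ratio_table = tibble::tibble()))
  }
  method_summary <- quant |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_concentration = median(.data$concentration),
      median_accuracy_percent = median(.data$accuracy_percent, na.rm = TRUE),
      fraction_in_band = mean(
        .data$accuracy_percent >= accuracy_band[1] &
          .data$accuracy_percent <= accuracy_band[2], na.rm = TRUE),
      .groups = "drop"
    )
  per_met <- quant |>
    dplyr::mutate(approach = ifelse(.data$method == "EC", "EC", "RRF")) |>
    dplyr::group_by(.data$metabolite_id, .data$polarity, .data$approach) |>
    dplyr::summarise(mean_concentration = mean(.data$concentration),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "approach",
                       values_from = "mean_concentration")
  ratio_table <- if (all(c("EC", "RRF") %in% names(per_met))) {
    per_met |>
      dplyr::mutate(rrf_over_ec = .data$RRF / .data$EC) |>
      dplyr::select("metabolite_id", "polarity", "EC", "RRF", "rrf_over_ec")
  } else tibble::tibble()
  list(method_summary = method_summary, ratio_table = ratio_table)
}
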