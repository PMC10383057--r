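PPM_BIN_BREAKS <- c(0, 0.5, 1, 2, Inf)
PPM_BIN_LABELS <- c("<0.5", "0.5-1", "1-2", ">2")
CV_BIN_BREAKS <- c(0, 5, 10, 15, 20, Inf)
CV_BIN_LABELS <- c("<5", "5-10", "10-15", "15-20", ">20")

#' Mass-accuracy summary in ppm
#'
#' Joins observed m/z values against the transition list and reports the
#' signed and absolute ppm error per metabolite (mean over measurements
#' with an observed m/z), binned into the reporting categories
#' `<0.5, 0.5-1, 1-2, >2` ppm.
#'
#' @param measurements Measurement tibble (rows without `observed_mz` are
#'   skipped).
#' @param transitions Transition tibble.
#' @return List with `per_metabolite` tibble and `bins` count tibble.
#' @export
mass_error_summary <- function(measurements, transitions) {
  mm <- measurements[is.finite(measurements$observed_mz), ]
  mm <- dplyr::left_join(
    mm, transitions[, c("metabolite_id", "polarity", "theoretical_mz")],
    by = c("metabolite_id", "polarity"))
  per <- mm |>
    dplyr::group_by(.data$metabolite_id, .data$polarity) |>
    dplyr::summarise(
      mean_ppm = mean(mass_error_ppm(.data$observed_mz, .data$theoretical_mz)),
      mean_abs_ppm = mean(abs(mass_error_ppm(.data$observed_mz,
                                             .data$theoretical_mz))),
      .groups = "drop")
  bins <- tibble::tibble(
    bin = factor(PPM_BIN_LABELS, levels = PPM_BIN_LABELS),
    count = as.integer(table(cut(per$mean_abs_ppm, PPM_BIN_BREAKS,
                                 labels = PPM_BIN_LABELS, right = FALSE)))
  )
  list(per_metabolite = per, bins = bins)
}

#' Retention-time deviation across runs
#'
#' Per metabolite: `100 * (max - min) / median` of observed RTs across
#' runs, plus an out-of-window flag whenever any run's RT differs from the
#' expected RT by more than the matching tolerance (default +/-0.7 min).
#' Metabolites observed in a single run are skipped (deviation undefined).
#'
#' @param measurements Measurement tibble with `observed_rt`.
#' @param transitions Transition tibble supplying `expected_rt`.
#' @param rt_tolerance_min RT matching window in minutes (default 0.7).
#' @return Tibble `metabolite_id, polarity, n_runs, rt_deviation_percent,
#'   max_abs_shift_min, out_of_window`.
#' @export
rt_deviation <- function(measurements, transitions, rt_tolerance_min = 0.7) {
  mm <- measurements[is.finite(measurements$observed_rt), ]
  mm <- dplyr::left_join(
    mm, transitions[, c("metabolite_id", "polarity", "expected_rt")],
    by = c("metabolite_id", "polarity"))
  mm <- mm |>
    dplyr::add_count(.data$metabolite_id, .data$polarity) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::select(-"n")
  if (nrow(mm) == 0) {
    return(tibble::tibble(metabolite_id = character(0),
                          polarity = character(0), n_runs = integer(0),
                          rt_deviation_percent = numeric(0),
                          max_abs_shift_min = numeric(0),
                          out_of_window = logical(0)))
  }
  mm |>
    dplyr::group_by(.data$metabolite_id, .data$polarity) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      rt_deviation_percent =
        100 * (max(.data$observed_rt) - min(.data$observed_rt)) /
          median(.data$observed_rt),
      max_abs_shift_min = max(abs(.data$observed_rt - .data$expected_rt)),
      out_of_window = any(abs(.data$observed_rt - .data$expected_rt) >
                            rt_tolerance_min),
      .groups = "drop")
}

#' Peak-area CV distribution across metabolites
#'
#' Computes the replicate CV of peak areas per metabolite within each
#' sample and averages over samples, then bins metabolites into the
#' reporting categories `<5, 5-10, 10-15, 15-20, >20` percent. Zero-mean
#' groups get an undefined (NA) CV and are excluded from the bins.
#'
#' @param measurements Measurement tibble.
#' @param sample_types Which sample types to include (default `standard`).
#' @return List with `per_metabolite` tibble and `bins` count tibble.
#' @export
peak_area_cv_summary <- function(measurements, sample_types = "standard") {
  mm <- measurements[measurements$sample_type %in% sample_types, ]
  per <- mm |>
    dplyr::add_count(.data$metabolite_id, .data$polarity, .data$sample_id) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::select(-"n") |>
    dplyr::group_by(.data$metabolite_id, .data$polarity, .data$sample_id) |>
    dplyr::summarise(cv = cv_percent(.data$peak_area), .groups = "drop") |>
    dplyr::group_by(.data$metabolite_id, .data$polarity) |>
    dplyr::summarise(mean_cv_percent = mean(.data$cv), .groups = "drop")
  defined <- per$mean_cv_percent[is.finite(per$mean_cv_percent)]
  bins <- tibble::tibble(
    bin = factor(CV_BIN_LABELS, levels = CV_BIN_LABELS),
    count = as.integer(table(cut(defined, CV_BIN_BREAKS,
                                 labels = CV_BIN_LABELS, right = FALSE)))
  )
  list(per_metabolite = per, bins = bins)
}

#' Run-level QC metrics for system-suitability tracking
#'
#' Collapses one run's measurement table into the tracked parameters:
#' total integrated area (TIC-like), median absolute mass error, and
#' median RT shift versus the expected RTs.
#'
#' @param measurements One run's measurement tibble.
#' @param transitions Transition tibble.
#' @return One-row tibble of metrics.
#' @export
run_qc_metrics <- function(measurements, transitions) {
  tr <- transitions[, c("metabolite_id", "polarity", "theoretical_mz",
                        "expected_rt")]
  mm <- dplyr::left_join(measurements, tr,
                         by = c("metabolite_id", "polarity"))
  ppm <- abs(mass_error_ppm(mm$observed_mz[is.finite(mm$observed_mz)],
                            mm$theoretical_mz[is.finite(mm$observed_mz)]))
  shift <- abs(mm$observed_rt - mm$expected_rt)
  tibble::tibble(
    tic_like_total_area = sum(mm$peak_area),
    median_abs_mass_error_ppm = if (length(ppm)) median(ppm) else NA_real_,
    median_abs_rt_shift_min = if (any(is.finite(shift))) {
      median(shift[is.finite(shift)])
    } else NA_real_
  )
}

#' Compare a run's QC metrics against its history
#'
#' Each metric is compared to the rolling median of up to the last
#' `history_window` prior runs. A metric is flagged when it departs from
#' the baseline by more than its band: a relative band (percent) for the
#' TIC-like area, an absolute band in ppm for mass error, an absolute band
#' in minutes for RT shift. With no history every metric passes with a
#' "no baseline" note.
#'
#' @param current One-row metrics tibble from [run_qc_metrics()].
#' @param history Metrics tibble of prior runs (0+ rows, same columns).
#' @param area_band_percent Relative band for total area (default 30).
#' @param mass_band_ppm Absolute band for mass error (default 5).
#' @param rt_band_min Absolute band for RT shift (default 0.7).
#' @param history_window Number of most recent runs in the baseline
#'   (default 20).
#' @return Tibble `metric, value, baseline, flagged, note`.
#' @export
autoqc_compare <- function(current, history,
                           area_band_percent = 30,
                           mass_band_ppm = 5,
                           rt_band_min = 0.7,
                           history_window = 20) {
  specs <- list(
    list(metric = "tic_like_total_area", type = "relative",
         band = area_band_percent),
    list(metric = "median_abs_mass_error_ppm", type = "absolute",
         band = mass_band_ppm),
    list(metric = "median_abs_rt_shift_min", type = "absolute",
         band = rt_band_min)
  )
  rows <- lapply(specs, function(sp) {
    value <- current[[sp$metric]][1]
    hist_vals <- if (nrow(history) > 0) {
      utils::tail(history[[sp$metric]], history_window)
    } else numeric(0)
    hist_vals <- hist_vals[is.finite(hist_vals)]
    if (length(hist_vals) == 0) {
      return(tibble::tibble(metric = sp$metric, value = value,
                            baseline = NA_real_, flagged = FALSE,
                            note = "no baseline"))
    }
    base <- median(hist_vals)
    flagged <- if (!is.finite(value)) {
      FALSE
    } else if (sp$type == "relative") {
      abs(value - base) > sp$band / 100 * base
    } else {
      abs(value - base) > sp$band
    }
    tibble::tibble(metric = sp$metric, value = value, baseline = base,
                   flagged = flagged, note = "")
  })
  dplyr::bind_rows(rows)
}
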