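# File-oriented pipeline stages. Each stage reads the CSV artifacts of the
# previous ones, runs the engine, and writes its outputs with write_report()
# so an identical config and inputs give byte-identical files. The effective
# config is echoed into every output directory for provenance.

write_effective_config <- function(config, out_dir) {
  cfg <- unclass(config)
  yaml::write_yaml(cfg, file.path(out_dir, "config_used.yaml"))
}

#' Stage: generate a synthetic dataset
#'
#' Writes the transition list, the standard-series peak-area table,
#' optionally a suppressed matrix + solvent pair, and the ground-truth
#' tables for a named preset.
#'
#' @param out_dir Output directory.
#' @param preset Preset name for [scenario_presets()].
#' @param n_metabolites Number of analytes.
#' @param seed Integer seed.
#' @param levels Optional override of the standard-series concentrations.
#' @param with_matrix If `TRUE`, also generate one matrix/solvent sample
#'   pair with true concentrations drawn log-uniformly over the series
#'   range.
#' @return Invisible list of the generated objects.
#' @export
rrfq_synth <- function(out_dir, preset = "clean", n_metabolites = 20,
                       seed = 1L, levels = NULL, with_matrix = FALSE) {
  spec <- scenario_presets(preset, n_metabolites = n_metabolites, seed = seed)
  if (!is.null(levels)) spec$levels <- sort(levels)
  std <- generate_standard_series(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_transition_list(std$transitions, file.path(out_dir, "transitions.csv"))
  meas <- std$measurements
  truth_tables <- list(truth = std$truth)
  if (with_matrix) {
    tc <- run_with_seed(spec$seed + 5L, stats::setNames(
      exp(runif(spec$n_metabolites, log(min(spec$levels) * 10),
                log(max(spec$levels) / 2))),
      spec$metabolite_ids))
    mat <- generate_matrix_samples(spec, tc)
    meas <- dplyr::bind_rows(meas, mat$measurements)
    truth_tables$sample_truth <- mat$sample_truth
  }
  write_peak_areas(meas, file.path(out_dir, "peak_areas.csv"))
  write_report(truth_tables, out_dir)
  invisible(list(spec = spec, transitions = std$transitions,
                 measurements = meas))
}

#' Stage: fit calibration curves
#'
#' @param transitions_csv,peak_areas_csv Input file paths.
#' @param out_dir Output directory (gets `calibration.csv` + summary).
#' @param config A [run_config()].
#' @return The calibration report tibble, invisibly.
#' @export
rrfq_calibrate <- function(transitions_csv, peak_areas_csv, out_dir,
                           config = run_config()) {
  transitions <- read_transition_list(transitions_csv)
  measurements <- read_peak_areas(peak_areas_csv, transitions)
  cal <- calibrate_run(measurements, transitions, config)
  write_report(list(calibration = cal$report), out_dir)
  write_effective_config(config, out_dir)
  invisible(cal$report)
}

#' Stage: select references and build the RRF table
#'
#' @param transitions_csv,peak_areas_csv,calibration_csv Input file paths.
#' @param out_dir Output directory (gets `references.csv`, `rrf_table.csv`).
#' @param config A [run_config()].
#' @return List with `references` and `rrf_table`, invisibly.
#' @export
rrfq_rrf <- function(transitions_csv, peak_areas_csv, calibration_csv,
                     out_dir, config = run_config()) {
  transitions <- read_transition_list(transitions_csv)
  measurements <- read_peak_areas(peak_areas_csv, transitions)
  report <- readr::read_csv(calibration_csv, show_col_types = FALSE,
                            progress = FALSE)
  curves <- curves_from_report(report)
  refs <- select_references(summarize_references(measurements, transitions,
                                                 config),
                            k = config$n_references)
  rrf_table <- build_rrf_table(curves, refs)
  write_report(list(references = refs, rrf_table = rrf_table), out_dir)
  write_effective_config(config, out_dir)
  invisible(list(references = refs, rrf_table = rrf_table))
}

#' Stage: quantify samples by EC and RRF
#'
#' @param transitions_csv,peak_areas_csv,calibration_csv,references_csv,rrf_table_csv
#'   Input file paths.
#' @param out_dir Output directory (gets `quantification.csv`,
#'   `replicate_cv.csv`, `method_summary.csv`, `ratio_table.csv`,
#'   `suppression.csv`).
#' @param config A [run_config()].
#' @param sample_types Sample types to quantify.
#' @param truth_csv Optional per-sample truth table
#'   (`metabolite_id, sample_id, true_concentration`).
#' @return The quantification tibble, invisibly.
#' @export
rrfq_quantify <- function(transitions_csv, peak_areas_csv, calibration_csv,
                          references_csv, rrf_table_csv, out_dir,
                          config = run_config(),
                          sample_types = c("standard", "matrix"),
                          truth_csv = NULL) {
  transitions <- read_transition_list(transitions_csv)
  measurements <- read_peak_areas(peak_areas_csv, transitions)
  curves <- curves_from_report(
    readr::read_csv(calibration_csv, show_col_types = FALSE, progress = FALSE))
  references <- readr::read_csv(references_csv, show_col_types = FALSE,
                                progress = FALSE)
  rrf_table <- readr::read_csv(rrf_table_csv, show_col_types = FALSE,
                               progress = FALSE)
  truth <- if (!is.null(truth_csv)) {
    readr::read_csv(truth_csv, show_col_types = FALSE, progress = FALSE)
  } else NULL
  quant <- quantify_run(measurements, curves, references, rrf_table, config,
                        sample_types = sample_types, truth = truth)
  cmp <- tryCatch(compare_methods(quant),
                  rrfq_warning = function(w) {
                    list(method_summary = tibble::tibble(),
                         ratio_table = tibble::tibble())
                  })
  sup <- withCallingHandlers(
    ion_suppression_table(measurements),
    rrfq_warning = function(w) invokeRestart("muffleWarning"))
  write_report(list(quantification = quant,
                    replicate_cv = replicate_cv_table(quant),
                    method_summary = cmp$method_summary,
                    ratio_table = cmp$ratio_table,
                    suppression = sup), out_dir)
  write_effective_config(config, out_dir)
  invisible(quant)
}

#' Stage: QC metrics and system-suitability comparison
#'
#' @param transitions_csv,peak_areas_csv Input file paths.
#' @param out_dir Output directory.
#' @param history_csv Optional CSV of prior-run metrics
#'   (columns as [run_qc_metrics()]).
#' @param config A [run_config()].
#' @param strict If `TRUE`, raise an error when any AutoQC metric is
#'   flagged (CI-friendly gate; the CLI maps this onto a nonzero exit).
#' @return List of QC tables, invisibly.
#' @export
rrfq_qc <- function(transitions_csv, peak_areas_csv, out_dir,
                    history_csv = NULL, config = run_config(),
                    strict = FALSE) {
  transitions <- read_transition_list(transitions_csv)
  measurements <- read_peak_areas(peak_areas_csv, transitions)
  mass <- mass_error_summary(measurements, transitions)
  rt <- rt_deviation(measurements, transitions, config$rt_tolerance_min)
  area_cv <- peak_area_cv_summary(measurements)
  metrics <- run_qc_metrics(measurements, transitions)
  history <- if (!is.null(history_csv) && file.exists(history_csv)) {
    readr::read_csv(history_csv, show_col_types = FALSE, progress = FALSE)
  } else metrics[0, ]
  flags <- autoqc_compare(metrics, history)
  write_report(list(mass_error = mass$per_metabolite,
                    mass_error_bins = mass$bins,
                    rt_deviation = rt,
                    peak_area_cv = area_cv$per_metabolite,
                    peak_area_cv_bins = area_cv$bins,
                    run_metrics = metrics,
                    autoqc_flags = flags), out_dir)
  if (strict && any(flags$flagged)) {
    rrfq_abort(
      sprintf("AutoQC flag(s) raised for: %s",
              paste(flags$metric[flags$flagged], collapse = ", ")),
      "rrfq_qc_flag_error"
    )
  }
  invisible(list(mass_error = mass, rt_deviation = rt,
                 peak_area_cv = area_cv, run_metrics = metrics,
                 autoqc_flags = flags))
}
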