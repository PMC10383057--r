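# Default 8-level standard series (uM) used throughout: a 3.5-decade dilution
# range typical of targeted metabolomics validation.
DEFAULT_LEVELS <- c(0.03, 0.3, 3, 6, 12, 25, 50, 100)

#' Pipeline run configuration
#'
#' Collects every tunable parameter of the quantification engine with its
#' default. Defaults mirror the validated workflow: 1/x-weighted calibration,
#' a +/-15 percent back-calculation bias filter, an R-squared gate of 0.9,
#' at least 3 surviving concentration levels, an RT matching window of
#' +/-0.7 min, six reference compounds, an S/N threshold of 2 for the LOD,
#' and internal standards spiked at 1.25 uM.
#'
#' @param weighting Calibration weighting scheme: `"1/x"` (default),
#'   `"1/x^2"`, or `"none"`.
#' @param bias_limit_percent Half-width of the accepted back-calculation
#'   accuracy band around 100 percent (default 15, i.e. 85--115 percent,
#'   closed interval).
#' @param r2_gate Minimum weighted R-squared for a metabolite to be
#'   quantifiable (default 0.9, strict inequality).
#' @param min_points Minimum number of surviving concentration levels
#'   (default 3).
#' @param rt_tolerance_min Retention-time matching window in minutes
#'   (default 0.7).
#' @param n_references Number of reference compounds selected among internal
#'   standards (default 6).
#' @param sn_lod_threshold Signal-to-noise multiple defining the LOD
#'   (default 2).
#' @param concentration_levels Ordered standard-series concentrations in uM.
#' @param is_spike_concentration Internal-standard spike concentration in uM
#'   (default 1.25).
#' @param reference_scope Which runs feed the internal-standard CV used for
#'   reference selection: `"standard"` (default), `"matrix"`, or `"all"`.
#' @param rf_from_slope If `TRUE`, reference RFs come from a fitted
#'   internal-standard calibration slope rather than the single-point
#'   area/concentration ratio (sensitivity analysis; default `FALSE`).
#' @param rrf_reference_area `"replicate"` (default) pairs each analyte
#'   measurement with the reference area from the same injection;
#'   `"mean"` uses the mean reference area per sample.
#' @param seed Integer seed controlling all randomness.
#' @return A list with class `rrfq_config`.
#' @examples
#' cfg <- run_config(weighting = "1/x", seed = 7)
#' cfg$bias_limit_percent
#' @export
run_config <- function(weighting = c("1/x", "1/x^2", "none"),
                       bias_limit_percent = 15,
                       r2_gate = 0.9,
                       min_points = 3,
                       rt_tolerance_min = 0.7,
                       n_references = 6,
                       sn_lod_threshold = 2,
                       concentration_levels = DEFAULT_LEVELS,
                       is_spike_concentration = 1.25,
                       reference_scope = c("standard", "matrix", "all"),
                       rf_from_slope = FALSE,
                       rrf_reference_area = c("replicate", "mean"),
                       seed = 1L) {
  weighting <- normalize_weighting(if (length(weighting) > 1) weighting[1] else weighting)
  reference_scope <- match.arg(reference_scope)
  rrf_reference_area <- match.arg(rrf_reference_area)
  if (bias_limit_percent <= 0) {
    rrfq_abort("`bias_limit_percent` must be positive.", "rrfq_config_error")
  }
  if (min_points < 2) {
    rrfq_abort("`min_points` must be at least 2.", "rrfq_config_error")
  }
  if (n_references < 1) {
    rrfq_abort("`n_references` must be at least 1.", "rrfq_config_error")
  }
  if (is_spike_concentration <= 0) {
    rrfq_abort("`is_spike_concentration` must be positive.", "rrfq_config_error")
  }
  structure(
    list(
      weighting = weighting,
      bias_limit_percent = bias_limit_percent,
      r2_gate = r2_gate,
      min_points = as.integer(min_points),
      rt_tolerance_min = rt_tolerance_min,
      n_references = as.integer(n_references),
      sn_lod_threshold = sn_lod_threshold,
      concentration_levels = sort(concentration_levels),
      is_spike_concentration = is_spike_concentration,
      reference_scope = reference_scope,
      rf_from_slope = rf_from_slope,
      rrf_reference_area = rrf_reference_area,
      seed = as.integer(seed)
    ),
    class = "rrfq_config"
  )
}

normalize_weighting <- function(weighting) {
  w <- tolower(gsub("²", "2", weighting))
  w <- switch(w,
    "1/x" = "1/x",
    "1/x2" = , "1/x^2" = , "1/xx" = "1/x^2",
    "none" = , "1" = "none",
    rrfq_abort(
      sprintf("Unknown weighting '%s' (use '1/x', '1/x^2' or 'none').",
              weighting),
      "rrfq_config_error"
    )
  )
  w
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; absent keys keep their
#' defaults, unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `rrfq_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    rrfq_abort(sprintf("Config file not found: %s", path), "rrfq_io_error")
  }
  values <- yaml::read_yaml(path)
  if (is.null(values)) values <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(values), known)
  if (length(unknown) > 0) {
    rrfq_abort(
      sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
      "rrfq_config_error"
    )
  }
  do.call(run_config, values)
}

#' @export
print.rrfq_config <- function(x, ...) {
  cat("<rrfq_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
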