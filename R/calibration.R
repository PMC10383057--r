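weight_vector <- function(x, weighting) {
  switch(weighting,
    "1/x"   = 1 / x,
    "1/x^2" = 1 / x^2,
    "none"  = rep(1, length(x)),
    rrfq_abort(sprintf("Unknown weighting '%s'.", weighting),
               "rrfq_config_error")
  )
}

#' Weighted straight-line fit
#'
#' Fits `y = intercept + slope * x` minimising the weighted sum of squared
#' residuals with weights `1/x`, `1/x^2`, or `1` per point. This is the
#' calibration model used for external standard curves: 1/x weighting keeps
#' the low end of a multi-decade series from being swamped by the top
#' levels when the noise is proportional to the signal.
#'
#' The reported R-squared is the weighted coefficient of determination
#' `1 - sum(w e^2) / sum(w (y - ybar_w)^2)` with `ybar_w` the weighted mean.
#'
#' @param x Concentrations (uM); must contain at least two distinct values
#'   and be strictly positive for the reciprocal weightings.
#' @param y Peak areas (detector units).
#' @param weighting `"1/x"`, `"1/x^2"`, or `"none"`.
#' @return A list with `slope`, `intercept`, `r_squared`, and `n`.
#' @examples
#' fit_weighted_line(c(1, 2, 4), c(10, 20, 40), "1/x")
#' @export
fit_weighted_line <- function(x, y, weighting = "1/x") {
  weighting <- normalize_weighting(weighting)
  if (length(x) != length(y)) {
    rrfq_abort("`x` and `y` must have the same length.", "rrfq_value_error")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2) {
    rrfq_abort("Need at least two distinct x values to fit a line.",
               "rrfq_degenerate_design_error")
  }
  if (weighting != "none" && any(x <= 0)) {
    rrfq_abort("Reciprocal weighting requires strictly positive x.",
               "rrfq_value_error")
  }
  w <- weight_vector(x, weighting)
  fit <- stats::lm(y ~ x, weights = w)
  coefs <- stats::coef(fit)
  ybar_w <- sum(w * y) / sum(w)
  ss_res <- sum(w * stats::residuals(fit)^2)
  ss_tot <- sum(w * (y - ybar_w)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res <= 1e-12)
  list(slope = unname(coefs["x"]), intercept = unname(coefs["(Intercept)"]),
       r_squared = r2, n = length(x))
}

#' Back-calculation accuracy of a calibration point
#'
#' Inverts the curve at the observed peak area and expresses the
#' back-calculated concentration as a percentage of the nominal one:
#' `100 * ((area - intercept) / slope) / nominal`. 100 means perfect
#' recovery; the bias filter accepts the closed band
#' `100 +/- bias_limit_percent`.
#'
#' @param curve A `calibration_curve` or any list with `slope` and
#'   `intercept`.
#' @param peak_area Observed peak area(s).
#' @param nominal_concentration Nominal concentration(s) in uM.
#' @return Accuracy in percent (vectorised).
#' @export
back_calc_accuracy <- function(curve, peak_area, nominal_concentration) {
  if (!is.finite(curve$slope) || curve$slope == 0) {
    rrfq_abort("Accuracy undefined: calibration slope is zero.",
               "rrfq_undefined_accuracy_error")
  }
  100 * ((peak_area - curve$intercept) / curve$slope) / nominal_concentration
}

new_calibration_curve <- function(metabolite_id, polarity, slope, intercept,
                                  weighting, r_squared, n_points_used,
                                  excluded_levels, quantifiable, reason,
                                  lod = NA_real_, loq = NA_real_) {
  structure(
    list(metabolite_id = metabolite_id, polarity = polarity,
         slope = slope, intercept = intercept, weighting = weighting,
         r_squared = r_squared, n_points_used = n_points_used,
         excluded_levels = excluded_levels, lod = lod, loq = loq,
         quantifiable = quantifiable, reason = reason),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s [%s]\n  slope %.6g, intercept %.6g, R2 %.5f (%s), levels used %d\n",
    x$metabolite_id, x$polarity, x$slope, x$intercept, x$r_squared,
    x$weighting, x$n_points_used))
  if (nrow(x$excluded_levels) > 0) {
    cat("  excluded:",
        paste(sprintf("%g uM (%s)", x$excluded_levels$level,
                      x$excluded_levels$reason), collapse = ", "), "\n")
  }
  cat(sprintf("  quantifiable: %s%s\n", x$quantifiable,
              if (!x$quantifiable) paste0(" (", x$reason, ")") else ""))
  invisible(x)
}

#' Fit a bias-filtered calibration curve for one metabolite
#'
#' The full curation applied to each standard series:
#' \enumerate{
#'   \item fit a reference line on the lowest `min_points` concentration
#'     levels (the region where detector response is linear by design;
#'     using a global fit here would let a saturated top level drag the
#'     line and make the clean low levels look biased);
#'   \item compute each level's mean back-calculation accuracy against
#'     that reference line;
#'   \item exclude levels whose accuracy falls outside the closed band
#'     `100 +/- bias_limit_percent` (default 85--115 percent);
#'   \item refit once on all replicate points of the surviving levels.
#' }
#' The exclude-and-refit pass runs exactly once; iterating it can cascade
#' exclusions unpredictably. The curve is `quantifiable` when the refit
#' R-squared exceeds `r2_gate`, at least `min_points` levels survive, and
#' the slope is positive. Failure modes set `quantifiable = FALSE` with a
#' reason instead of raising.
#'
#' @param points Data frame with `nominal_concentration`, `peak_area`, and
#'   optionally `replicate_index` (replicate points are fitted individually).
#' @param config A [run_config()].
#' @param metabolite_id,polarity Identifiers recorded on the curve.
#' @return A `calibration_curve` object.
#' @export
fit_calibration <- function(points, config = run_config(),
                            metabolite_id = NA_character_,
                            polarity = NA_character_) {
  stopifnot(is.data.frame(points))
  no_excl <- tibble::tibble(level = numeric(0), reason = character(0),
                            accuracy_percent = numeric(0))
  levels_all <- sort(unique(points$nominal_concentration))
  fail <- function(reason, fit = NULL, n_used = 0L, excl = no_excl) {
    new_calibration_curve(
      metabolite_id, polarity,
      slope = fit$slope %||% NA_real_, intercept = fit$intercept %||% NA_real_,
      weighting = config$weighting, r_squared = fit$r_squared %||% NA_real_,
      n_points_used = n_used, excluded_levels = excl,
      quantifiable = FALSE, reason = reason)
  }
  if (length(levels_all) < config$min_points) {
    return(fail(sprintf("only %d concentration level(s), need %d",
                        length(levels_all), config$min_points)))
  }

  # Reference line for the bias filter: anchored on the lowest min_points
  # levels, falling back to a global fit when that anchor is degenerate.
  anchor <- levels_all[seq_len(config$min_points)]
  in_anchor <- points$nominal_concentration %in% anchor
  fit0 <- tryCatch(
    fit_weighted_line(points$nominal_concentration[in_anchor],
                      points$peak_area[in_anchor], config$weighting),
    rrfq_error = function(e) NULL
  )
  if (is.null(fit0) || !is.finite(fit0$slope) || fit0$slope <= 0) {
    fit0 <- tryCatch(
      fit_weighted_line(points$nominal_concentration, points$peak_area,
                        config$weighting),
      rrfq_error = function(e) NULL
    )
  }
  if (is.null(fit0) || !is.finite(fit0$slope) || fit0$slope == 0) {
    return(fail("degenerate initial fit"))
  }

  level_acc <- vapply(levels_all, function(lv) {
    sel <- points$nominal_concentration == lv
    mean(back_calc_accuracy(fit0, points$peak_area[sel], lv))
  }, numeric(1))
  lo <- 100 - config$bias_limit_percent
  hi <- 100 + config$bias_limit_percent
  ok <- level_acc >= lo & level_acc <= hi   # boundary levels are kept
  excluded <- tibble::tibble(
    level = levels_all[!ok],
    reason = sprintf("bias: mean back-calc accuracy %.1f%% outside [%g, %g]%%",
                     level_acc[!ok], lo, hi),
    accuracy_percent = level_acc[!ok]
  )
  surv <- levels_all[ok]
  if (length(surv) < 2) {
    return(fail(sprintf("only %d level(s) pass the bias filter",
                        length(surv)), fit0, length(surv), excluded))
  }
  keep <- points$nominal_concentration %in% surv
  fit1 <- fit_weighted_line(points$nominal_concentration[keep],
                            points$peak_area[keep], config$weighting)

  quant <- TRUE; reason <- ""
  if (length(surv) < config$min_points) {
    quant <- FALSE
    reason <- sprintf("only %d level(s) pass the bias filter, need %d",
                      length(surv), config$min_points)
  } else if (!is.finite(fit1$r_squared) || fit1$r_squared <= config$r2_gate) {
    quant <- FALSE
    reason <- sprintf("R-squared %.4f not above gate %.2f",
                      fit1$r_squared, config$r2_gate)
  } else if (fit1$slope <= 0) {
    quant <- FALSE
    reason <- "non-positive slope"
  }
  new_calibration_curve(metabolite_id, polarity, fit1$slope, fit1$intercept,
                        config$weighting, fit1$r_squared,
                        n_points_used = length(surv),
                        excluded_levels = excluded,
                        quantifiable = quant, reason = reason)
}

#' Limit of detection by line extrapolation
#'
#' Solves `slope * x + intercept = sn_threshold * noise_level` for `x`: the
#' concentration at which the expected response reaches the chosen multiple
#' (default 2) of the noise level. Extrapolation can yield non-positive
#' solutions (when the intercept already exceeds the noise threshold);
#' those are not meaningful detection limits and are returned as `NA` with
#' a `reason` attribute rather than reported.
#'
#' @param curve A `calibration_curve` (needs positive `slope`).
#' @param noise_level Noise estimate in detector units (typically the mean
#'   blank peak area for the metabolite).
#' @param sn_threshold Signal-to-noise multiple (default 2).
#' @return The LOD in uM, or `NA_real_` (with attribute `reason`) when
#'   undefined.
#' @export
estimate_lod <- function(curve, noise_level, sn_threshold = 2) {
  undefined <- function(reason) {
    structure(NA_real_, reason = reason)
  }
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    return(undefined("non-positive slope"))
  }
  if (!is.finite(noise_level) || noise_level < 0) {
    return(undefined("no noise estimate"))
  }
  x <- (sn_threshold * noise_level - curve$intercept) / curve$slope
  if (!is.finite(x) || x <= 0) {
    return(undefined(sprintf("non-positive extrapolated LOD (%.4g uM)", x)))
  }
  x
}

#' Limit of quantification as the lowest identified level
#'
#' The lowest nominal concentration whose mean replicate peak area exceeds
#' the detection threshold. With no blank-derived threshold available, any
#' level with a positive mean area counts as identified.
#'
#' @param points Data frame with `nominal_concentration` and `peak_area`.
#' @param detection_threshold Detector-units threshold (default 0).
#' @return The LOQ in uM, or `NA_real_` when no level is detected.
#' @export
estimate_loq <- function(points, detection_threshold = 0) {
  if (detection_threshold < 0) {
    rrfq_abort("`detection_threshold` must be non-negative.",
               "rrfq_value_error")
  }
  levels <- sort(unique(points$nominal_concentration))
  for (lv in levels) {
    m <- mean(points$peak_area[points$nominal_concentration == lv])
    if (m > detection_threshold) return(lv)
  }
  NA_real_
}

# Blank-derived noise level for the LOD: mean blank area, falling back to the
# max blank area, NA when the metabolite has no blank measurements.
blank_noise_level <- function(measurements, metabolite_id, polarity) {
  b <- measurements[measurements$metabolite_id == metabolite_id &
                      measurements$polarity == polarity &
                      measurements$sample_type == "blank", "peak_area",
                    drop = TRUE]
  b <- b[is.finite(b)]
  if (length(b) == 0) return(NA_real_)
  m <- mean(b)
  if (is.finite(m) && m > 0) m else max(b)
}

# Blank-derived identification threshold for the LOQ: mean + 3 SD of blanks,
# 0 (any positive mean area counts) when no blanks exist.
blank_detection_threshold <- function(measurements, metabolite_id, polarity) {
  b <- measurements[measurements$metabolite_id == metabolite_id &
                      measurements$polarity == polarity &
                      measurements$sample_type == "blank", "peak_area",
                    drop = TRUE]
  b <- b[is.finite(b)]
  if (length(b) < 2) return(0)
  mean(b) + 3 * stats::sd(b)
}

#' Calibrate every analyte in a measurement table
#'
#' Runs [fit_calibration()] on the standard-series measurements of each
#' non-internal-standard metabolite per polarity, then attaches LOD
#' (blank-noise extrapolation at the configured S/N threshold) and LOQ
#' (lowest identified level) to each curve.
#'
#' @param measurements Measurement tibble (see [read_peak_areas()]).
#' @param transitions Transition tibble (identifies internal standards).
#' @param config A [run_config()].
#' @return A list with `curves` (named list of `calibration_curve`, keyed
#'   `metabolite_id|polarity`) and `report` (one-row-per-curve tibble).
#' @export
calibrate_run <- function(measurements, transitions, config = run_config()) {
  std <- measurements[measurements$sample_type == "standard", ]
  is_ids <- transitions$metabolite_id[transitions$is_internal_standard]
  std <- std[!std$metabolite_id %in% is_ids, ]
  keys <- unique(std[, c("metabolite_id", "polarity")])
  curves <- list()
  for (i in seq_len(nrow(keys))) {
    mid <- keys$metabolite_id[i]; pol <- keys$polarity[i]
    pts <- std[std$metabolite_id == mid & std$polarity == pol, ]
    curve <- fit_calibration(pts, config, metabolite_id = mid, polarity = pol)
    curve$lod <- as.numeric(estimate_lod(
      curve, blank_noise_level(measurements, mid, pol),
      config$sn_lod_threshold))
    curve$loq <- estimate_loq(
      pts, blank_detection_threshold(measurements, mid, pol))
    curves[[paste(mid, pol, sep = "|")]] <- curve
  }
  list(curves = curves, report = calibration_report(curves))
}

#' Turn a list of calibration curves into the report tibble
#'
#' @param curves Named list of `calibration_curve` objects.
#' @return Tibble with one row per curve; `excluded_levels` is a
#'   semicolon-separated list of excluded concentrations.
#' @export
calibration_report <- function(curves) {
  rows <- lapply(curves, function(cv) {
    tibble::tibble(
      metabolite_id = cv$metabolite_id,
      polarity = cv$polarity,
      slope = cv$slope,
      intercept = cv$intercept,
      weighting = cv$weighting,
      r_squared = cv$r_squared,
      n_points_used = cv$n_points_used,
      excluded_levels = paste(cv$excluded_levels$level, collapse = ";"),
      lod_uM = cv$lod,
      loq_uM = cv$loq,
      quantifiable = cv$quantifiable,
      reason = cv$reason
    )
  })
  dplyr::bind_rows(rows)
}

# Rebuild minimal curve objects from a calibration report CSV so pipeline
# stages can be run from files.
curves_from_report <- function(report) {
  curves <- list()
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    excl_levels <- if (nzchar(r$excluded_levels %||% "") &&
                       !is.na(r$excluded_levels)) {
      as.numeric(strsplit(r$excluded_levels, ";")[[1]])
    } else numeric(0)
    curves[[paste(r$metabolite_id, r$polarity, sep = "|")]] <-
      new_calibration_curve(
        r$metabolite_id, r$polarity, r$slope, r$intercept, r$weighting,
        r$r_squared, r$n_points_used,
        tibble::tibble(level = excl_levels,
                       reason = rep("bias", length(excl_levels)),
                       accuracy_percent = rep(NA_real_, length(excl_levels))),
        r$quantifiable, ifelse(is.na(r$reason), "", r$reason),
        lod = r$lod_uM, loq = r$loq_uM)
  }
  curves
}
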