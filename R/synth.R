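# 13C-labeled amino-acid internal-standard panel (17 compounds, the size of
# a typical commercial labeled amino-acid mix) with neutral formulas of the
# unlabeled species; the label changes retention behaviour and m/z in ways
# this simulator does not model.
IS_PANEL <- tibble::tibble(
  is_id = paste0("is_", c("ala", "arg", "asn", "asp", "glu", "gln", "gly",
                          "his", "ile", "leu", "lys", "met", "phe", "pro",
                          "ser", "thr", "val"), "_13c"),
  formula = c("C3H7NO2", "C6H14N4O2", "C4H8N2O3", "C4H7NO4", "C5H9NO4",
              "C5H10N2O3", "C2H5NO2", "C6H9N3O2", "C6H13NO2", "C6H13NO2",
              "C6H14N2O2", "C5H11NO2S", "C9H11NO2", "C5H9NO2", "C3H7NO3",
              "C4H9NO3", "C5H11NO2")
)

# Formula pool for synthetic analytes (common polar metabolites), recycled.
ANALYTE_FORMULAS <- c(
  "C6H12O6", "C3H6O3", "C6H8O7", "C4H6O4", "C3H4O3", "C5H10N2O3",
  "C9H11NO2", "C4H4O4", "C6H13NO2", "C5H9NO4", "C10H13N5O4", "C4H9NO3",
  "C6H6O6", "C5H4N4O3", "C7H6O2", "C4H7NO4", "C3H7NO2", "C6H14N4O2",
  "C5H11NO2S", "C2H5NO2"
)

run_with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic targeted LC-MS dataset
#'
#' Defines the ground truth a simulated run is generated from: per-compound
#' ionization efficiency (true response factor, drawn log-uniformly over
#' `rf_range` under `seed`), an optional detector-saturation midpoint
#' `c50` (response `rf * c / (1 + c / c50)`), multiplicative lognormal
#' replicate noise of a given CV, per-compound matrix suppression factors,
#' the standard-series design (default: 8 levels 0.03--100 uM in
#' triplicate), and the internal-standard panel spiked at 1.25 uM.
#'
#' @param n_metabolites Number of analytes.
#' @param polarity `"positive"` or `"negative"`.
#' @param rf_range Range (detector units per uM) for the log-uniform true
#'   RF draw.
#' @param intercept True baseline response in detector units (default 0).
#' @param c50 Saturation midpoint in uM; `Inf` disables saturation.
#' @param noise_cv_percent Replicate noise CV in percent.
#' @param suppression Named numeric vector of matrix suppression factors in
#'   (0, 1] per compound id (analytes and internal standards); compounds
#'   absent from the map default to 1 (no suppression).
#' @param levels Standard-series concentrations in uM.
#' @param n_replicates Replicates per sample (default 3).
#' @param is_ids Internal-standard ids (default: the bundled 17-compound
#'   labeled amino-acid panel).
#' @param is_spike Internal-standard spike concentration in uM (default
#'   1.25).
#' @param seed Integer seed; identical specs generate identical datasets.
#' @return A list with class `synth_spec`, including the drawn `true_rf`.
#' @export
synth_spec <- function(n_metabolites = 20,
                       polarity = c("positive", "negative"),
                       rf_range = c(1e3, 1e5),
                       intercept = 0,
                       c50 = Inf,
                       noise_cv_percent = 2,
                       suppression = NULL,
                       levels = DEFAULT_LEVELS,
                       n_replicates = 3,
                       is_ids = IS_PANEL$is_id,
                       is_spike = 1.25,
                       seed = 1L) {
  polarity <- match.arg(polarity)
  if (n_metabolites < 1) {
    rrfq_abort("`n_metabolites` must be at least 1.", "rrfq_validation_error")
  }
  if (any(levels <= 0) || length(levels) < 2) {
    rrfq_abort("`levels` must be >= 2 positive concentrations.",
               "rrfq_validation_error")
  }
  if (noise_cv_percent < 0) {
    rrfq_abort("`noise_cv_percent` must be non-negative.",
               "rrfq_validation_error")
  }
  if (!is.infinite(c50) && c50 <= 0) {
    rrfq_abort("`c50` must be positive (or Inf).", "rrfq_validation_error")
  }
  if (!is.null(suppression)) {
    if (is.null(names(suppression)) ||
        any(suppression <= 0 | suppression > 1)) {
      rrfq_abort("`suppression` must be a named vector with factors in (0, 1].",
                 "rrfq_validation_error")
    }
  }
  metabolite_ids <- sprintf("met_%03d", seq_len(n_metabolites))
  compound_ids <- c(metabolite_ids, is_ids)
  true_rf <- run_with_seed(seed, {
    stats::setNames(
      exp(runif(length(compound_ids), log(rf_range[1]), log(rf_range[2]))),
      compound_ids)
  })
  structure(
    list(n_metabolites = as.integer(n_metabolites), polarity = polarity,
         rf_range = rf_range, intercept = intercept, c50 = c50,
         noise_cv_percent = noise_cv_percent, suppression = suppression,
         levels = sort(levels), n_replicates = as.integer(n_replicates),
         metabolite_ids = metabolite_ids, is_ids = is_ids,
         is_spike = is_spike, seed = as.integer(seed), true_rf = true_rf),
    class = "synth_spec"
  )
}

# Lognormal multiplier with unit mean and the requested CV:
# sigma^2 = log(1 + cv^2), mu = -sigma^2/2.
noise_multiplier <- function(n, cv_percent) {
  cv <- cv_percent / 100
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

saturated_response <- function(rf, conc, c50, intercept) {
  rf * conc / (1 + conc / c50) + intercept
}

suppression_factor <- function(spec, compound_id) {
  if (is.null(spec$suppression)) return(1)
  x <- unname(spec$suppression[compound_id])
  ifelse(is.na(x), 1, x)
}

#' Transition list for a synthetic dataset
#'
#' @param spec A [synth_spec()].
#' @return A transition tibble matching [read_transition_list()] output.
#' @export
generate_transitions <- function(spec) {
  adduct <- if (spec$polarity == "positive") "[M+H]+" else "[M-H]-"
  formulas <- c(
    rep_len(ANALYTE_FORMULAS, spec$n_metabolites),
    IS_PANEL$formula[match(spec$is_ids, IS_PANEL$is_id)]
  )
  formulas[is.na(formulas)] <- "C5H11NO2"
  ids <- c(spec$metabolite_ids, spec$is_ids)
  rts <- run_with_seed(spec$seed + 7L, round(runif(length(ids), 1.2, 12), 2))
  tibble::tibble(
    metabolite_id = ids,
    name = ids,
    formula = formulas,
    adduct = adduct,
    polarity = spec$polarity,
    theoretical_mz = compute_theoretical_mz(formulas, adduct),
    expected_rt = rts,
    is_internal_standard = ids %in% spec$is_ids
  )
}

# One block of measurement rows for a set of compounds in one sample.
synth_rows <- function(spec, transitions, sample_id, sample_type, rep_idx,
                       conc_map, suppress) {
  ids <- names(conc_map)
  tr <- transitions[match(ids, transitions$metabolite_id), ]
  sup <- if (suppress) {
    vapply(ids, function(id) suppression_factor(spec, id), numeric(1))
  } else rep(1, length(ids))
  clean <- unname(sup) * saturated_response(unname(spec$true_rf[ids]),
                                            unname(conc_map),
                                            spec$c50, spec$intercept)
  area <- clean * noise_multiplier(length(ids), spec$noise_cv_percent)
  jitter_on <- spec$noise_cv_percent > 0
  mz_obs <- tr$theoretical_mz *
    (1 + jitter_on * rnorm(length(ids), 0, 0.5e-6))
  rt_obs <- tr$expected_rt + jitter_on * rnorm(length(ids), 0, 0.03)
  tibble::tibble(
    metabolite_id = ids,
    sample_id = sample_id,
    replicate_index = rep_idx,
    sample_type = sample_type,
    polarity = spec$polarity,
    peak_area = area,
    observed_mz = mz_obs,
    observed_rt = rt_obs,
    nominal_concentration = ifelse(
      sample_type == "standard" | ids %in% spec$is_ids,
      unname(conc_map), NA_real_)
  )
}

#' Generate a synthetic standard calibration series
#'
#' Simulates the standard-series design: one sample per concentration
#' level, `n_replicates` injections each, analytes at the level
#' concentration and internal standards at the constant spike. Areas follow
#' `area = [rf * c / (1 + c / c50) + intercept] * exp(eps)` with
#' mean-unbiased lognormal noise. Blank injections (all compounds at zero
#' concentration, pure baseline noise) are appended so LOD/LOQ estimation
#' has a noise floor.
#'
#' @param spec A [synth_spec()].
#' @param n_blanks Number of blank injections (default 3).
#' @return List with `transitions`, `measurements`, and a `truth` tibble of
#'   all generating parameters.
#' @export
generate_standard_series <- function(spec, n_blanks = 3) {
  stopifnot(inherits(spec, "synth_spec"))
  transitions <- generate_transitions(spec)
  rows <- run_with_seed(spec$seed + 1L, {
    out <- list()
    for (li in seq_along(spec$levels)) {
      conc_map <- c(
        stats::setNames(rep(spec$levels[li], spec$n_metabolites),
                        spec$metabolite_ids),
        stats::setNames(rep(spec$is_spike, length(spec$is_ids)), spec$is_ids))
      for (r in seq_len(spec$n_replicates)) {
        out[[length(out) + 1]] <- synth_rows(
          spec, transitions, sprintf("std_%02d", li), "standard", r,
          conc_map, suppress = FALSE)
      }
    }
    # Blanks: baseline-only signal, a small fixed fraction of the weakest
    # expected analyte response so LODs land near the bottom of the series.
    blank_level <- 1e-3 * min(spec$true_rf) * min(spec$levels)
    for (b in seq_len(n_blanks)) {
      ids <- c(spec$metabolite_ids, spec$is_ids)
      mult <- noise_multiplier(length(ids),
                               max(spec$noise_cv_percent, 10))
      out[[length(out) + 1]] <- tibble::tibble(
        metabolite_id = ids,
        sample_id = sprintf("blank_%02d", b),
        replicate_index = 1L,
        sample_type = "blank",
        polarity = spec$polarity,
        peak_area = blank_level * mult,
        observed_mz = NA_real_,
        observed_rt = NA_real_,
        nominal_concentration = NA_real_
      )
    }
    dplyr::bind_rows(out)
  })
  list(
    transitions = transitions,
    measurements = rows,
    truth = synth_truth(spec)
  )
}

#' Generate synthetic matrix samples with paired solvent references
#'
#' Simulates biological-matrix injections: every compound's linear response
#' is scaled by its matrix suppression factor (default 1 when absent from
#' the map), internal standards are spiked at the usual concentration, and
#' a paired `solvent_reference` sample with identical true concentrations
#' but no suppression is generated for ion-suppression evaluation.
#'
#' @param spec A [synth_spec()].
#' @param true_concentrations Named vector of analyte concentrations (uM)
#'   in the matrix sample; names must be analyte ids from the spec.
#' @param matrix_id Sample-id stem (default `"plasma"`).
#' @return List with `transitions`, `measurements`, and `truth` (including
#'   a `sample_truth` table of per-sample true concentrations).
#' @export
generate_matrix_samples <- function(spec, true_concentrations,
                                    matrix_id = "plasma") {
  stopifnot(inherits(spec, "synth_spec"))
  unknown <- setdiff(names(true_concentrations), spec$metabolite_ids)
  if (length(unknown) > 0) {
    rrfq_abort(
      sprintf("Unknown compound(s) in true_concentrations: %s",
              paste(unknown, collapse = ", ")),
      "rrfq_validation_error"
    )
  }
  transitions <- generate_transitions(spec)
  conc_map <- c(true_concentrations,
                stats::setNames(rep(spec$is_spike, length(spec$is_ids)),
                                spec$is_ids))
  rows <- run_with_seed(spec$seed + 2L, {
    out <- list()
    for (r in seq_len(spec$n_replicates)) {
      out[[length(out) + 1]] <- synth_rows(
        spec, transitions, paste0(matrix_id, "_01"), "matrix", r,
        conc_map, suppress = TRUE)
    }
    for (r in seq_len(spec$n_replicates)) {
      out[[length(out) + 1]] <- synth_rows(
        spec, transitions, "solvent_01", "solvent_reference", r,
        conc_map, suppress = FALSE)
    }
    dplyr::bind_rows(out)
  })
  sample_truth <- tibble::tibble(
    metabolite_id = names(true_concentrations),
    sample_id = paste0(matrix_id, "_01"),
    true_concentration = unname(true_concentrations)
  )
  truth <- synth_truth(spec)
  list(transitions = transitions, measurements = rows,
       truth = truth, sample_truth = sample_truth)
}

synth_truth <- function(spec) {
  ids <- c(spec$metabolite_ids, spec$is_ids)
  tibble::tibble(
    compound_id = ids,
    polarity = spec$polarity,
    is_internal_standard = ids %in% spec$is_ids,
    rf_true = unname(spec$true_rf[ids]),
    intercept_true = spec$intercept,
    c50_uM = spec$c50,
    noise_cv_percent = spec$noise_cv_percent,
    suppression_true = vapply(ids, function(id) suppression_factor(spec, id),
                              numeric(1)),
    seed = spec$seed
  )
}

#' Named scenario presets for the simulator
#'
#' \describe{
#'   \item{clean}{2 percent noise, no suppression, no saturation.}
#'   \item{saturated_positive}{saturation midpoint `c50 = 50` uM in
#'     positive mode, so the 100 uM level responds at a third of its linear
#'     value and fails the bias filter.}
#'   \item{suppressed_plasma}{per-compound suppression drawn log-uniformly
#'     in (0.2, 0.95) — the qualitative spread seen between weakly and
#'     strongly suppressed amino acids in plasma.}
#'   \item{mismatched_reference}{noiseless; analytes suppressed at 0.8,
#'     internal standards at 0.4, so reference choice biases RRF results by
#'     the factor ratio.}
#' }
#'
#' @param name Preset name.
#' @param n_metabolites Number of analytes (default 20).
#' @param seed Seed (default 1).
#' @return A [synth_spec()].
#' @export
scenario_presets <- function(name = c("clean", "saturated_positive",
                                      "suppressed_plasma",
                                      "mismatched_reference"),
                             n_metabolites = 20, seed = 1L) {
  if (length(name) != 1 || !name %in% c("clean", "saturated_positive",
                                        "suppressed_plasma",
                                        "mismatched_reference")) {
    rrfq_abort(
      paste("Unknown preset. Available: clean, saturated_positive,",
            "suppressed_plasma, mismatched_reference"),
      "rrfq_validation_error"
    )
  }
  base <- function(...) synth_spec(n_metabolites = n_metabolites,
                                   seed = seed, ...)
  switch(name,
    clean = base(noise_cv_percent = 2),
    saturated_positive = base(noise_cv_percent = 2, c50 = 50,
                              polarity = "positive"),
    suppressed_plasma = {
      sp <- base(noise_cv_percent = 2)
      ids <- c(sp$metabolite_ids, sp$is_ids)
      sp$suppression <- run_with_seed(seed + 3L, stats::setNames(
        exp(runif(length(ids), log(0.2), log(0.95))), ids))
      sp
    },
    mismatched_reference = {
      sp <- base(noise_cv_percent = 0)
      sp$suppression <- stats::setNames(
        c(rep(0.8, length(sp$metabolite_ids)), rep(0.4, length(sp$is_ids))),
        c(sp$metabolite_ids, sp$is_ids))
      sp
    }
  )
}
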