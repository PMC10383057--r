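quant_curve <- function(slope, intercept = 0, id = "m", pol = "positive") {
  structure(list(metabolite_id = id, polarity = pol, slope = slope,
                 intercept = intercept, quantifiable = TRUE, reason = ""),
            class = "calibration_curve")
}

test_that("external-calibration inversion is exact arithmetic", {
  cv <- quant_curve(1000)
  expect_equal(quantify_ec(12500, cv), 12.5)
  expect_equal(quantify_ec(cv$intercept, cv), 0)
  # negative results are reported, not clamped
  expect_lt(quantify_ec(-100, cv), 0)
  bad <- quant_curve(1000); bad$quantifiable <- FALSE
  expect_error(quantify_ec(1, bad), class = "rrfq_contract_error")
})

test_that("RRF quantification follows the single-point formula", {
  expect_equal(quantify_rrf(500, 1000, 1.25, 0.5), 1.25)
  # RRF 1 and equal areas return the reference spike concentration
  expect_equal(quantify_rrf(777, 777, 1.25, 1), 1.25)
  expect_error(quantify_rrf(500, 0, 1.25, 0.5),
               class = "rrfq_undefined_quantification_error")
  expect_error(quantify_rrf(500, 1000, 1.25, -1), class = "rrfq_value_error")
})

test_that("replicate CV matches hand calculations and is scale invariant", {
  expect_equal(replicate_cv(c(2, 2, 2)), 0)
  expect_equal(replicate_cv(c(8, 12)), 28.2843, tolerance = 1e-4)
  set.seed(3)
  x <- rlnorm(5)
  expect_equal(replicate_cv(7 * x), replicate_cv(x), tolerance = 1e-12)
  expect_true(is.na(replicate_cv(c(-1, 1))))  # zero mean: flagged undefined
  expect_error(replicate_cv(5), class = "rrfq_value_error")
})

test_that("ion suppression is the relative area loss, enhancement flagged", {
  expect_equal(ion_suppression(250, 1000)$suppression_percent, 75)
  expect_equal(ion_suppression(1000, 1000)$suppression_percent, 0)
  enh <- ion_suppression(1200, 1000)
  expect_equal(enh$suppression_percent, -20)
  expect_true(enh$enhancement)
  expect_error(ion_suppression(1, 0),
               class = "rrfq_undefined_quantification_error")
})

test_that("suppression table reproduces the generator's configured factors", {
  spec <- synth_spec(n_metabolites = 4, noise_cv_percent = 0, seed = 17)
  ids <- c(spec$metabolite_ids, spec$is_ids)
  spec$suppression <- stats::setNames(
    rep(c(0.7, 0.4), length.out = length(ids)), ids)
  mat <- generate_matrix_samples(
    spec, stats::setNames(rep(5, 4), spec$metabolite_ids))
  sup <- ion_suppression_table(mat$measurements)
  expect_equal(nrow(sup), length(ids))
  expect_equal(sup$suppression_percent,
               100 * (1 - unname(spec$suppression[sup$compound_id])),
               tolerance = 1e-9)
})

# End-to-end harness shared by the matched/mismatched suppression checks.
suppressed_quant <- function(s_analyte, s_reference, noise = 0, seed = 31) {
  spec <- synth_spec(n_metabolites = 5, noise_cv_percent = noise, seed = seed)
  ids <- c(spec$metabolite_ids, spec$is_ids)
  spec$suppression <- stats::setNames(
    c(rep(s_analyte, length(spec$metabolite_ids)),
      rep(s_reference, length(spec$is_ids))), ids)
  std <- generate_standard_series(spec)
  truth_conc <- stats::setNames(c(0.5, 2, 8, 20, 60), spec$metabolite_ids)
  mat <- generate_matrix_samples(spec, truth_conc)
  cfg <- run_config(seed = seed)
  cal <- calibrate_run(std$measurements, std$transitions, cfg)
  refs <- select_references(summarize_references(std$measurements,
                                                 std$transitions, cfg), 6)
  rrf <- build_rrf_table(cal$curves, refs)
  quantify_run(mat$measurements, cal$curves, refs, rrf, cfg,
               sample_types = "matrix", truth = mat$sample_truth)
}

test_that("matched suppression cancels in RRF but biases EC by the factor", {
  for (s in c(0.3, 0.8)) {
    q <- suppressed_quant(s, s)
    ec <- q[q$method == "EC", ]
    rr <- q[q$method != "EC", ]
    expect_equal(unique(round(ec$accuracy_percent, 9)), 100 * s,
                 tolerance = 1e-9)
    expect_equal(max(abs(rr$accuracy_percent - 100)), 0, tolerance = 1e-9)
  }
})

test_that("mismatched reference suppression biases RRF by s_analyte/s_reference", {
  q <- suppressed_quant(0.8, 0.4)
  rr <- q[q$method != "EC", ]
  expect_equal(max(abs(rr$accuracy_percent - 200)), 0, tolerance = 1e-9)
  # EC still under-reads by the analyte factor
  expect_equal(max(abs(q$accuracy_percent[q$method == "EC"] - 80)), 0,
               tolerance = 1e-9)
})

test_that("scaling all areas leaves RRF unchanged and scales EC", {
  spec <- synth_spec(n_metabolites = 3, noise_cv_percent = 0, seed = 41)
  std <- generate_standard_series(spec)
  truth_conc <- stats::setNames(c(1, 5, 20), spec$metabolite_ids)
  mat <- generate_matrix_samples(spec, truth_conc)
  cfg <- run_config(seed = 41)
  cal <- calibrate_run(std$measurements, std$transitions, cfg)
  refs <- select_references(summarize_references(std$measurements,
                                                 std$transitions, cfg), 6)
  rrf <- build_rrf_table(cal$curves, refs)
  q1 <- quantify_run(mat$measurements, cal$curves, refs, rrf, cfg,
                     sample_types = "matrix", truth = mat$sample_truth)
  # simulate a run with 3x detector drift
  drifted <- mat$measurements
  drifted$peak_area <- 3 * drifted$peak_area
  q3 <- quantify_run(drifted, cal$curves, refs, rrf, cfg,
                     sample_types = "matrix", truth = mat$sample_truth)
  key <- function(q) paste(q$metabolite_id, q$replicate_index, q$method)
  expect_equal(key(q1), key(q3))
  is_ec <- q1$method == "EC"
  expect_equal(q3$concentration[!is_ec], q1$concentration[!is_ec],
               tolerance = 1e-12)
  expect_equal(q3$concentration[is_ec], 3 * q1$concentration[is_ec],
               tolerance = 1e-12)
})

test_that("isotope-matched references are tagged as a distinguished tier", {
  expect_true(is_isotope_match("ala", "is_ala_13c"))
  expect_true(is_isotope_match("Leu", "is_leu_13c"))
  expect_false(is_isotope_match("met_001", "is_ala_13c"))
})

test_that("method comparison summarises accuracy and RRF/EC ratios", {
  spec <- synth_spec(n_metabolites = 4, noise_cv_percent = 0, seed = 19)
  std <- generate_standard_series(spec)
  cfg <- run_config(seed = 19)
  cal <- calibrate_run(std$measurements, std$transitions, cfg)
  refs <- select_references(summarize_references(std$measurements,
                                                 std$transitions, cfg), 6)
  rrf <- build_rrf_table(cal$curves, refs)
  q <- quantify_run(std$measurements, cal$curves, refs, rrf, cfg,
                    sample_types = "standard")
  cmp <- compare_methods(q)
  expect_equal(cmp$method_summary$median_accuracy_percent,
               rep(100, nrow(cmp$method_summary)), tolerance = 1e-9)
  expect_equal(cmp$method_summary$fraction_in_band,
               rep(1, nrow(cmp$method_summary)))
  expect_equal(cmp$ratio_table$rrf_over_ec,
               rep(1, nrow(cmp$ratio_table)), tolerance = 1e-9)
  expect_warning(compare_methods(q[q$method == "EC", ]),
                 class = "rrfq_empty_table_warning")
})
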