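test_that("theoretical m/z agrees with the independent mass-table oracle", {
  for (entry in oracle_panel) {
    expect_equal(compute_theoretical_mz(entry$formula, "[M+H]+"),
                 oracle_mz(entry$counts, +1), tolerance = 1e-4 / 100,
                 info = entry$formula)
    expect_equal(compute_theoretical_mz(entry$formula, "[M-H]-"),
                 oracle_mz(entry$counts, -1), tolerance = 1e-4 / 100,
                 info = entry$formula)
  }
  # absolute agreement < 1e-4 Th
  diffs <- vapply(oracle_panel, function(e) {
    abs(compute_theoretical_mz(e$formula, "[M+H]+") - oracle_mz(e$counts, 1))
  }, numeric(1))
  expect_lt(max(diffs), 1e-4)
})

test_that("m/z computation is pure and rejects bad input", {
  expect_identical(compute_theoretical_mz("C6H12O6", "[M+H]+"),
                   compute_theoretical_mz("C6H12O6", "[M+H]+"))
  # typographic minus accepted
  expect_equal(compute_theoretical_mz("H2O", "[M−H]−"),
               compute_theoretical_mz("H2O", "[M-H]-"))
  expect_error(compute_theoretical_mz("C6H12O6", "[M+Na]+"),
               class = "rrfq_adduct_error")
  expect_error(parse_formula("C6Xx12O6"), class = "rrfq_formula_error")
  expect_error(parse_formula("C6H12O6!"), class = "rrfq_formula_error")
  expect_identical(parse_formula("CH4"), parse_formula("C1H4"))
})

test_that("transition list reader validates rows and keys", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "metabolite_id,name,formula,adduct,polarity,theoretical_mz,expected_rt,is_internal_standard",
    "glycine,glycine,C2H5NO2,[M+H]+,positive,76.0393,7.2,false"), f)
  tr <- read_transition_list(f)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$theoretical_mz, 76.0393, tolerance = 1e-6)
  expect_false(tr$is_internal_standard)

  # header-only file: empty collection, no error
  writeLines(
    "metabolite_id,name,formula,adduct,polarity,theoretical_mz,expected_rt,is_internal_standard",
    f)
  expect_equal(nrow(read_transition_list(f)), 0)

  # duplicate (metabolite_id, polarity)
  writeLines(c(
    "metabolite_id,name,formula,adduct,polarity,theoretical_mz,expected_rt,is_internal_standard",
    "glycine,glycine,C2H5NO2,[M+H]+,positive,76.0393,7.2,false",
    "glycine,glycine,C2H5NO2,[M+H]+,positive,76.0393,7.2,false"), f)
  expect_error(read_transition_list(f), class = "rrfq_duplicate_key_error")

  # missing required column is named in the error
  writeLines(c("metabolite_id,name,formula,adduct,polarity,expected_rt",
               "g,g,C2H5NO2,[M+H]+,positive,7.2"), f)
  expect_error(read_transition_list(f), "is_internal_standard",
               class = "rrfq_schema_error")

  # polarity inconsistent with adduct sign
  writeLines(c(
    "metabolite_id,name,formula,adduct,polarity,theoretical_mz,expected_rt,is_internal_standard",
    "glycine,glycine,C2H5NO2,[M+H]+,negative,76.0393,7.2,false"), f)
  expect_error(read_transition_list(f), class = "rrfq_schema_error")
})

test_that("m/z is filled from the formula when the column is absent", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "metabolite_id,name,formula,adduct,polarity,expected_rt,is_internal_standard",
    "glycine,glycine,C2H5NO2,[M+H]+,positive,7.2,false"), f)
  tr <- read_transition_list(f)
  expect_equal(tr$theoretical_mz, 76.0393, tolerance = 1e-4)
})

test_that("peak-area reader resolves ids and enforces invariants", {
  tr <- make_transitions(c("a", "b"))
  f <- withr::local_tempfile(fileext = ".csv")
  hdr <- "metabolite_id,sample_id,replicate,sample_type,polarity,peak_area,observed_mz,observed_rt,nominal_concentration_uM"
  writeLines(c(hdr,
               "a,std_01,1,standard,positive,100,,,3",
               "a,std_01,2,standard,positive,110,,,3",
               "a,std_01,3,standard,positive,90,,,3"), f)
  m <- read_peak_areas(f, tr)
  expect_equal(nrow(m), 3)
  expect_setequal(m$replicate_index, 1:3)
  expect_equal(unique(m$nominal_concentration), 3)

  writeLines(c(hdr, "zzz,std_01,1,standard,positive,100,,,3"), f)
  expect_error(read_peak_areas(f, tr), "zzz",
               class = "rrfq_unresolved_reference_error")

  writeLines(c(hdr, "a,std_01,1,standard,positive,-5,,,3"), f)
  expect_error(read_peak_areas(f, tr), class = "rrfq_validation_error")

  # standard rows must carry a nominal concentration
  writeLines(c(hdr, "a,std_01,1,standard,positive,100,,,"), f)
  expect_error(read_peak_areas(f, tr), class = "rrfq_validation_error")
})

test_that("synthetic peak-area tables round-trip losslessly", {
  for (seed in c(3, 11)) {
    spec <- synth_spec(n_metabolites = 4, noise_cv_percent = 5, seed = seed)
    std <- generate_standard_series(spec)
    f <- withr::local_tempfile(fileext = ".csv")
    write_peak_areas(std$measurements, f)
    back <- read_peak_areas(f, std$transitions)
    expect_equal(as.data.frame(back), as.data.frame(std$measurements),
                 tolerance = 1e-12)
    ft <- withr::local_tempfile(fileext = ".csv")
    write_transition_list(std$transitions, ft)
    expect_equal(as.data.frame(read_transition_list(ft)),
                 as.data.frame(std$transitions), tolerance = 1e-12)
  }
})

test_that("write_report emits per-table CSVs plus a JSON summary", {
  dir <- withr::local_tempdir()
  one_row <- tibble::tibble(metabolite_id = "a", concentration = 1.234567)
  empty <- tibble::tibble(metric = character(0), value = numeric(0))
  files <- write_report(list(quant = one_row, qc = empty), dir)
  expect_true(all(file.exists(file.path(dir, c("quant.csv", "qc.csv",
                                               "summary.json")))))
  back <- readr::read_csv(file.path(dir, "quant.csv"), show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(one_row))
  # empty table: header only
  expect_equal(length(readLines(file.path(dir, "qc.csv"))), 1)
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$quant$rows, 1)
  expect_error(write_report(list(), dir), class = "rrfq_validation_error")
})

test_that("config round-trips through YAML and rejects unknown keys", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(weighting = "1/x^2", bias_limit_percent = 20,
                        seed = 9), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$weighting, "1/x^2")
  expect_equal(cfg$bias_limit_percent, 20)
  expect_equal(cfg$min_points, 3L)  # default preserved
  yaml::write_yaml(list(nonsense = 1), f)
  expect_error(read_run_config(f), class = "rrfq_config_error")
  expect_error(run_config(min_points = 1), class = "rrfq_config_error")
})
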