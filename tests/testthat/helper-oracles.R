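# Independent oracles the implementation is checked against. These are kept
# deliberately separate from the package code paths: the regression oracle
# solves the 2x2 weighted normal equations directly, and the mass oracle
# carries its own atomic-mass table.

# Weighted least squares via explicit normal equations.
wls_oracle <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  slope <- (sw * swxy - swx * swy) / (sw * swxx - swx^2)
  intercept <- (swy - slope * swx) / sw
  list(slope = slope, intercept = intercept)
}

# Monoisotopic masses, entered independently (CIAAW 2021 values).
oracle_masses <- c(
  C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462,
  P = 30.97376200, S = 31.97207117, Na = 22.98976928, Cl = 34.96885268,
  K = 38.96370649, F = 18.99840316
)
oracle_proton <- 1.00727646

oracle_mz <- function(counts, sign) {
  sum(oracle_masses[names(counts)] * counts) + sign * oracle_proton
}

# Ten-formula verification panel: element counts written out by hand.
oracle_panel <- list(
  list(formula = "H2O",       counts = c(H = 2, O = 1)),
  list(formula = "C2H5NO2",   counts = c(C = 2, H = 5, N = 1, O = 2)),
  list(formula = "C6H12O6",   counts = c(C = 6, H = 12, O = 6)),
  list(formula = "C3H7NO3",   counts = c(C = 3, H = 7, N = 1, O = 3)),
  list(formula = "C9H11NO2",  counts = c(C = 9, H = 11, N = 1, O = 2)),
  list(formula = "C5H11NO2S", counts = c(C = 5, H = 11, N = 1, O = 2, S = 1)),
  list(formula = "C10H13N5O4", counts = c(C = 10, H = 13, N = 5, O = 4)),
  list(formula = "C6H8O7",    counts = c(C = 6, H = 8, O = 7)),
  list(formula = "C4H6O4",    counts = c(C = 4, H = 6, O = 4)),
  list(formula = "C6H14N4O2", counts = c(C = 6, H = 14, N = 4, O = 2))
)

# Small in-memory standard-series builder for hand-constructed fixtures:
# exact linear response, optional per-level overrides.
make_points <- function(levels = c(0.03, 0.3, 3, 6, 12, 25, 50, 100),
                        slope = 1000, intercept = 0, n_rep = 3,
                        area_fun = NULL) {
  pts <- expand.grid(nominal_concentration = levels,
                     replicate_index = seq_len(n_rep))
  pts$peak_area <- if (is.null(area_fun)) {
    slope * pts$nominal_concentration + intercept
  } else {
    area_fun(pts$nominal_concentration)
  }
  pts
}

# Minimal transition table for tests that need one.
make_transitions <- function(ids, polarity = "positive",
                             is_internal = rep(FALSE, length(ids))) {
  adduct <- if (polarity == "positive") "[M+H]+" else "[M-H]-"
  tibble::tibble(
    metabolite_id = ids, name = ids, formula = "C6H12O6",
    adduct = adduct, polarity = polarity,
    theoretical_mz = compute_theoretical_mz("C6H12O6", adduct),
    expected_rt = 5, is_internal_standard = is_internal
  )
}
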