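# Monoisotopic masses (u) of the elements that occur in small-molecule
# metabolite formulas, CODATA/IUPAC values truncated at 1e-7 u.
MONOISOTOPIC_MASS <- c(
  C  = 12.0000000,
  H  = 1.0078250,
  N  = 14.0030740,
  O  = 15.9949146,
  P  = 30.9737615,
  S  = 31.9720707,
  Na = 22.9897693,
  K  = 38.9637065,
  Cl = 34.9688527,
  F  = 18.9984032,
  Br = 78.9183376,
  I  = 126.9044730,
  Se = 79.9165218,
  Si = 27.9769265,
  B  = 11.0093055,
  Fe = 55.9349363,
  Mg = 23.9850417,
  Ca = 39.9625910
)

# Mass of a proton (u): monoisotopic H minus the electron mass.
PROTON_MASS <- 1.0072765

SUPPORTED_ADDUCTS <- c("[M+H]+", "[M-H]-")

# Accept the typographic minus sign some exports use and normalise it.
normalize_adduct <- function(adduct) {
  gsub("−", "-", adduct)
}

#' Parse a molecular formula into element counts
#'
#' Accepts Hill-order formulas such as `"C6H12O6"` with optional explicit
#' counts of 1 (`"CH4"` and `"C1H4"` are equivalent). No isotopes, charges,
#' parentheses or adduct notation: this is the neutral molecule only.
#'
#' @param formula A single formula string.
#' @return A named integer vector of element counts.
#' @examples
#' parse_formula("C2H5NO2")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    rrfq_abort("`formula` must be a single non-empty string.",
               "rrfq_formula_error")
  }
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  matched <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(matched)) != nchar(formula)) {
    rrfq_abort(
      sprintf("Cannot parse formula '%s': unexpected characters.", formula),
      "rrfq_formula_error"
    )
  }
  elements <- sub("[0-9]*$", "", matched)
  counts <- as.integer(ifelse(grepl("[0-9]+$", matched),
                              sub("^[A-Za-z]+", "", matched), "1"))
  unknown <- setdiff(elements, names(MONOISOTOPIC_MASS))
  if (length(unknown) > 0) {
    rrfq_abort(
      sprintf("Unknown element symbol(s) in formula '%s': %s",
              formula, paste(unknown, collapse = ", ")),
      "rrfq_formula_error"
    )
  }
  tapply(counts, elements, sum)[unique(elements)]
}

#' Monoisotopic m/z of a singly charged adduct
#'
#' Computes the theoretical mass-to-charge ratio of `[M+H]+` or `[M-H]-`
#' (charge fixed at +/-1, matching simple dual-polarity ESI acquisition):
#' the monoisotopic neutral mass plus or minus one proton.
#'
#' @param formula Molecular formula string(s) of the neutral molecule.
#' @param adduct `"[M+H]+"` or `"[M-H]-"` (recycled against `formula`).
#' @return Numeric vector of m/z values in Thomson.
#' @examples
#' compute_theoretical_mz("H2O", "[M+H]+")   # 19.0178
#' compute_theoretical_mz("C2H5NO2", "[M+H]+") # glycine, 76.0393
#' @export
compute_theoretical_mz <- function(formula, adduct) {
  adduct <- normalize_adduct(adduct)
  n <- max(length(formula), length(adduct))
  formula <- rep_len(formula, n)
  adduct <- rep_len(adduct, n)
  bad <- !adduct %in% SUPPORTED_ADDUCTS
  if (any(bad)) {
    rrfq_abort(
      sprintf("Unsupported adduct(s): %s. Supported: %s",
              paste(unique(adduct[bad]), collapse = ", "),
              paste(SUPPORTED_ADDUCTS, collapse = ", ")),
      "rrfq_adduct_error"
    )
  }
  neutral <- vapply(formula, function(f) {
    counts <- parse_formula(f)
    sum(MONOISOTOPIC_MASS[names(counts)] * counts)
  }, numeric(1), USE.NAMES = FALSE)
  ifelse(adduct == "[M+H]+", neutral + PROTON_MASS, neutral - PROTON_MASS)
}

adduct_polarity <- function(adduct) {
  ifelse(normalize_adduct(adduct) == "[M+H]+", "positive", "negative")
}

#' Signed mass error in parts per million
#'
#' @param observed_mz Observed m/z (Th).
#' @param theoretical_mz Theoretical m/z (Th); must be positive.
#' @return Signed ppm error `1e6 * (observed - theoretical) / theoretical`.
#' @examples
#' mass_error_ppm(100.0001, 100) # 1 ppm
#' @export
mass_error_ppm <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0, na.rm = TRUE)) {
    rrfq_abort("`theoretical_mz` must be positive.", "rrfq_value_error")
  }
  1e6 * (observed_mz - theoretical_mz) / theoretical_mz
}
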