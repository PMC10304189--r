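# Element tables and physical constants.
#
# All lengths are Angstrom, energies Hartree, masses amu throughout the
# package; fractional coordinates exist only inside crystal_structure objects.

.element_data <- data.frame(
  symbol = c("H", "C", "N", "O", "F", "P", "S", "Cl"),
  mass   = c(1.008, 12.011, 14.007, 15.999, 18.998403, 30.973762, 32.06, 35.45),
  r_cov  = c(0.31, 0.76, 0.71, 0.66, 0.57, 1.07, 1.05, 1.02),
  stringsAsFactors = FALSE
)

# CODATA-style constants
.const <- list(
  hartree_J  = 4.3597447222071e-18,
  amu_kg     = 1.66053906660e-27,
  angstrom_m = 1e-10,
  c_cm_s     = 2.99792458e10
)

# sqrt(eigenvalue [Hartree / (amu Angstrom^2)]) * .freq_conv  ->  cm^-1
.freq_conv <- sqrt(.const$hartree_J / (.const$amu_kg * .const$angstrom_m^2)) /
  (2 * pi * .const$c_cm_s)

#' Atomic masses for element symbols
#' @param symbols character vector of element symbols
#' @return numeric vector of masses in amu
#' @export
element_mass <- function(symbols) {
  i <- match(symbols, .element_data$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol: ",
         paste(unique(symbols[is.na(i)]), collapse = ", "))
  }
  .element_data$mass[i]
}

#' Covalent radii (Cordero-style values) for element symbols
#' @param symbols character vector of element symbols
#' @return numeric vector of radii in Angstrom
#' @export
covalent_radius <- function(symbols) {
  i <- match(symbols, .element_data$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol: ",
         paste(unique(symbols[is.na(i)]), collapse = ", "))
  }
  .element_data$r_cov[i]
}

# Geometric unsaturation thresholds: a bond shorter than this for the given
# (sorted) element pair is treated as having multiple-bond character when
# flagging conjugated groups. The rule is a reproducible geometric stand-in
# for electronic-structure-based conjugation perception.
.unsat_threshold <- c(
  "C:C" = 1.45, "C:N" = 1.40, "C:O" = 1.30,
  "N:N" = 1.35, "N:O" = 1.35, "C:S" = 1.70, "O:O" = 1.35
)

# Link-atom X-H bond lengths used when capping severed covalent bonds.
.default_cap_lengths <- c(C = 1.09, N = 1.01, O = 0.96)

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = ":")
}

#' Round half away from zero
#'
#' Plain half-up rounding (3481.945 -> 3481.95 at 2 digits), used on all
#' reported frequency surfaces; base round() applies banker's rounding.
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
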