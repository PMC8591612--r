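# Physical constants and element data used across the package.
# Internal unit conventions:
#   SAXS:      q in 1/Angstrom, lengths in Angstrom, intensity in 1/Angstrom
#              (absolute scale; 1 mm^-1 == 1e-7 A^-1)
#   molecular: lengths in nm
#   AFM:       indentation nm, force nN, modulus GPa (1 GPa == 1 nN/nm^2)

#' Physical constants
#'
#' Gas constant (J mol^-1 K^-1), Avogadro number (mol^-1) and the classical
#' electron radius (Angstrom) as used throughout the package.
#'
#' @format Named numeric vector with elements `R_gas`, `N_A`, `r_e_A`.
#' @export
lnp_constants <- c(
  R_gas = 8.314462618,
  N_A   = 6.02214076e23,
  r_e_A = 2.8179403262e-5
)

# Element table: standard atomic weights, atomic numbers, approximate
# anomalous dispersion corrections f' at Cu K-alpha (8.05 keV, Henke tables),
# and Bondi van der Waals radii (nm).  f' values are small for light
# elements; they matter at the third significant figure of an X-ray SLD.
.element_table <- data.frame(
  symbol = c("H", "C", "N", "O", "Na", "P", "S", "Cl"),
  Z      = c(1, 6, 7, 8, 11, 15, 16, 17),
  mass   = c(1.008, 12.011, 14.007, 15.999, 22.990, 30.974, 32.06, 35.45),
  fprime = c(0.000, 0.018, 0.031, 0.049, 0.130, 0.283, 0.333, 0.364),
  vdw_nm = c(0.120, 0.170, 0.155, 0.152, 0.227, 0.180, 0.180, 0.175),
  stringsAsFactors = FALSE
)

.element_row <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  .element_table[i, , drop = FALSE]
}

#' Bondi van der Waals radii
#'
#' Returns the packaged Bondi van der Waals radius table used by the
#' solvent-accessible surface area calculation.
#'
#' @return Named numeric vector of radii in nm, named by element symbol.
#' @export
bondi_radii <- function() {
  stats::setNames(.element_table$vdw_nm, .element_table$symbol)
}

#' Molar mass from a chemical formula
#'
#' Parses a Hill-style formula such as `"C68H74O22"` and sums standard
#' atomic weights.
#'
#' @param formula Character formula, element symbols followed by optional
#'   integer counts.
#' @return Molar mass in g/mol.
#' @examples
#' molar_mass("H2O")
#' molar_mass("C68H74O22")
#' @export
molar_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse chemical formula: ", formula, call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", parts)
  cnts <- as.numeric(ifelse(grepl("[0-9]+$", parts),
                            sub("^[A-Za-z]+", "", parts), "1"))
  sum(.element_row(syms)$mass * cnts)
}

# Reference molar masses (g/mol) of the solvent species handled by the
# synthetic solvent-box generator.
.species_molar_mass <- c(
  water   = 18.015,
  acetone = 58.080,
  thf     = 72.107,
  dxn     = 88.106,
  dmso    = 78.133
)

.check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("`", name, "` must be positive and finite", call. = FALSE)
  }
  invisible(x)
}
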