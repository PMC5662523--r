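# Periodic-table reference data: element symbols and conventional atomic
# weights (IUPAC 2021 abridged values, 3-5 significant decimals; integer mass
# number of the most stable isotope for elements without a standard weight).
# Embedded as a static table so masses are reproducible with no runtime
# dependency on a chemistry toolkit.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

.element_weights <- c(
  1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948, 39.098, 40.078,
  44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546, 65.38,
  69.723, 72.630, 74.922, 78.971, 79.904, 83.798, 85.468, 87.62, 88.906, 91.224,
  92.906, 95.95, 97, 101.07, 102.91, 106.42, 107.87, 112.41, 114.82, 118.71,
  121.76, 127.60, 126.90, 131.29, 132.91, 137.33, 138.91, 140.12, 140.91, 144.24,
  145, 150.36, 151.96, 157.25, 158.93, 162.50, 164.93, 167.26, 168.93, 173.05,
  174.97, 178.49, 180.95, 183.84, 186.21, 190.23, 192.22, 195.08, 196.97, 200.59,
  204.38, 207.2, 208.98, 209, 210, 222, 223, 226, 227, 232.04,
  231.04, 238.03, 237, 244, 243, 247, 247, 251, 252, 257,
  258, 259, 266, 267, 268, 269, 270, 269, 278, 281,
  282, 285, 286, 289, 290, 293, 294, 294
)

#' Element symbol for an atomic number
#'
#' @param z Integer vector of atomic numbers (1-118).
#' @return Character vector of element symbols.
#' @examples
#' element_symbol(c(8, 1, 1))
#' @export
element_symbol <- function(z) {
  z <- as.integer(z)
  if (length(z) && (anyNA(z) || any(z < 1L) || any(z > 118L))) {
    stop("atomic numbers must be integers in [1, 118]", call. = FALSE)
  }
  .element_symbols[z]
}

#' Atomic number for an element symbol
#'
#' Case-sensitive on the conventional capitalization ("He", not "HE").
#'
#' @param symbol Character vector of element symbols.
#' @return Integer vector of atomic numbers.
#' @export
atomic_number <- function(symbol) {
  z <- match(symbol, .element_symbols)
  if (anyNA(z)) {
    bad <- unique(symbol[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  z
}

#' Standard atomic weight for an atomic number
#'
#' Conventional IUPAC weights from the table embedded in the package.
#'
#' @param z Integer vector of atomic numbers (1-118).
#' @return Numeric vector of atomic weights in amu.
#' @export
atomic_weight <- function(z) {
  element_symbol(z) # bounds check
  .element_weights[as.integer(z)]
}

# CODATA bohr radius in angstrom; single source of truth for unit conversion.
.bohr_to_angstrom <- 0.529177210903

# Closed unit vocabulary for physical quantities.
.quantity_units <- c(
  "hartree", "eV", "cm-1", "angstrom", "bohr", "amu", "debye", "dimensionless"
)
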