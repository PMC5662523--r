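# Core in-memory model: molecules, bonds, vibrational and volumetric data,
# calculations and unit-annotated quantities. Every codec and the data service
# maps into these types.

#' Construct a molecule
#'
#' A molecule holds atomic numbers, a flat 3N Cartesian coordinate vector in
#' angstrom (atom i occupies slots 3i+1..3i+3 in R's 1-based indexing), an
#' optional bond table, and optional identifier metadata. InChI/InChIKey are
#' accepted as metadata only; the package never computes them.
#'
#' @param atomic_numbers Integer vector of proton numbers, each in 1-118.
#' @param coords Numeric vector of length \code{3 * length(atomic_numbers)},
#'   angstrom, laid out x1,y1,z1,x2,...
#' @param bonds Data frame with integer columns \code{a}, \code{b} (0-based
#'   atom indices) and \code{order} (positive integer), or \code{NULL} for a
#'   molecule with no bond information.
#' @param name,inchi,inchikey,id Optional single strings.
#' @param extras Named list of pass-through fields preserved by the codecs.
#' @return An object of class \code{chem_molecule}.
#' @examples
#' water <- molecule(c(8, 1, 1),
#'                   c(0, 0, 0, 0.757, 0.586, 0, -0.757, 0.586, 0),
#'                   bonds = bond_table(c(0, 0), c(1, 2), c(1, 1)),
#'                   name = "water")
#' molecular_mass(water)
#' @export
molecule <- function(atomic_numbers, coords = numeric(3 * length(atomic_numbers)),
                     bonds = NULL, name = NULL, inchi = NULL, inchikey = NULL,
                     id = NULL, extras = list()) {
  mol <- structure(
    list(
      atomic_numbers = as.integer(atomic_numbers),
      coords = as.numeric(coords),
      bonds = if (is.null(bonds)) empty_bond_table() else as_bond_table(bonds),
      name = name, inchi = inchi, inchikey = inchikey, id = id,
      extras = extras
    ),
    class = "chem_molecule"
  )
  validate_molecule(mol)
  mol
}

#' Build a bond table
#'
#' @param a,b Integer vectors of 0-based atom indices.
#' @param order Integer vector of bond orders (default single bonds).
#' @return Data frame with columns \code{a}, \code{b}, \code{order}.
#' @export
bond_table <- function(a = integer(), b = integer(), order = rep(1L, length(a))) {
  data.frame(a = as.integer(a), b = as.integer(b), order = as.integer(order))
}

empty_bond_table <- function() bond_table()

as_bond_table <- function(x) {
  if (!is.data.frame(x) || !all(c("a", "b", "order") %in% names(x))) {
    stop("bonds must be a data frame with columns a, b, order", call. = FALSE)
  }
  bond_table(x$a, x$b, x$order)
}

#' Validate molecule invariants
#'
#' Checks the coordinate-length rule (3 slots per atom), atomic-number range,
#' and bond-index sanity. Errors list every violation found.
#'
#' @param mol A \code{chem_molecule}.
#' @return The molecule, invisibly, if valid.
#' @export
validate_molecule <- function(mol) {
  n <- length(mol$atomic_numbers)
  problems <- character()
  if (length(mol$coords) != 3L * n) {
    problems <- c(problems, sprintf(
      "coords length %d != 3 * atom count %d", length(mol$coords), n))
  }
  if (n > 0 && (anyNA(mol$atomic_numbers) ||
                any(mol$atomic_numbers < 1L) || any(mol$atomic_numbers > 118L))) {
    problems <- c(problems, "atomic numbers must lie in [1, 118]")
  }
  bt <- mol$bonds
  if (nrow(bt) > 0) {
    if (any(bt$a < 0L) || any(bt$b < 0L) || any(bt$a >= n) || any(bt$b >= n)) {
      problems <- c(problems, "bond endpoint index out of [0, atom_count)")
    }
    if (any(bt$a == bt$b)) problems <- c(problems, "bond endpoints must be distinct")
    if (any(bt$order < 1L)) problems <- c(problems, "bond order must be >= 1")
  }
  if (length(problems)) {
    stop("invalid molecule: ", paste(problems, collapse = "; "), call. = FALSE)
  }
  invisible(mol)
}

#' Number of atoms in a molecule
#' @param mol A \code{chem_molecule}.
#' @return Integer atom count.
#' @export
atom_count <- function(mol) length(mol$atomic_numbers)

#' @export
print.chem_molecule <- function(x, ...) {
  cat(sprintf("<molecule%s: %s, %d atoms, %d bonds>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              if (is.null(x$name)) hill_formula(x) else x$name,
              atom_count(x), nrow(x$bonds)))
  invisible(x)
}

#' Cartesian position of one atom
#'
#' Coordinates are stored as a flat array where the position of atom i starts
#' at offset 3i (0-based), so atom i maps to slots 3i+1..3i+3 of the R vector.
#'
#' @param mol A \code{chem_molecule}.
#' @param i 0-based atom index.
#' @return Numeric length-3 vector (x, y, z) in angstrom.
#' @export
atom_position <- function(mol, i) {
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 0L || i >= atom_count(mol)) {
    stop(sprintf("atom index %s out of range [0, %d)", i, atom_count(mol)),
         call. = FALSE)
  }
  mol$coords[(3L * i + 1L):(3L * i + 3L)]
}

#' Molecular mass
#'
#' Sum of the conventional standard atomic weights of all atoms.
#'
#' @param mol A \code{chem_molecule}.
#' @return Mass in amu; 0 for an empty molecule.
#' @export
molecular_mass <- function(mol) {
  if (atom_count(mol) == 0L) return(0)
  sum(atomic_weight(mol$atomic_numbers))
}

#' Hill-order molecular formula
#'
#' Carbon first, hydrogen second when carbon is present; otherwise all element
#' symbols in alphabetical order. Counts of one are omitted.
#'
#' @param mol A \code{chem_molecule}.
#' @return Formula string; empty string for an empty molecule.
#' @export
hill_formula <- function(mol) {
  z <- mol$atomic_numbers
  if (length(z) == 0L) return("")
  counts <- table(element_symbol(z))
  symbols <- sort(names(counts))
  if ("C" %in% symbols) {
    head <- intersect(c("C", "H"), symbols)
    symbols <- c(head, setdiff(symbols, head))
  }
  paste0(vapply(symbols, function(s) {
    k <- counts[[s]]
    if (k == 1L) s else paste0(s, k)
  }, character(1)), collapse = "")
}

#' Heavy-atom count
#'
#' Number of atoms that are not hydrogen.
#'
#' @param mol A \code{chem_molecule}.
#' @return Integer count.
#' @export
heavy_atom_count <- function(mol) sum(mol$atomic_numbers != 1L)

# ---------------------------------------------------------------------------
# Deterministic structure key
# ---------------------------------------------------------------------------

# Dual polynomial rolling hash over UTF-8 bytes; two independent (prime, base)
# pairs keep the digest well inside exact double arithmetic while giving a
# 16-hex-digit key.
.hash_string <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h1 <- 5381; h2 <- 99991
  p1 <- 2147483647; p2 <- 2147483629
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% p1
    h2 <- (h2 * 137 + b) %% p2
  }
  sprintf("%08x%08x", h1, h2)
}

#' Deterministic structure key
#'
#' A digest of the molecular graph — element multiset plus bond connectivity
#' with orders — that is invariant under reordering of the input atoms. Used
#' as the deduplication key for stored molecules when no InChIKey is supplied.
#' Atom labels are refined by iterative neighbourhood colouring
#' (Weisfeiler-Lehman style) before hashing, so any permutation of the same
#' graph yields the same key. It is a graph invariant, not a perfect canonical
#' code: distinct graphs hash to distinct keys in practice but without a
#' theoretical guarantee.
#'
#' @param mol A \code{chem_molecule}.
#' @return A 16-character hexadecimal string.
#' @export
structure_key <- function(mol) {
  n <- atom_count(mol)
  if (n == 0L) return(.hash_string("empty"))
  colors <- as.character(mol$atomic_numbers)
  bt <- mol$bonds
  # adjacency: list of (neighbor index, order) per atom
  nbr <- vector("list", n)
  if (nrow(bt) > 0) {
    for (k in seq_len(nrow(bt))) {
      a <- bt$a[k] + 1L; b <- bt$b[k] + 1L; o <- bt$order[k]
      nbr[[a]] <- rbind(nbr[[a]], c(b, o))
      nbr[[b]] <- rbind(nbr[[b]], c(a, o))
    }
  }
  for (round in seq_len(max(1L, n))) {
    new_colors <- vapply(seq_len(n), function(i) {
      sig <- if (is.null(nbr[[i]])) character() else
        sort(paste0(nbr[[i]][, 2], ":", colors[nbr[[i]][, 1]]))
      .hash_string(paste(colors[i], paste(sig, collapse = "|"), sep = "#"))
    }, character(1))
    if (length(unique(new_colors)) == length(unique(colors)) &&
        identical(match(new_colors, unique(new_colors)),
                  match(colors, unique(colors)))) {
      colors <- new_colors
      break
    }
    colors <- new_colors
  }
  edge_sigs <- if (nrow(bt) > 0) {
    sort(vapply(seq_len(nrow(bt)), function(k) {
      ends <- sort(c(colors[bt$a[k] + 1L], colors[bt$b[k] + 1L]))
      paste(ends[1], ends[2], bt$order[k], sep = "~")
    }, character(1)))
  } else character()
  .hash_string(paste(
    paste(sort(colors), collapse = ","),
    paste(edge_sigs, collapse = ","),
    sep = "//"))
}

# ---------------------------------------------------------------------------
# Quantities, vibrations, volumes, calculations
# ---------------------------------------------------------------------------

#' Unit-annotated physical quantity
#'
#' @param value Numeric value (scalar or vector).
#' @param units One of \code{"hartree"}, \code{"eV"}, \code{"cm-1"},
#'   \code{"angstrom"}, \code{"bohr"}, \code{"amu"}, \code{"debye"},
#'   \code{"dimensionless"}.
#' @return An object of class \code{chem_quantity}.
#' @export
quantity <- function(value, units) {
  if (!is.character(units) || length(units) != 1L || !(units %in% .quantity_units)) {
    stop("units must be one of: ", paste(.quantity_units, collapse = ", "),
         call. = FALSE)
  }
  structure(list(value = as.numeric(value), units = units),
            class = "chem_quantity")
}

#' Vibrational modes of a molecule
#'
#' @param frequencies Numeric vector, cm^-1.
#' @param modes List of flat 3N displacement vectors (unitless directions),
#'   one per frequency, or \code{NULL} when displacement vectors are not
#'   available (e.g. a log that reports only the frequency table).
#' @param intensities Optional numeric vector, km/mol, same length as
#'   \code{frequencies}.
#' @return An object of class \code{chem_vibrations}.
#' @export
vibrational_data <- function(frequencies, modes = NULL, intensities = NULL) {
  frequencies <- as.numeric(frequencies)
  if (!is.null(modes)) {
    modes <- lapply(modes, as.numeric)
    if (length(modes) != length(frequencies)) {
      stop("number of modes must equal number of frequencies", call. = FALSE)
    }
    if (length(modes) > 1 && length(unique(lengths(modes))) != 1L) {
      stop("all mode vectors must have the same length (3N)", call. = FALSE)
    }
  }
  if (!is.null(intensities)) {
    intensities <- as.numeric(intensities)
    if (length(intensities) != length(frequencies)) {
      stop("intensities must match frequencies in length", call. = FALSE)
    }
  }
  structure(list(frequencies = frequencies, intensities = intensities,
                 modes = modes),
            class = "chem_vibrations")
}

#' Volumetric data on a regular grid
#'
#' Cube-file convention: values vary fastest along z.
#'
#' @param origin Numeric length-3, angstrom.
#' @param spacing Numeric length-3 grid step, angstrom.
#' @param dims Integer length-3 (nx, ny, nz), all positive.
#' @param values Numeric vector of length \code{prod(dims)}.
#' @param label Text label, e.g. an orbital identifier.
#' @return An object of class \code{chem_volume}.
#' @export
volumetric_data <- function(origin, spacing, dims, values, label = "") {
  dims <- as.integer(dims)
  if (length(origin) != 3L || length(spacing) != 3L || length(dims) != 3L) {
    stop("origin, spacing and dims must each have length 3", call. = FALSE)
  }
  if (any(dims < 1L)) stop("grid dimensions must be positive", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) != prod(dims)) {
    stop(sprintf("values length %d != nx*ny*nz = %d",
                 length(values), prod(dims)), call. = FALSE)
  }
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = dims, values = values, label = label),
            class = "chem_volume")
}

#' Calculation record
#'
#' Provenance and results of one quantum-chemistry calculation, linked to its
#' parent molecule by id.
#'
#' @param id Opaque identifier string.
#' @param molecule_id Identifier of the parent molecule (non-empty).
#' @param code Name of the code that produced the result (e.g. "NWChem").
#' @param theory Level of theory (e.g. "scf", "dft").
#' @param calculation_types Character vector of type tags (e.g. "energy",
#'   "vibrational").
#' @param file_id Optional reference to the original output file.
#' @param properties Named list of \code{\link{quantity}} objects.
#' @param vibrations Optional \code{\link{vibrational_data}}.
#' @param volumes List of \code{\link{volumetric_data}}.
#' @return An object of class \code{chem_calculation}.
#' @export
calculation <- function(id, molecule_id, code = "", theory = "",
                        calculation_types = character(), file_id = NULL,
                        properties = list(), vibrations = NULL,
                        volumes = list()) {
  if (!is.character(molecule_id) || length(molecule_id) != 1L ||
      !nzchar(molecule_id)) {
    stop("molecule_id must be a non-empty string", call. = FALSE)
  }
  structure(list(id = id, molecule_id = molecule_id, code = code,
                 theory = theory,
                 calculation_types = as.character(calculation_types),
                 file_id = file_id, properties = properties,
                 vibrations = vibrations, volumes = volumes),
            class = "chem_calculation")
}
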