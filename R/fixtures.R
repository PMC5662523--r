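# Deterministic fixtures: the canonical water molecule used throughout the
# documentation and tests, and a seeded random-molecule generator so every
# suite runs without external data.

# Run code with a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Canonical water molecule
#'
#' The running example used across the codecs and the service: O at the
#' origin, both H in the xy plane, two O-H single bonds.
#'
#' @return A \code{\link{molecule}} named "water".
#' @examples
#' w <- canonical_water()
#' hill_formula(w)
#' @export
canonical_water <- function() {
  molecule(
    atomic_numbers = c(8L, 1L, 1L),
    coords = c(0, 0, 0, 0.757, 0.586, 0, -0.757, 0.586, 0),
    bonds = bond_table(a = c(0L, 0L), b = c(1L, 2L), order = c(1L, 1L)),
    name = "water"
  )
}

#' Seeded random molecule
#'
#' Generates a molecule that always satisfies the model invariants. Bonds are
#' drawn as a random spanning tree plus extra edges, so bond indices are
#' always valid and the graph is connected whenever bonds are requested at
#' all; with \code{bond_density = 0} no bonds are generated.
#'
#' @param seed Integer seed; the same seed always yields the same molecule.
#' @param n_atoms Length-2 integer range for the atom count.
#' @param elements Pool of atomic numbers to draw from.
#' @param bond_density Real in [0, 1]; 0 means no bonds, larger values add
#'   more extra edges beyond the spanning tree.
#' @return A validated \code{\link{molecule}}.
#' @export
random_molecule <- function(seed, n_atoms = c(2L, 12L),
                            elements = c(1L, 6L, 7L, 8L, 9L, 15L, 16L, 17L),
                            bond_density = 0.3) {
  stopifnot(length(n_atoms) == 2L, n_atoms[1] >= 1L, n_atoms[2] >= n_atoms[1],
            bond_density >= 0, bond_density <= 1)
  with_seed(seed, {
    n <- sample(n_atoms[1]:n_atoms[2], 1L)
    z <- sample(elements, n, replace = TRUE)
    coords <- round(runif(3L * n, -6, 6), 4)
    bonds <- NULL
    if (bond_density > 0 && n >= 2L) {
      a <- integer(); b <- integer()
      for (i in 2:n) { # spanning tree keeps indices connected and in range
        j <- if (i == 2L) 1L else sample(seq_len(i - 1L), 1L)
        a <- c(a, j - 1L); b <- c(b, i - 1L)
      }
      n_extra <- stats::rbinom(1L, n, bond_density / 2)
      for (k in seq_len(n_extra)) {
        pair <- sort(sample(seq_len(n), 2L)) - 1L
        dup <- any(a == pair[1] & b == pair[2])
        if (!dup) { a <- c(a, pair[1]); b <- c(b, pair[2]) }
      }
      bonds <- bond_table(a, b, order = sample(1:3, length(a), replace = TRUE,
                                               prob = c(0.8, 0.15, 0.05)))
    }
    molecule(z, coords, bonds = bonds, name = sprintf("random-%d", seed))
  })
}

#' Random vibrational data for a molecule
#'
#' Seeded generator of plausible mode data (3N-6 modes, or fewer for tiny
#' molecules) used by fixtures and tests.
#'
#' @param mol A \code{\link{molecule}}.
#' @param seed Integer seed.
#' @return A \code{\link{vibrational_data}} object, or \code{NULL} if the
#'   molecule has fewer than two atoms.
#' @export
random_vibrations <- function(mol, seed) {
  n <- atom_count(mol)
  n_modes <- max(3L * n - 6L, if (n >= 2L) 1L else 0L)
  if (n_modes == 0L) return(NULL)
  with_seed(seed, {
    freqs <- sort(round(runif(n_modes, 50, 4000), 2))
    ints <- round(runif(n_modes, 0, 500), 2)
    modes <- lapply(seq_len(n_modes), function(i) {
      v <- runif(3L * n, -1, 1)
      round(v / max(abs(v)), 5)
    })
    vibrational_data(freqs, modes, ints)
  })
}

#' Random atom-order permutation of a molecule
#'
#' Reorders atoms (and remaps bond indices accordingly); the result describes
#' the same molecular graph and geometry as the input.
#'
#' @param mol A \code{\link{molecule}}.
#' @param seed Integer seed.
#' @return A permuted \code{\link{molecule}}.
#' @export
permute_molecule <- function(mol, seed) {
  n <- atom_count(mol)
  if (n < 2L) return(mol)
  with_seed(seed, {
    perm <- sample(n) # new order: position k holds old atom perm[k]
    inv <- integer(n); inv[perm] <- seq_len(n)
    coords <- as.numeric(vapply(perm, function(i) atom_position(mol, i - 1L),
                                numeric(3)))
    bt <- mol$bonds
    bonds <- if (nrow(bt) > 0) {
      bond_table(inv[bt$a + 1L] - 1L, inv[bt$b + 1L] - 1L, bt$order)
    } else NULL
    molecule(mol$atomic_numbers[perm], coords, bonds = bonds, name = mol$name,
             inchi = mol$inchi, inchikey = mol$inchikey, id = mol$id)
  })
}
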