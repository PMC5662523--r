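# ChemLog JSON codec: the object-oriented, unit-annotated dialect that
# replaces a quantum-chemistry log file. A document carries an ordered
# "calculations" array; shared objects (molecules, basis sets, setups, atoms)
# are written once with an "id" tag and referenced afterwards by that tag
# string — a pointer to the first mention, in strict document order.
#
# Dialect (documented package decision):
#   simulation            pass-through metadata (code, version, ...)
#   calculations[]        one object per calculation in run order
#     id                  "Calculation.k"
#     calculationSetup    {id, theory, task, basisSet: {id, name} | "BasisSet.j"}
#     molecule            {id, atoms: [{id, element, coordinates: {value,
#                          units}}]} | "Molecule.j"
#     calculationResults  named quantities {value, units}, vibrational data,
#                          per-atom properties carrying an "atom" reference
# A string value under the keys molecule / basisSet / calculationSetup / atom
# is a reference; strings elsewhere are literals.

.chemlog_ref_keys <- c("molecule", "basisSet", "calculationSetup", "atom")

is_json_object <- function(x) is.list(x) && !is.null(names(x))

# Depth-first, document-order walk. Registers every object bearing an "id"
# and checks every reference string against the ids seen so far.
chemlog_scan <- function(tree) {
  registry <- list()
  errors <- character()
  walk <- function(node, path) {
    if (is_json_object(node)) {
      id <- node$id
      if (!is.null(id) && is.character(id) && length(id) == 1L) {
        if (!is.null(registry[[id]])) {
          errors <<- c(errors, sprintf(
            "duplicate id-tag \"%s\" at %s (already defined)", id, path))
        } else {
          registry[[id]] <<- node
        }
      }
      for (key in names(node)) {
        child <- node[[key]]
        if (key %in% .chemlog_ref_keys && is.character(child) &&
            length(child) == 1L) {
          if (!nzchar(child) || is.null(registry[[child]])) {
            errors <<- c(errors, sprintf(
              "unresolved reference \"%s\" at %s.%s (no earlier id-tag)",
              child, path, key))
          }
        } else {
          walk(child, paste0(path, ".", key))
        }
      }
    } else if (is.list(node)) {
      for (i in seq_along(node)) walk(node[[i]], sprintf("%s[%d]", path, i - 1L))
    }
  }
  walk(tree, "$")
  list(registry = registry, errors = errors)
}

#' Construct a ChemLog document from a raw tree
#'
#' Builds the id-tag registry in document order and checks every reference.
#' References must point to an id-tag defined earlier in the document
#' (pointer to the first mention); forward or dangling references and
#' duplicate id-tags are rejected.
#'
#' @param tree Nested list in the ChemLog layout (as produced by
#'   \code{jsonlite::fromJSON(text, simplifyVector = FALSE)} or built in code).
#' @return An object of class \code{chemlog_document} with fields
#'   \code{tree}, \code{calculations} and \code{registry}.
#' @export
chemlog_document <- function(tree) {
  if (!is_json_object(tree) || is.null(tree$calculations) ||
      !is.list(tree$calculations)) {
    stop("ChemLog document must be an object with a \"calculations\" array",
         call. = FALSE)
  }
  scan <- chemlog_scan(tree)
  if (length(scan$errors)) {
    stop("invalid ChemLog document:\n",
         paste0("  ", scan$errors, collapse = "\n"), call. = FALSE)
  }
  structure(list(tree = tree, calculations = tree$calculations,
                 registry = scan$registry),
            class = "chemlog_document")
}

#' Parse ChemLog JSON text
#'
#' @param text JSON text in the ChemLog dialect.
#' @return A \code{\link{chemlog_document}}.
#' @export
parse_chemlog <- function(text) {
  chemlog_document(json_read(text))
}

#' @export
print.chemlog_document <- function(x, ...) {
  cat(sprintf("<ChemLog document: %d calculation(s), %d id-tag(s)>\n",
              length(x$calculations), length(x$registry)))
  invisible(x)
}

#' Resolve an id-tag reference
#'
#' Returns the registry object for an id-tag; resolving the same tag twice
#' returns the identical object.
#'
#' @param doc A \code{\link{chemlog_document}}.
#' @param idtag Reference string, e.g. \code{"Molecule.2"}.
#' @return The referenced object (a named list).
#' @export
resolve_reference <- function(doc, idtag) {
  stopifnot(inherits(doc, "chemlog_document"))
  if (!is.character(idtag) || length(idtag) != 1L || !nzchar(idtag) ||
      is.null(doc$registry[[idtag]])) {
    stop(sprintf("cannot resolve id-tag \"%s\"", as.character(idtag)[1]),
         call. = FALSE)
  }
  doc$registry[[idtag]]
}

# Resolve a field that may be inline or a reference string.
chemlog_deref <- function(doc, x) {
  if (is.character(x) && length(x) == 1L) resolve_reference(doc, x) else x
}

# Replace any repeated inline object whose id was already emitted with its
# id-tag string; error if two different objects claim the same id.
chemlog_dedup <- function(tree) {
  seen <- list()
  walk <- function(node) {
    if (is_json_object(node)) {
      id <- node$id
      if (!is.null(id) && is.character(id) && length(id) == 1L) {
        if (!is.null(seen[[id]])) {
          if (!identical(seen[[id]], node)) {
            stop(sprintf(
              "two different objects carry the id-tag \"%s\"", id),
              call. = FALSE)
          }
          return(id) # subsequent mention -> reference string
        }
        seen[[id]] <<- node
      }
      for (key in names(node)) node[[key]] <- walk(node[[key]])
      node
    } else if (is.list(node)) {
      lapply(node, walk)
    } else {
      node
    }
  }
  walk(tree)
}

#' Write ChemLog JSON text
#'
#' The first mention of each id-tagged object is written inline; any later
#' inline repetition of the same object is replaced by its id-tag reference
#' string, so no object is ever serialized twice. \code{parse_chemlog} of the
#' output reproduces the document.
#'
#' @param doc A \code{\link{chemlog_document}}.
#' @param pretty Pretty-print the JSON (default TRUE).
#' @return JSON text.
#' @export
write_chemlog <- function(doc, pretty = TRUE) {
  stopifnot(inherits(doc, "chemlog_document"))
  tree <- chemlog_dedup(doc$tree)
  as.character(jsonlite::toJSON(tree, auto_unbox = TRUE, digits = NA,
                                pretty = pretty, null = "null"))
}

chemlog_coord_to_angstrom <- function(value, units) {
  switch(units,
         angstrom = value,
         bohr = value * .bohr_to_angstrom,
         stop(sprintf("unsupported coordinate units \"%s\"", units),
              call. = FALSE))
}

#' Extract a core-model molecule from a ChemLog calculation
#'
#' Flattens the per-atom objects of one calculation's molecule (resolving a
#' reference if needed) into the core arrays, converting each atom's
#' coordinates to angstrom using its declared units.
#'
#' @param doc A \code{\link{chemlog_document}}.
#' @param calc_index 1-based calculation index.
#' @return A \code{\link{molecule}}; its \code{id} is the ChemLog id-tag.
#' @export
extract_molecule <- function(doc, calc_index = 1L) {
  stopifnot(inherits(doc, "chemlog_document"))
  n_calc <- length(doc$calculations)
  calc_index <- as.integer(calc_index)
  if (length(calc_index) != 1L || is.na(calc_index) ||
      calc_index < 1L || calc_index > n_calc) {
    stop(sprintf("calculation index %s out of range [1, %d]",
                 calc_index, n_calc), call. = FALSE)
  }
  calc <- doc$calculations[[calc_index]]
  molobj <- chemlog_deref(doc, calc$molecule)
  if (is.null(molobj) || is.null(molobj$atoms)) {
    stop("calculation has no molecule with atoms", call. = FALSE)
  }
  atoms <- molobj$atoms
  z <- integer(length(atoms))
  coords <- numeric(3L * length(atoms))
  for (i in seq_along(atoms)) {
    atom <- atoms[[i]]
    if (is.null(atom$element) || is.null(atom$coordinates)) {
      stop(sprintf("atom %d is missing element or coordinates", i),
           call. = FALSE)
    }
    z[i] <- atomic_number(atom$element)
    xyz <- num_vec(atom$coordinates$value)
    if (length(xyz) != 3L) {
      stop(sprintf("atom %d coordinates must have 3 components", i),
           call. = FALSE)
    }
    units <- atom$coordinates$units
    if (is.null(units)) units <- "angstrom"
    coords[(3L * i - 2L):(3L * i)] <- chemlog_coord_to_angstrom(xyz, units)
  }
  molecule(z, coords,
           name = if (is.null(molobj$name)) NULL else molobj$name,
           id = if (is.null(molobj$id)) NULL else molobj$id)
}

# Pull vibrational results (if any) out of a calculation's results block.
chemlog_vibrations <- function(calc) {
  res <- calc$calculationResults
  if (is.null(res) || is.null(res$vibrationalFrequencies)) return(NULL)
  freqs <- num_vec(res$vibrationalFrequencies$value)
  ints <- if (!is.null(res$vibrationalIntensities)) {
    num_vec(res$vibrationalIntensities$value)
  } else NULL
  modes <- if (is.null(res$normalModes)) NULL else
    lapply(res$normalModes, num_vec)
  vibrational_data(freqs, modes = modes, intensities = ints)
}
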