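# Chemical JSON codec: the array-oriented dialect aimed at visualization and
# single-document storage. Atoms, bonds, vibrations and volumetric data are
# stored in flat arrays; the 3D position of atom N starts at offset 3N in the
# coordinate array.
#
# Dialect (documented package decision):
#   chemicalJson          version integer (1)
#   name / inchi / inchikey
#   atoms.elements.number  [z1, z2, ...]
#   atoms.coords.3d        [x1, y1, z1, x2, ...]
#   bonds.connections.index [a1, b1, a2, b2, ...]   (0-based)
#   bonds.order            [o1, o2, ...]
#   vibrations.frequencies / .intensities / .eigenVectors
#   volume.origin / .spacing / .dimensions / .values / .label
# Unknown top-level keys round-trip untouched through the molecule's extras.

.cjson_known_keys <- c("chemicalJson", "name", "inchi", "inchikey",
                       "atoms", "bonds", "vibrations", "volume")

json_read <- function(text) {
  jsonlite::fromJSON(text, simplifyVector = FALSE)
}

num_vec <- function(x) if (length(x) == 0L) numeric() else as.numeric(unlist(x))
int_vec <- function(x) if (length(x) == 0L) integer() else as.integer(unlist(x))

violation <- function(path, message) data.frame(path = path, message = message,
                                                stringsAsFactors = FALSE)

no_violations <- function() data.frame(path = character(), message = character(),
                                       stringsAsFactors = FALSE)

is_num_list <- function(x) {
  is.list(x) && all(vapply(x, function(v) is.numeric(v) && length(v) == 1L,
                           logical(1)))
}

#' Validate a parsed Chemical JSON document
#'
#' Structural validation of a document already parsed into an R list (see
#' \code{jsonlite::fromJSON} with \code{simplifyVector = FALSE}). Violations
#' are returned as data, not raised: each row carries the JSON path of the
#' problem and a message.
#'
#' @param doc A list as returned by \code{jsonlite::fromJSON(text,
#'   simplifyVector = FALSE)}.
#' @return A data frame with columns \code{path} and \code{message}; zero rows
#'   when the document is valid.
#' @export
validate_cjson <- function(doc) {
  v <- no_violations()
  if (!is.list(doc)) {
    return(violation("$", "document must be a JSON object"))
  }
  elements <- int_vec(doc$atoms$elements$number)
  coords <- num_vec(doc$atoms$coords[["3d"]])
  n <- length(elements)
  if (is.null(doc$atoms)) {
    v <- rbind(v, violation("$.atoms", "missing atoms section"))
  } else {
    if (length(elements) &&
        (anyNA(elements) || any(elements < 1L) || any(elements > 118L))) {
      v <- rbind(v, violation("$.atoms.elements.number",
                              "atomic numbers must lie in [1, 118]"))
    }
    if (length(coords) != 3L * n) {
      v <- rbind(v, violation("$.atoms.coords.3d", sprintf(
        "coordinate array length %d != 3 * element count %d (3N layout)",
        length(coords), n)))
    }
  }
  if (!is.null(doc$bonds)) {
    conn <- int_vec(doc$bonds$connections$index)
    ord <- int_vec(doc$bonds$order)
    if (length(conn) %% 2L != 0L) {
      v <- rbind(v, violation("$.bonds.connections.index",
                              "connection index array length must be even"))
    } else {
      if (length(ord) != length(conn) / 2L) {
        v <- rbind(v, violation("$.bonds.order", sprintf(
          "order array length %d != connection pairs %d",
          length(ord), length(conn) / 2L)))
      }
      if (length(conn) && (any(conn < 0L) || any(conn >= n))) {
        v <- rbind(v, violation("$.bonds.connections.index", sprintf(
          "bond endpoint index out of range [0, %d)", n)))
      }
      if (length(conn) >= 2L) {
        a <- conn[seq(1L, length(conn), by = 2L)]
        b <- conn[seq(2L, length(conn), by = 2L)]
        if (any(a == b)) {
          v <- rbind(v, violation("$.bonds.connections.index",
                                  "bond endpoints must be distinct"))
        }
      }
    }
    if (length(ord) && any(ord < 1L)) {
      v <- rbind(v, violation("$.bonds.order", "bond order must be >= 1"))
    }
  }
  if (!is.null(doc$vibrations)) {
    freqs <- num_vec(doc$vibrations$frequencies)
    evs <- doc$vibrations$eigenVectors
    if (!is.null(evs) && length(evs) != length(freqs)) {
      v <- rbind(v, violation("$.vibrations.eigenVectors", sprintf(
        "number of eigenvectors %d != number of frequencies %d",
        length(evs), length(freqs))))
    } else if (!is.null(evs)) {
      bad <- which(vapply(evs, function(m) length(unlist(m)) != 3L * n,
                          logical(1)))
      for (i in bad) {
        v <- rbind(v, violation(sprintf("$.vibrations.eigenVectors[%d]", i - 1L),
                                sprintf("mode vector length != 3N = %d", 3L * n)))
      }
    }
    ints <- doc$vibrations$intensities
    if (!is.null(ints) && length(ints) != length(freqs)) {
      v <- rbind(v, violation("$.vibrations.intensities",
                              "intensities length != frequencies length"))
    }
  }
  if (!is.null(doc$volume)) {
    dims <- int_vec(doc$volume$dimensions)
    vals <- num_vec(doc$volume$values)
    if (length(dims) != 3L || any(dims < 1L)) {
      v <- rbind(v, violation("$.volume.dimensions",
                              "dimensions must be 3 positive integers"))
    } else if (length(vals) != prod(dims)) {
      v <- rbind(v, violation("$.volume.values", sprintf(
        "values length %d != nx*ny*nz = %d", length(vals), prod(dims))))
    }
  }
  v
}

#' Parse Chemical JSON text
#'
#' Parses and validates a Chemical JSON document and maps it onto the core
#' model. Unknown top-level keys are preserved in the molecule's
#' \code{extras} so that a write after a parse round-trips them untouched.
#'
#' @param text JSON text.
#' @return A list with components \code{molecule} (a \code{\link{molecule}}),
#'   \code{vibrations} (\code{\link{vibrational_data}} or \code{NULL}) and
#'   \code{volume} (\code{\link{volumetric_data}} or \code{NULL}).
#' @export
parse_cjson <- function(text) {
  doc <- json_read(text)
  v <- validate_cjson(doc)
  if (nrow(v) > 0) {
    stop("invalid Chemical JSON:\n",
         paste(sprintf("  %s: %s", v$path, v$message), collapse = "\n"),
         call. = FALSE)
  }
  elements <- int_vec(doc$atoms$elements$number)
  coords <- num_vec(doc$atoms$coords[["3d"]])
  bonds <- NULL
  if (!is.null(doc$bonds)) {
    conn <- int_vec(doc$bonds$connections$index)
    if (length(conn)) {
      bonds <- bond_table(conn[seq(1L, length(conn), by = 2L)],
                          conn[seq(2L, length(conn), by = 2L)],
                          int_vec(doc$bonds$order))
    }
  }
  extras <- doc[setdiff(names(doc), .cjson_known_keys)]
  mol <- molecule(elements, coords, bonds = bonds,
                  name = if (is.null(doc$name)) NULL else as.character(doc$name),
                  inchi = if (is.null(doc$inchi)) NULL else as.character(doc$inchi),
                  inchikey = if (is.null(doc$inchikey)) NULL else as.character(doc$inchikey),
                  extras = extras)
  vib <- NULL
  if (!is.null(doc$vibrations)) {
    ints <- doc$vibrations$intensities
    evs <- doc$vibrations$eigenVectors
    vib <- vibrational_data(
      num_vec(doc$vibrations$frequencies),
      modes = if (is.null(evs)) NULL else lapply(evs, num_vec),
      intensities = if (is.null(ints)) NULL else num_vec(ints))
  }
  vol <- NULL
  if (!is.null(doc$volume)) {
    vol <- volumetric_data(num_vec(doc$volume$origin),
                           num_vec(doc$volume$spacing),
                           int_vec(doc$volume$dimensions),
                           num_vec(doc$volume$values),
                           label = if (is.null(doc$volume$label)) "" else
                             as.character(doc$volume$label))
  }
  list(molecule = mol, vibrations = vib, volume = vol)
}

cjson_tree <- function(mol, vibrations = NULL, volume = NULL) {
  doc <- list(chemicalJson = 1L)
  if (!is.null(mol$name)) doc$name <- mol$name
  if (!is.null(mol$inchi)) doc$inchi <- mol$inchi
  if (!is.null(mol$inchikey)) doc$inchikey <- mol$inchikey
  doc$atoms <- list(
    elements = list(number = I(mol$atomic_numbers)),
    coords = list(`3d` = I(mol$coords)))
  bt <- mol$bonds
  if (nrow(bt) > 0) {
    doc$bonds <- list(
      connections = list(index = I(as.integer(rbind(bt$a, bt$b)))),
      order = I(bt$order))
  }
  if (!is.null(vibrations)) {
    vb <- list(frequencies = I(vibrations$frequencies))
    if (!is.null(vibrations$intensities)) {
      vb$intensities <- I(vibrations$intensities)
    }
    if (!is.null(vibrations$modes)) {
      vb$eigenVectors <- lapply(vibrations$modes, I)
    }
    doc$vibrations <- vb
  }
  if (!is.null(volume)) {
    doc$volume <- list(origin = I(volume$origin), spacing = I(volume$spacing),
                       dimensions = I(volume$dims), values = I(volume$values),
                       label = volume$label)
  }
  for (k in names(mol$extras)) doc[[k]] <- mol$extras[[k]]
  doc
}

#' Write Chemical JSON text
#'
#' Emits a single self-contained document. Numbers are serialized at full
#' precision so a parse of the output reproduces the input field-by-field.
#'
#' @param mol A \code{\link{molecule}}.
#' @param vibrations Optional \code{\link{vibrational_data}}.
#' @param volume Optional \code{\link{volumetric_data}}.
#' @param pretty Pretty-print the JSON (default TRUE).
#' @return JSON text (single string).
#' @export
write_cjson <- function(mol, vibrations = NULL, volume = NULL, pretty = TRUE) {
  validate_molecule(mol)
  doc <- cjson_tree(mol, vibrations, volume)
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                pretty = pretty, null = "null"))
}
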