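# In-memory molecule and calculation store with an optional newline-delimited
# JSON journal for persistence. A molecular graph is stored once: molecules
# are deduplicated by InChIKey when supplied, otherwise by the deterministic
# structure key. Calculations always reference a parent molecule.

#' Create a molecule/calculation store
#'
#' @param path Optional journal file; every accepted upload is appended as one
#'   JSON line and the file is replayed on creation, so a store can be
#'   reopened from disk.
#' @param seed Integer seed for id generation (ids are 24-hex-character
#'   strings, deterministic per store seed and insertion order).
#' @return An object of class \code{chem_store} (an environment).
#' @export
chem_store <- function(path = NULL, seed = 1L) {
  store <- new.env(parent = emptyenv())
  store$molecules <- list()    # id -> molecule
  store$mol_order <- character()
  store$mol_index <- list()    # dedup key -> id
  store$calcs <- list()        # id -> calculation record
  store$calc_order <- character()
  store$calc_by_mol <- list()  # molecule id -> character vector of calc ids
  store$counter <- 0L
  store$seed <- as.integer(seed)
  store$path <- path
  store$replaying <- FALSE
  class(store) <- "chem_store"
  if (!is.null(path) && file.exists(path)) {
    store$replaying <- TRUE
    for (line in readLines(path, warn = FALSE)) {
      if (!nzchar(trimws(line))) next
      entry <- json_read(line)
      if (identical(entry$op, "molecule")) {
        store_add_molecule(store, parse_cjson(entry$cjson)$molecule)
      } else if (identical(entry$op, "calculations")) {
        store_upload_calculations(store, entry$chemlog)
      }
    }
    store$replaying <- FALSE
  }
  store
}

#' @export
print.chem_store <- function(x, ...) {
  cat(sprintf("<chem_store: %d molecule(s), %d calculation(s)>\n",
              length(x$mol_order), length(x$calc_order)))
  invisible(x)
}

next_id <- function(store) {
  store$counter <- store$counter + 1L
  a <- .hash_string(sprintf("id:%d:%d", store$seed, store$counter))
  b <- .hash_string(sprintf("salt:%d:%d", store$counter, store$seed))
  paste0(a, substr(b, 1L, 8L))
}

journal_append <- function(store, entry) {
  if (is.null(store$path) || store$replaying) return(invisible())
  line <- as.character(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA))
  cat(line, "\n", sep = "", file = store$path, append = TRUE)
}

mol_dedup_key <- function(mol) {
  if (!is.null(mol$inchikey) && nzchar(mol$inchikey)) {
    paste0("ik:", mol$inchikey)
  } else {
    paste0("sk:", structure_key(mol))
  }
}

#' Add a molecule to the store
#'
#' Deduplicated on the uniqueness index (InChIKey when present, otherwise the
#' structure key): adding an already-known structure returns the existing id.
#'
#' @param store A \code{\link{chem_store}}.
#' @param mol A \code{\link{molecule}}.
#' @return The molecule id (24-hex string).
#' @export
store_add_molecule <- function(store, mol) {
  validate_molecule(mol)
  key <- mol_dedup_key(mol)
  existing <- store$mol_index[[key]]
  if (!is.null(existing)) return(existing)
  id <- next_id(store)
  mol$id <- id
  store$molecules[[id]] <- mol
  store$mol_order <- c(store$mol_order, id)
  store$mol_index[[key]] <- id
  journal_append(store, list(op = "molecule",
                             cjson = write_cjson(mol, pretty = FALSE)))
  id
}

#' Retrieve a stored molecule by id
#' @param store A \code{\link{chem_store}}.
#' @param id Molecule id.
#' @return The \code{\link{molecule}}, or NULL when unknown.
#' @export
store_get_molecule <- function(store, id) store$molecules[[id]]

#' Molecules in insertion order
#' @param store A \code{\link{chem_store}}.
#' @return Named list of molecules keyed by id.
#' @export
store_molecules <- function(store) {
  stats::setNames(lapply(store$mol_order, function(id) store$molecules[[id]]),
                  store$mol_order)
}

mol_summary <- function(mol) {
  list(id = mol$id, inchikey = mol$inchikey, name = mol$name)
}

#' Upload a ChemLog document to the store
#'
#' Extracts each calculation's molecule (deduplicated store-wide), then
#' records one calculation per entry of the calculations array with its
#' provenance (code, theory, calculation types) and results (mapped Chemical
#' JSON, vibrational data).
#'
#' @param store A \code{\link{chem_store}}.
#' @param text ChemLog JSON text (or an already parsed
#'   \code{\link{chemlog_document}}).
#' @return A list with \code{moleculeId} (parent molecule of the first
#'   calculation), \code{moleculeIds} (one per calculation) and
#'   \code{calculationIds}.
#' @export
store_upload_calculations <- function(store, text) {
  doc <- if (inherits(text, "chemlog_document")) text else parse_chemlog(text)
  code <- doc$tree$simulation$code
  if (is.null(code)) code <- "unknown"
  mol_ids <- character()
  calc_ids <- character()
  for (k in seq_along(doc$calculations)) {
    calc <- doc$calculations[[k]]
    mol <- extract_molecule(doc, k)
    mol$id <- NULL # store assigns ids
    mol_id <- store_add_molecule(store, mol)
    setup <- chemlog_deref(doc, calc$calculationSetup)
    theory <- if (is.null(setup$theory)) "unknown" else setup$theory
    vib <- chemlog_vibrations(calc)
    types <- if (!is.null(setup$task)) as.character(setup$task) else "energy"
    if (!is.null(vib) && !("frequency" %in% types)) {
      types <- unique(c(types, "vibrational"))
    }
    props <- list()
    te <- calc$calculationResults$totalEnergy
    if (!is.null(te)) props$totalEnergy <- quantity(te$value, te$units)
    id <- next_id(store)
    rec <- calculation(id = id, molecule_id = mol_id, code = code,
                       theory = theory, calculation_types = types,
                       file_id = if (is.null(calc$fileId)) NULL else calc$fileId,
                       properties = props, vibrations = vib)
    rec$cjson <- chemlog_to_cjson(doc, k)
    store$calcs[[id]] <- rec
    store$calc_order <- c(store$calc_order, id)
    store$calc_by_mol[[mol_id]] <- c(store$calc_by_mol[[mol_id]], id)
    mol_ids <- c(mol_ids, mol_id)
    calc_ids <- c(calc_ids, id)
  }
  journal_append(store, list(
    op = "calculations",
    chemlog = write_chemlog(doc, pretty = FALSE)))
  list(moleculeId = mol_ids[1], moleculeIds = mol_ids,
       calculationIds = calc_ids)
}

#' Calculations stored for a molecule
#'
#' @param store A \code{\link{chem_store}}.
#' @param molecule_id Parent molecule id.
#' @return List of calculation records (possibly empty).
#' @export
store_calculations_for <- function(store, molecule_id) {
  ids <- store$calc_by_mol[[molecule_id]]
  lapply(ids, function(id) store$calcs[[id]])
}

#' Retrieve a stored calculation by id
#' @param store A \code{\link{chem_store}}.
#' @param id Calculation id.
#' @return The calculation record, or NULL when unknown.
#' @export
store_get_calculation <- function(store, id) store$calcs[[id]]

#' Store-wide referential integrity check
#'
#' @param store A \code{\link{chem_store}}.
#' @return TRUE if every calculation's molecule id resolves to a stored
#'   molecule, otherwise FALSE.
#' @export
store_integrity_ok <- function(store) {
  all(vapply(store$calc_order, function(id) {
    !is.null(store$molecules[[store$calcs[[id]]$molecule_id]])
  }, logical(1)))
}
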