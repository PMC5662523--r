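# Format conversion: ChemLog -> Chemical JSON mapping, the general
# dispatcher between xyz / cml / cjson / chemlog, and vibrational-mode
# animation frames.

.chem_formats <- c("xyz", "cml", "cjson", "chemlog")
.chem_write_formats <- c("xyz", "cml", "cjson")

normalize_format <- function(x) {
  f <- tolower(as.character(x)[1])
  if (!(f %in% .chem_formats)) {
    stop(sprintf("unknown format \"%s\"; supported: %s", x,
                 paste(.chem_formats, collapse = ", ")), call. = FALSE)
  }
  f
}

#' Map a ChemLog calculation to a Chemical JSON document
#'
#' Flattens the per-atom objects into the array layout, carries vibrational
#' results (frequencies, intensities, normal modes) into the vibrations
#' section when present, and records provenance (code, theory) in a
#' \code{metadata} block.
#'
#' @param doc A \code{\link{chemlog_document}}.
#' @param calc_index 1-based calculation index.
#' @return The Chemical JSON document as a nested list; serialize with
#'   \code{\link{cjson_text}}.
#' @export
chemlog_to_cjson <- function(doc, calc_index = 1L) {
  mol <- extract_molecule(doc, calc_index)
  calc <- doc$calculations[[calc_index]]
  vib <- chemlog_vibrations(calc)
  setup <- chemlog_deref(doc, calc$calculationSetup)
  meta <- list()
  code <- doc$tree$simulation$code
  if (!is.null(code)) meta$code <- code
  if (!is.null(setup$theory)) meta$theory <- setup$theory
  if (length(meta)) mol$extras$metadata <- meta
  cjson_tree(mol, vibrations = vib)
}

#' Serialize a Chemical JSON document tree
#'
#' @param tree Nested list as produced by \code{\link{chemlog_to_cjson}}.
#' @param pretty Pretty-print (default TRUE).
#' @return JSON text.
#' @export
cjson_text <- function(tree, pretty = TRUE) {
  as.character(jsonlite::toJSON(tree, auto_unbox = TRUE, digits = NA,
                                pretty = pretty, null = "null"))
}

#' Convert between molecular file formats
#'
#' Reads the input in \code{from}, maps it through the core molecule model,
#' and writes it in \code{to}. ChemLog is a read-only source (its first
#' calculation is converted); xyz, cml and cjson are both sources and
#' targets. Conversions that pass through XYZ lose bond information — a
#' format limitation flagged in the result rather than silently dropped.
#'
#' @param input Input text.
#' @param from,to Format names (case-insensitive): \code{"xyz"},
#'   \code{"cml"}, \code{"cjson"}; \code{"chemlog"} as \code{from} only.
#' @return An object of class \code{chem_conversion}: a list with
#'   \code{text} (the converted document) and \code{lossy} (character vector
#'   of loss warnings, empty when the conversion is faithful).
#' @export
chem_convert <- function(input, from, to) {
  from <- normalize_format(from)
  to <- normalize_format(to)
  if (!(to %in% .chem_write_formats)) {
    stop(sprintf(
      "unsupported conversion target \"%s\"; supported pairs: {%s} -> {%s}",
      to, paste(.chem_formats, collapse = ","),
      paste(.chem_write_formats, collapse = ",")), call. = FALSE)
  }
  vib <- NULL; vol <- NULL
  mol <- switch(from,
    xyz = read_xyz(input),
    cml = read_cml(input),
    cjson = {
      parsed <- parse_cjson(input)
      vib <- parsed$vibrations; vol <- parsed$volume
      parsed$molecule
    },
    chemlog = {
      doc <- parse_chemlog(input)
      vib <- chemlog_vibrations(doc$calculations[[1]])
      extract_molecule(doc, 1L)
    })
  lossy <- character()
  if (from == "xyz" && nrow(mol$bonds) == 0L) {
    # nothing to lose coming from xyz, but note the format carries no bonds
  }
  if (to == "xyz") {
    if (nrow(mol$bonds) > 0L) {
      lossy <- c(lossy, "xyz output drops bond information")
    }
    if (!is.null(vib)) lossy <- c(lossy, "xyz output drops vibrational data")
  }
  if (to == "cml" && !is.null(vib)) {
    lossy <- c(lossy, "cml output drops vibrational data")
  }
  text <- switch(to,
    xyz = write_xyz(mol),
    cml = write_cml(mol),
    cjson = write_cjson(mol, vibrations = vib, volume = vol))
  structure(list(text = text, lossy = lossy), class = "chem_conversion")
}

#' @export
print.chem_conversion <- function(x, ...) {
  cat(x$text)
  if (length(x$lossy)) cat("## lossy:", paste(x$lossy, collapse = "; "), "\n")
  invisible(x)
}

#' Animation frames for a vibrational mode
#'
#' Produces a looping sequence of coordinate arrays displacing the
#' equilibrium geometry along one normal mode. The displacement vector is
#' normalized to unit max-norm, then frame k (0-based) is
#' \code{r0 + amplitude * sin(2 pi k / n_frames) * d}. Frame 0 is the
#' equilibrium geometry and the sequence loops.
#'
#' @param mol A \code{\link{molecule}} giving the equilibrium geometry.
#' @param vib A \code{\link{vibrational_data}}.
#' @param mode_index 1-based mode index.
#' @param amplitude Peak displacement in angstrom (>= 0).
#' @param n_frames Number of frames in one loop (>= 1).
#' @return List of \code{n_frames} flat coordinate vectors.
#' @export
vibration_frames <- function(mol, vib, mode_index, amplitude = 0.5,
                             n_frames = 20L) {
  stopifnot(inherits(vib, "chem_vibrations"))
  mode_index <- as.integer(mode_index)
  if (length(mode_index) != 1L || is.na(mode_index) || mode_index < 1L ||
      mode_index > length(vib$modes)) {
    stop(sprintf("mode index %s out of range [1, %d]",
                 mode_index, length(vib$modes)), call. = FALSE)
  }
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  d <- vib$modes[[mode_index]]
  if (length(d) != length(mol$coords)) {
    stop("mode vector length does not match 3N for this molecule",
         call. = FALSE)
  }
  peak <- max(abs(d))
  if (peak > 0) d <- d / peak
  lapply(seq_len(n_frames) - 1L, function(k) {
    # sinpi is exact at quarter periods, so a 4-frame loop hits 0, +A, 0, -A
    mol$coords + amplitude * sinpi(2 * k / n_frames) * d
  })
}
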