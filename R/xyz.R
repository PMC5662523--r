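# XYZ codec: count line, comment line, then one "symbol x y z" line per atom,
# coordinates in angstrom. XYZ carries no bond information.

#' Read an XYZ file
#'
#' @param text XYZ text (single string or character vector of lines).
#' @return A \code{\link{molecule}} (no bonds; the comment line becomes the
#'   name when non-empty).
#' @export
read_xyz <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) < 2L) stop("XYZ input too short", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0L) {
    stop("XYZ count line is not a non-negative integer", call. = FALSE)
  }
  comment <- lines[2]
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    stop(sprintf("XYZ count line claims %d atoms but %d atom lines found",
                 n, length(body)), call. = FALSE)
  }
  body <- body[seq_len(n)]
  z <- integer(n)
  coords <- numeric(3L * n)
  for (i in seq_along(body)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tok) < 4L) {
      stop(sprintf("XYZ atom line %d has fewer than 4 fields", i), call. = FALSE)
    }
    z[i] <- atomic_number(tok[1])
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) {
      stop(sprintf("XYZ atom line %d has non-numeric coordinates", i),
           call. = FALSE)
    }
    coords[(3L * i - 2L):(3L * i)] <- xyz
  }
  name <- trimws(comment)
  molecule(z, coords, name = if (nzchar(name)) name else NULL)
}

#' Write an XYZ file
#'
#' Fixed-width, 6-decimal coordinates; the molecule name (if any) becomes the
#' comment line.
#'
#' @param mol A \code{\link{molecule}}.
#' @return XYZ text ending in a newline.
#' @export
write_xyz <- function(mol) {
  validate_molecule(mol)
  n <- atom_count(mol)
  lines <- c(as.character(n),
             if (is.null(mol$name)) "" else mol$name)
  for (i in seq_len(n)) {
    p <- atom_position(mol, i - 1L)
    lines <- c(lines, sprintf("%-3s %12.6f %12.6f %12.6f",
                              element_symbol(mol$atomic_numbers[i]),
                              p[1], p[2], p[3]))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
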