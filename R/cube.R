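# Gaussian-cube text writer for volumetric data (molecular orbitals, density
# grids). Cube files are conventionally in atomic units: the angstrom-stored
# origin/spacing/coordinates are converted to bohr on output. Values are laid
# out with z varying fastest, six per line.

#' Write volumetric data as Gaussian cube text
#'
#' @param mol A \code{\link{molecule}} whose geometry heads the file.
#' @param vol A \code{\link{volumetric_data}}.
#' @return Cube-format text.
#' @export
write_cube <- function(mol, vol) {
  stopifnot(inherits(vol, "chem_volume"))
  validate_molecule(mol)
  to_bohr <- 1 / .bohr_to_angstrom
  n <- atom_count(mol)
  lines <- c(
    if (nzchar(vol$label)) vol$label else "volumetric data",
    "generated by chemtrove",
    sprintf("%5d %11.6f %11.6f %11.6f", n,
            vol$origin[1] * to_bohr, vol$origin[2] * to_bohr,
            vol$origin[3] * to_bohr),
    sprintf("%5d %11.6f %11.6f %11.6f", vol$dims[1], vol$spacing[1] * to_bohr, 0, 0),
    sprintf("%5d %11.6f %11.6f %11.6f", vol$dims[2], 0, vol$spacing[2] * to_bohr, 0),
    sprintf("%5d %11.6f %11.6f %11.6f", vol$dims[3], 0, 0, vol$spacing[3] * to_bohr))
  for (i in seq_len(n)) {
    p <- atom_position(mol, i - 1L) * to_bohr
    z <- mol$atomic_numbers[i]
    lines <- c(lines, sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                              z, as.numeric(z), p[1], p[2], p[3]))
  }
  vals <- vol$values
  chunks <- split(vals, ceiling(seq_along(vals) / 6))
  lines <- c(lines, vapply(chunks, function(v) {
    paste(sprintf("%13.5E", v), collapse = " ")
  }, character(1)))
  paste0(paste(lines, collapse = "\n"), "\n")
}
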