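# NWChem-style log ingestion: a table-driven parser that turns plain-text
# quantum-chemistry output into a ChemLog document, plus the synthetic log
# generator that makes the parser testable without external data. The
# generator emits the structural elements the parser recognizes — geometry
# tables, basis echo, per-module total-energy lines, a frequency table — in
# the layout NWChem uses, with seed-driven whitespace jitter so the parser
# cannot rely on column positions.

# Energy labels recognized, mapped to the theory tag. The table is the
# extension point for other codes' labels.
.energy_labels <- c("Total SCF energy" = "scf",
                    "Total DFT energy" = "dft")

#' Specification of a synthetic NWChem-style log
#'
#' Describes the molecule, geometry units and task sequence a generated log
#' should contain. Energies are given in hartree, frequencies in cm^-1,
#' intensities in km/mol.
#'
#' @param molecule A \code{\link{molecule}}.
#' @param tasks List of task descriptors, each a list with \code{type}
#'   ("scf", "dft" or "freq"), \code{basis} (name string), \code{energy}
#'   (hartree), and for "freq" tasks \code{theory} ("scf" or "dft", default
#'   "scf"), \code{frequencies} and optional \code{intensities}.
#' @param geometry_units "angstrom" or "bohr" — the units the log prints the
#'   geometry in.
#' @param seed Integer; drives whitespace jitter in the formatted output.
#'   Token content is seed-independent.
#' @return An object of class \code{log_fixture_spec}.
#' @export
log_fixture_spec <- function(molecule, tasks, geometry_units = "angstrom",
                             seed = 0L) {
  validate_molecule(molecule)
  geometry_units <- match.arg(geometry_units, c("angstrom", "bohr"))
  if (!is.list(tasks) || length(tasks) == 0L) {
    stop("tasks must be a non-empty list", call. = FALSE)
  }
  for (i in seq_along(tasks)) {
    t <- tasks[[i]]
    if (!(t$type %in% c("scf", "dft", "freq"))) {
      stop(sprintf("task %d: unknown type \"%s\"", i, t$type), call. = FALSE)
    }
    if (is.null(t$basis) || is.null(t$energy)) {
      stop(sprintf("task %d: basis and energy are required", i), call. = FALSE)
    }
    if (t$type == "freq") {
      if (is.null(t$frequencies) || length(t$frequencies) == 0L) {
        stop(sprintf("task %d: freq task requires frequencies", i),
             call. = FALSE)
      }
      if (!is.null(t$intensities) &&
          length(t$intensities) != length(t$frequencies)) {
        stop(sprintf("task %d: intensities length must match frequencies", i),
             call. = FALSE)
      }
    }
  }
  structure(list(molecule = molecule, tasks = tasks,
                 geometry_units = geometry_units, seed = as.integer(seed)),
            class = "log_fixture_spec")
}

# Re-space a line: same tokens, random gap widths. Leading indent preserved
# in spirit (one leading gap drawn too).
jitter_line <- function(line) {
  if (!nzchar(trimws(line))) return(line)
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  gaps <- strrep(" ", sample(1:4, length(tok) + 1L, replace = TRUE))
  paste0(gaps[1], paste0(tok, gaps[-1], collapse = ""))
}

geometry_block_lines <- function(mol, units) {
  hdr <- if (units == "angstrom") {
    " Output coordinates in angstroms (scale by  1.889725989 to convert to a.u.)"
  } else {
    " Output coordinates in a.u. (scale by  1.000000000 to convert to a.u.)"
  }
  lines <- c("", hdr, "",
             "  No.       Tag          Charge          X              Y              Z",
             " ---- ---------------- ---------- -------------- -------------- --------------")
  scale <- if (units == "bohr") 1 / .bohr_to_angstrom else 1
  for (i in seq_len(atom_count(mol))) {
    p <- atom_position(mol, i - 1L) * scale
    lines <- c(lines, sprintf("%5d %-16s %10.4f %14.8f %14.8f %14.8f",
                              i, element_symbol(mol$atomic_numbers[i]),
                              mol$atomic_numbers[i], p[1], p[2], p[3]))
  }
  c(lines, "")
}

#' Generate a synthetic NWChem-style log
#'
#' Emits a banner, an echoed geometry table before every task, and one module
#' section per task with its basis echo, labeled total-energy line and (for
#' frequency tasks) a projected-frequency table. Whitespace between tokens is
#' jittered by the spec's seed; the token stream itself is seed-independent.
#'
#' @param spec A \code{\link{log_fixture_spec}}.
#' @return The log text.
#' @export
generate_nwchem_log <- function(spec) {
  stopifnot(inherits(spec, "log_fixture_spec"))
  mol <- spec$molecule
  lines <- c(
    "          Northwest Computational Chemistry Package (NWChem) 7.0",
    "          -----------------------------------------------------",
    "",
    sprintf("          Job title: %s",
            if (is.null(mol$name)) "synthetic" else mol$name),
    "")
  for (t in spec$tasks) {
    theory <- if (t$type == "freq") {
      if (is.null(t$theory)) "scf" else t$theory
    } else t$type
    lines <- c(lines, geometry_block_lines(mol, spec$geometry_units))
    lines <- c(lines,
               sprintf(" ao basis = \"%s\"", t$basis),
               "",
               sprintf("                         NWChem %s Module",
                       toupper(theory)),
               "                         -----------------",
               "",
               sprintf("         Total %s energy = %18.12f",
                       toupper(theory), t$energy),
               "")
    if (t$type == "freq") {
      ints <- if (is.null(t$intensities)) rep(0, length(t$frequencies)) else
        t$intensities
      lines <- c(lines,
        "              NWChem Nuclear Hessian and Frequency Analysis",
        " ----------------------------------------------------------------------------",
        " Normal Eigenvalue ||           Projected Infra Red Intensities",
        "  Mode   [cm**-1]  || [atomic units] [(debye/angs)**2] [(KM/mol)] [arbitrary]",
        " ------ ----------  || -------------- ----------------- ---------- -----------")
      for (m in seq_along(t$frequencies)) {
        lines <- c(lines, sprintf(
          "%7d %12.3f || %14.6f %17.3f %10.3f %11.3f",
          m, t$frequencies[m], 0, 0, ints[m], 0))
      }
      lines <- c(lines, "")
    }
  }
  lines <- c(lines, " Total times  cpu:        0.1s     wall:        0.1s")
  jittered <- with_seed(spec$seed, vapply(lines, jitter_line, character(1),
                                          USE.NAMES = FALSE))
  paste0(paste(jittered, collapse = "\n"), "\n")
}

parse_number <- function(token, line_no, what) {
  x <- suppressWarnings(as.numeric(gsub("[dD]", "e", token)))
  if (is.na(x)) {
    stop(sprintf("line %d: cannot parse %s from \"%s\"", line_no, what, token),
         call. = FALSE)
  }
  x
}

#' Parse an NWChem-style log into a ChemLog document
#'
#' One calculation is emitted per recognized total-energy line, in document
#' order; the geometry table most recently echoed before the energy line is
#' that calculation's molecule. A geometry identical to one already emitted
#' is written as an id-tag reference instead of being repeated, and the same
#' applies to basis sets. Geometry coordinates keep the units the log
#' declares (no silent conversion); energies are stored in hartree and
#' frequencies in cm^-1.
#'
#' @param text Log text (single string or character vector of lines).
#' @return A \code{\link{chemlog_document}}.
#' @export
parse_nwchem_log <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text

  geometries <- list()   # each: list(tree=..., key=...)
  bases <- list()        # basis name -> inline tree already emitted? id
  calcs <- list()
  cur_geom <- NULL       # index into geometries
  cur_basis <- NULL      # basis name
  i <- 1L
  n_lines <- length(lines)

  read_geometry <- function(start, units) {
    # skip header rows until the dashed separator, then read data rows
    j <- start
    while (j <= n_lines && !grepl("^\\s*-{2,}", lines[j])) j <- j + 1L
    j <- j + 1L
    z <- integer(); xyz <- numeric()
    while (j <= n_lines) {
      tok <- strsplit(trimws(lines[j]), "\\s+")[[1]]
      if (length(tok) < 6L || is.na(suppressWarnings(as.integer(tok[1])))) break
      z <- c(z, atomic_number(tok[2]))
      xyz <- c(xyz, vapply(tok[4:6], parse_number, numeric(1),
                           line_no = j, what = "coordinate"))
      j <- j + 1L
    }
    if (length(z) == 0L) {
      stop(sprintf("line %d: geometry table has no atom rows", start),
           call. = FALSE)
    }
    list(z = z, xyz = unname(xyz), units = units, end = j)
  }

  while (i <= n_lines) {
    line <- lines[i]

    if (grepl("Output\\s+coordinates\\s+in", line)) {
      # the angstrom header also mentions a.u. ("convert to a.u."), so test
      # for the angstrom wording first
      units <- if (grepl("angstrom", line)) "angstrom" else "bohr"
      g <- read_geometry(i + 1L, units)
      key <- paste(g$units, paste(g$z, collapse = ","),
                   paste(format(g$xyz, digits = 15), collapse = ","), sep = "|")
      found <- Filter(function(k) geometries[[k]]$key == key,
                      seq_along(geometries))
      if (length(found)) {
        cur_geom <- found[[1]]
      } else {
        mol_id <- sprintf("Molecule.%d", length(geometries) + 1L)
        atoms <- lapply(seq_along(g$z), function(a) {
          list(id = sprintf("Atom.%d.Mol.%d", a, length(geometries) + 1L),
               element = element_symbol(g$z[a]),
               coordinates = list(
                 value = I(g$xyz[(3L * a - 2L):(3L * a)]),
                 units = g$units))
        })
        geometries[[length(geometries) + 1L]] <-
          list(key = key, tree = list(id = mol_id, atoms = atoms),
               emitted = FALSE)
        cur_geom <- length(geometries)
      }
      i <- g$end
      next
    }

    m <- regmatches(line, regexec("ao\\s+basis\\s*=\\s*\"([^\"]+)\"", line))[[1]]
    if (length(m) == 2L) {
      cur_basis <- m[2]
      i <- i + 1L
      next
    }

    matched_label <- NULL
    for (label in names(.energy_labels)) {
      # whitespace between label words is not significant
      pat <- gsub(" ", "\\\\s+", label)
      if (grepl(pat, line)) { matched_label <- label; break }
    }
    if (!is.null(matched_label)) {
      if (is.null(cur_geom)) {
        stop(sprintf("line %d: energy line before any geometry table", i),
             call. = FALSE)
      }
      pat <- gsub(" ", "\\\\s+", matched_label)
      tok <- strsplit(sub(paste0(".*", pat, "\\s*=\\s*"), "", line),
                      "\\s+")[[1]]
      energy <- parse_number(tok[1], i, "energy")
      k <- length(calcs) + 1L
      basis_name <- if (is.null(cur_basis)) "unknown" else cur_basis
      basis_tree <- if (!is.null(bases[[basis_name]])) {
        bases[[basis_name]] # id-tag reference string
      } else {
        id <- sprintf("BasisSet.%d", length(bases) + 1L)
        bases[[basis_name]] <- id
        list(id = id, name = basis_name)
      }
      geom <- geometries[[cur_geom]]
      mol_field <- if (geom$emitted) geom$tree$id else geom$tree
      geometries[[cur_geom]]$emitted <- TRUE
      calcs[[k]] <- list(
        id = sprintf("Calculation.%d", k),
        calculationSetup = list(
          id = sprintf("Setup.%d", k),
          theory = .energy_labels[[matched_label]],
          task = "energy",
          basisSet = basis_tree),
        molecule = mol_field,
        calculationResults = list(
          totalEnergy = list(value = energy, units = "hartree")))
      i <- i + 1L
      next
    }

    if (grepl("Normal\\s+Eigenvalue", line)) {
      if (length(calcs) == 0L) {
        stop(sprintf("line %d: frequency table before any energy line", i),
             call. = FALSE)
      }
      j <- i + 1L
      while (j <= n_lines && !grepl("^\\s*-{2,}", lines[j])) j <- j + 1L
      j <- j + 1L
      freqs <- numeric(); ints <- numeric()
      while (j <= n_lines) {
        tok <- strsplit(trimws(lines[j]), "\\s+")[[1]]
        if (length(tok) < 7L || is.na(suppressWarnings(as.integer(tok[1])))) break
        freqs <- c(freqs, parse_number(tok[2], j, "frequency"))
        ints <- c(ints, parse_number(tok[6], j, "intensity"))
        j <- j + 1L
      }
      k <- length(calcs)
      calcs[[k]]$calculationSetup$task <- "frequency"
      calcs[[k]]$calculationResults$vibrationalFrequencies <-
        list(value = I(freqs), units = "cm-1")
      calcs[[k]]$calculationResults$vibrationalIntensities <-
        list(value = I(ints), units = "km/mol")
      i <- j
      next
    }

    i <- i + 1L
  }

  if (length(geometries) == 0L) {
    stop("no geometry table found in log", call. = FALSE)
  }
  if (length(calcs) == 0L) {
    stop("no recognized energy line found in log", call. = FALSE)
  }
  chemlog_document(list(
    simulation = list(code = "NWChem", version = "synthetic-log"),
    calculations = calcs))
}

#' Random log-fixture specification
#'
#' Seeded generator of a molecule plus a 1-3 task sequence with energies
#' rounded to 6 decimals (the precision a fixed-point log line carries
#' exactly) and, for frequency tasks, a 3N-6-mode frequency table.
#'
#' @param seed Integer seed.
#' @return A \code{\link{log_fixture_spec}}.
#' @export
random_log_spec <- function(seed) {
  with_seed(seed, {
    mol <- random_molecule(seed + 1000L, n_atoms = c(3L, 8L))
    n_tasks <- sample(1:3, 1L)
    bases <- c("sto-3g", "6-31g", "cc-pvdz")
    tasks <- lapply(seq_len(n_tasks), function(k) {
      type <- sample(c("scf", "dft", "freq"), 1L)
      t <- list(type = type,
                basis = sample(bases, 1L),
                energy = round(runif(1, -500, -1), 6))
      if (type == "freq") {
        n_modes <- max(3L * atom_count(mol) - 6L, 1L)
        t$theory <- sample(c("scf", "dft"), 1L)
        t$frequencies <- sort(round(runif(n_modes, 50, 4000), 2))
        t$intensities <- round(runif(n_modes, 0, 300), 2)
      }
      t
    })
    units <- sample(c("angstrom", "bohr"), 1L)
    log_fixture_spec(mol, tasks, geometry_units = units, seed = seed)
  })
}
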