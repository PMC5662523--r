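---
title: "Chemical data formats, log ingestion and the molecular data service"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical data formats, log ingestion and the molecular data service}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemtrove)
```

## The problem

Quantum-chemistry codes still communicate mostly through free-form text log
files: a human-readable transcript of geometries, basis sets, energies and
frequency tables that every downstream tool re-parses with its own ad-hoc
scraper. chemtrove implements a structured alternative built on two JSON
dialects with complementary philosophies, the machinery to move data between
them and the classic interchange formats (XYZ, CML), a parser that ingests
NWChem-style logs into the structured form, and a small data service that
stores, deduplicates, searches and serves molecules and calculations.

## The two JSON dialects

**Chemical JSON** is array-oriented and aimed at visualization and
single-document storage. Atoms are three parallel arrays — element numbers,
a flat 3N coordinate array, and bond index/order arrays — so the 3D position
of atom *N* starts at offset 3N of the coordinate array. This is the natural
transport layer for a renderer: one allocation per property, no per-atom
object overhead, and sections (bonds, vibrations, volumes) can stream in
incrementally. The exact key spelling used by the package
(`chemicalJson`, `atoms.elements.number`, `atoms.coords.3d`,
`bonds.connections.index`, `bonds.order`, `vibrations.frequencies` /
`intensities` / `eigenVectors`, `volume.*`) is part of this package's
documented dialect; unknown top-level keys round-trip untouched, because the
format is expected to keep evolving.

**ChemLog JSON** is object-oriented and replaces the log file itself. Every
atom is a self-contained object carrying its element and unit-annotated
coordinates; a document holds an ordered `calculations` array, one entry per
task of a multi-step run. Two features distinguish it:

* **Explicit units.** Every physical value is an object `{value, units}`
  with units drawn from a closed vocabulary (`hartree`, `eV`, `cm-1`,
  `angstrom`, `bohr`, `amu`, `debye`, `dimensionless`). Coordinates keep the
  units the producing code printed; conversion to the package's internal
  angstrom convention happens only at extraction, using the CODATA factor
  1 bohr = 0.529177210903 Å.
* **Id-tag references.** Multi-step runs reuse geometries and basis sets.
  The first mention of a shared object is written inline with an `"id"` tag
  (`"Molecule.2"`, `"Atom.1.Mol.2"`, `"BasisSet.1"`); later uses are plain
  strings naming that tag — a pointer to the first mention. References are
  only recognized in the linking positions `molecule`, `basisSet`,
  `calculationSetup` and `atom`; a string anywhere else is a literal, which
  keeps molecule names from being misread as links. The reader enforces
  strict document-order semantics: duplicate tags, forward references and
  dangling references are all rejected with the offending tag named.
  JSON-pointer/RFC-style referencing is deliberately not implemented; the
  id-tag convention is the format.

Mapping between the dialects is a flattening: per-atom objects become the
parallel arrays, vibrational results become the `vibrations` section, and
provenance (code, theory) is carried into a `metadata` block.

## Core model and derived fields

Both codecs meet in a small S3 model: `molecule` (atomic numbers, flat 3N
angstrom coordinates, 0-based bond table, identifier metadata),
`vibrational_data`, `volumetric_data`, `calculation` and `quantity`.
Derived fields used by search — molecular mass, Hill formula, atom and
heavy-atom counts — come from a static table of conventional IUPAC atomic
weights (2021 abridged values, integer mass numbers for elements with no
standard weight) embedded in the package, so masses are reproducible with no
chemistry toolkit at runtime. InChI and InChIKey are accepted and stored as
metadata but never computed; the package takes no position on structure
normalization.

When no InChIKey is supplied, deduplication falls back to `structure_key()`:
a digest of the molecular graph obtained by iterative neighbourhood colour
refinement (Weisfeiler–Lehman style) over element and bond-order labels,
hashed with a dual polynomial rolling hash. The key is invariant under any
reordering of the input atoms — the property the store actually needs — but
colour refinement is not a perfect canonical code: certain regular
non-isomorphic graphs can in principle collide. For the small covalent
molecules this store targets that risk is negligible, and a supplied
InChIKey always takes precedence.

## Log ingestion

`parse_nwchem_log()` is table-driven: a label table maps recognized
total-energy lines (`Total SCF energy`, `Total DFT energy`) to theory tags,
and is the intended extension point for other codes' labels. Parsing is
token-based, never column-based: the companion generator jitters all
inter-token whitespace under a seed precisely so that the tests would catch
any reliance on fixed columns. Association rules, chosen here because log
files do not declare them: the geometry table most recently echoed before an
energy line is that calculation's molecule; a frequency table attaches to
the most recent calculation. A geometry or basis set identical to one
already emitted becomes an id-tag reference rather than a repeat. One
wording subtlety: the angstrom geometry header also contains the string
"a.u." (in "scale by ... to convert to a.u."), so unit detection tests for
the angstrom wording first.

The synthetic generator defines the study conditions for the
parameter-recovery suite: molecules of 3–8 atoms from a main-group element
pool, 1–3 task sequences over the scf/dft/freq types, energies drawn in
[-500, -1] hartree and rounded to 6 decimals, frequencies in [50, 4000]
cm⁻¹ rounded to 2. The 6-decimal rounding is what makes "exact" energy
recovery a meaningful claim: a fixed-point energy line printed with 12
decimals carries a 6-decimal value losslessly through print-and-parse. The
generator emulates the structural skeleton of a real log (banner, geometry
tables, module sections, frequency table), not its full variety — basis
tables, MO vectors and optimizer traces are out of scope — so a passing
recovery suite demonstrates the parser's association and conversion logic,
not coverage of every production NWChem output.

## Conversion and animation

The dispatcher `chem_convert()` composes reader ∘ writer through the core
molecule. XYZ carries no bonds, so any conversion into XYZ from a
bond-carrying format attaches a lossy-conversion warning to the result
rather than failing or silently dropping data; ChemLog is a read-only source
(its first calculation is selected). Coordinates survive every supported
double conversion to ≤ 1e-6 Å: Chemical JSON serializes numbers at full
precision, XYZ at fixed 6 decimals, CML at 15 significant digits.

Vibrational animation uses the standard sinusoidal loop: the mode's
displacement vector is normalized to unit max-norm, and frame *k* of *n* is
`r0 + A·sin(2πk/n)·d`. The implementation evaluates the phase with
`sinpi()`, which is exact at quarter periods, so a 4-frame loop hits the
factors (0, +A, 0, −A) exactly and frame 0 is always the equilibrium
geometry.

## The query language

Search uses a small boolean/comparison language: numeric fields `mass`,
`atomCount`, `heavyAtomCount` with `< <= > >= = !=`, string fields `name`,
`inchi`, `inchikey`, `formula` with `=` (case-insensitive exact) and `~`
(case-insensitive substring). `and` binds tighter than `or`; parentheses
group; a bare word is shorthand for `name ~ word`, matching search-box
behaviour. There is no `not` operator. Mass comparisons are exact on floats
by design — predictable semantics, with ranges (`mass>17 and mass<19`) as
the documented idiom. A comparison against a missing optional field is
false. The evaluator is verified against an independent brute-force oracle
over hundreds of random molecule/query pairs, and the canonical printer
`format_query()` is a parse fixpoint.

## The data service

The service layer is a pure request router: `api_handle(store, method,
path, query, body)` returns status, content type and body text, which makes
the entire endpoint contract testable in-process. `api_serve()` is a thin
adapter that runs the same router behind httpuv when that package is
available. Design choices: no authentication (all endpoints public);
24-hex-character ids generated deterministically from a store seed and an
insertion counter, so test runs are reproducible; persistence as a
newline-delimited JSON journal replayed at startup; the `/api/v1` prefix
fixed; misses on collection queries return an empty JSON array with status
200, while unknown ids return 404. Molecule uniqueness is structure-level:
repeated uploads of the same document create new calculation records but
exactly one molecule record. Note that ChemLog molecules carry no bond
information, so a molecule uploaded via a log and the same molecule added
directly with bonds are distinct structures under the fallback key — by
design, since the graphs genuinely differ.

## Test scale and determinism

All randomized suites run under fixed seeds through a scoped-RNG helper that
restores the caller's stream. Problem sizes, chosen as comfortable
desk-scale checks: 100 random molecules per codec round trip, 50 random log
specs for parameter recovery, 200 molecules × 100 random ASTs for
query/oracle equivalence, and a handful of upload sequences for the service
invariants. `scripts/acceptance.R` recomputes the same quantities from
scratch at those sizes under a caller-supplied seed.

## Known limitations

* Bond perception, stereochemistry and charge/spin bookkeeping are out of
  scope; bonds are stored, never inferred from geometry.
* The CML codec covers the `atomArray`/`bondArray` attribute subset only.
* The log parser targets the synthetic generator's dialect of NWChem-style
  output; production logs with basis tables, MO vectors or optimization
  traces are not covered.
* `structure_key()` is a graph invariant, not a canonical code (see above).
* The query engine is a linear scan; no indexing, ranking or substructure
  search.
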