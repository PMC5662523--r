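# chemtrove

Structured chemical data for R: two JSON dialects used in computational
chemistry, the converters between them and the classic interchange formats,
a parser that ingests NWChem-style text logs into structured documents, a
molecule search language, and a small REST-style data service.

Quantum-chemistry results mostly live in free-form log files that every
downstream tool re-parses by hand. chemtrove implements a structured
alternative built around two complementary JSON formats:

* **Chemical JSON** — array-oriented, built for visualization and
  single-document storage. Element numbers, coordinates and bonds are
  parallel flat arrays; the 3D position of atom *N* starts at offset 3N of
  the coordinate array. Optional sections carry vibrational modes
  (frequencies in cm⁻¹, intensities in km/mol, per-mode 3N displacement
  vectors) and volumetric grids (cube-style origin/spacing/dims/values).
* **ChemLog JSON** — object-oriented, a replacement for the log file
  itself. An ordered `calculations` array holds one entry per task of a
  multi-step run; every physical value is unit-annotated
  (`{"value": ..., "units": "hartree"}`); shared objects (geometries, basis
  sets, atoms) are written once with an `"id"` tag (`"Molecule.2"`,
  `"Atom.1.Mol.2"`) and referenced afterwards by that tag string — a
  pointer to the first mention, validated in strict document order.

Around the formats the package provides XYZ and CML (subset) codecs, a
conversion dispatcher that flags lossy paths (XYZ carries no bonds), a
table-driven NWChem-style log parser with a seeded synthetic log generator,
sinusoidal vibrational-animation frames, a boolean/comparison query language
(`mass>17 and mass<19`, `formula=C6H6 or water`), and an in-memory,
journal-backed molecule/calculation store exposed through REST-shaped
endpoints (`/api/v1/molecules`, `/api/v1/calculations`,
`/api/v1/molecules/conversions/{format}`) as a pure, in-process-testable
request router.

## Worked example

Generate a two-task (SCF energy + frequency) synthetic log for water, ingest
it, upload it to a store, and query the service:

```r
library(chemtrove)

w <- canonical_water()
molecular_mass(w)   # 18.015 (amu)
hill_formula(w)     # "H2O"

spec <- log_fixture_spec(w, tasks = list(
  list(type = "scf", basis = "sto-3g", energy = -74.965901),
  list(type = "freq", theory = "scf", basis = "sto-3g", energy = -74.965901,
       frequencies = c(1595.0, 3657.05, 3755.93), intensities = c(65, 4, 50))))
doc <- parse_nwchem_log(generate_nwchem_log(spec))
doc
#> <ChemLog document: 2 calculation(s), 9 id-tag(s)>
doc$calculations[[2]]$molecule   # shared geometry became a reference
#> [1] "Molecule.1"

store <- chem_store(seed = 1L)
up <- store_upload_calculations(store, doc)
up$moleculeId
#> [1] "3b77ccca22fdc5f835cd617a"
up$calculationIds
#> [1] "3b77cccb22fdc5f935cda483" "3b77cccc22fdc5fa35cde78c"

api_handle(store, "GET", "/api/v1/molecules/search",
           query = list(q = "mass>17 and mass<19"))$body
#> [{"id":"3b77ccca22fdc5f835cd617a","inchikey":null,"name":null}]

cat(api_handle(store, "GET",
    sprintf("/api/v1/molecules/%s/xyz", up$moleculeId))$body)
#> 3
#>
#> O       0.000000     0.000000     0.000000
#> H       0.757000     0.586000     0.000000
#> H      -0.757000     0.586000     0.000000
```

The two calculations share one geometry, so the ChemLog document stores the
molecule once and the second calculation refers to it by its id-tag; the
upload deduplicates on the structure level, so re-uploading the same
document reuses the molecule record and only adds calculation records.

A command-line front end over the same functions lives at
`inst/cli/chemtrove` (validate / convert / ingest / search / make-log /
make-molecule / serve).

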