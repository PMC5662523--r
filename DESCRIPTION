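Package: chemtrove
Title: Chemical JSON and ChemLog Data Formats, Converters, and a Molecular Data Service
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Readers, writers and validators for two JSON dialects used in
    computational chemistry: the array-oriented Chemical JSON format aimed at
    visualization and document storage, and the object-oriented ChemLog JSON
    format that replaces a quantum-chemistry log file with unit-annotated,
    id-referenced structured output. Includes XYZ and CML (subset) codecs, a
    format-conversion dispatcher, a parser that ingests NWChem-style plain-text
    log files into ChemLog documents, a boolean/numeric query language over
    molecule collections, vibrational-mode animation frames, and an in-memory
    molecular data service exposing molecules, calculations and conversion
    endpoints through a REST-style request router.
License: BSD_3_clause + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    httpuv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
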