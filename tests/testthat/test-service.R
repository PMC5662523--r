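as_json <- function(res) jsonlite::fromJSON(res$body, simplifyVector = FALSE)

seeded_store <- function() {
  store <- chem_store(seed = 42L)
  w <- canonical_water()
  w$inchikey <- "XLYOFNOQVPJJNP-UHFFFAOYSA-N"
  store_add_molecule(store, w)
  store_add_molecule(store, molecule(c(6L, 1L, 1L, 1L, 1L), numeric(15),
                                     name = "methane"))
  store
}

test_that("molecule GET query requires exactly one parameter", {
  store <- seeded_store()
  res <- api_handle(store, "GET", "/api/v1/molecules",
                    query = list(name = "water"))
  expect_equal(res$status, 200L)
  hits <- as_json(res)
  expect_length(hits, 1L)
  expect_setequal(names(hits[[1]]), c("id", "inchikey", "name"))
  expect_identical(hits[[1]]$name, "water")

  miss <- api_handle(store, "GET", "/api/v1/molecules",
                     query = list(name = "unobtainium"))
  expect_equal(miss$status, 200L)
  expect_identical(miss$body, "[]") # empty JSON array on no match

  expect_equal(api_handle(store, "GET", "/api/v1/molecules")$status, 400L)
  expect_equal(api_handle(store, "GET", "/api/v1/molecules",
                          query = list(name = "x", inchi = "y"))$status, 400L)
})

test_that("formatted molecule retrieval returns re-parsable bodies", {
  store <- seeded_store()
  id <- store$mol_order[1]
  xyz <- api_handle(store, "GET", sprintf("/api/v1/molecules/%s/xyz", id))
  expect_equal(xyz$status, 200L)
  expect_identical(xyz$content_type, "text/plain")
  expect_match(xyz$body, "^3")
  expect_coords_equal(read_xyz(xyz$body), canonical_water())

  cml <- api_handle(store, "GET", sprintf("/api/v1/molecules/%s/cml", id))
  expect_identical(cml$content_type, "chemical/x-cml")
  expect_coords_equal(read_cml(cml$body), canonical_water())

  cjson <- api_handle(store, "GET", sprintf("/api/v1/molecules/%s/cjson", id))
  expect_identical(cjson$content_type, "application/json")
  expect_equal(atom_count(parse_cjson(cjson$body)$molecule), 3L)

  expect_equal(api_handle(store, "GET",
                          "/api/v1/molecules/ffffffffffffffffffffffff/xyz")$status,
               404L)
  expect_equal(api_handle(store, "GET",
                          sprintf("/api/v1/molecules/%s/sdf", id))$status, 400L)
})

test_that("inchikey endpoint returns the full record or 404", {
  store <- seeded_store()
  hit <- api_handle(store, "GET",
                    "/api/v1/molecules/inchikey/XLYOFNOQVPJJNP-UHFFFAOYSA-N")
  expect_equal(hit$status, 200L)
  rec <- as_json(hit)
  expect_identical(rec$inchikey, "XLYOFNOQVPJJNP-UHFFFAOYSA-N")
  expect_identical(rec$formula, "H2O")
  expect_equal(rec$mass, 18.015, tolerance = 1e-9)
  expect_equal(api_handle(store, "GET",
                          "/api/v1/molecules/inchikey/NOPE")$status, 404L)
  # keys are matched case-sensitively (canonical uppercase)
  expect_equal(api_handle(store, "GET",
    "/api/v1/molecules/inchikey/xlyofnoqvpjjnp-uhfffaoysa-n")$status, 404L)
})

test_that("search endpoint delegates to the query engine", {
  store <- seeded_store()
  res <- api_handle(store, "GET", "/api/v1/molecules/search",
                    query = list(q = "mass>17 and mass<19"))
  hits <- as_json(res)
  expect_length(hits, 1L)
  expect_identical(hits[[1]]$name, "water")
  engine <- search_molecules(store_molecules(store), "mass>17 and mass<19")
  expect_identical(hits[[1]]$id, engine[[1]]$id)
  expect_identical(api_handle(store, "GET", "/api/v1/molecules/search",
                              query = list(q = "mass>9999"))$body, "[]")
  expect_equal(api_handle(store, "GET", "/api/v1/molecules/search",
                          query = list(q = "mass>"))$status, 400L)
  expect_equal(api_handle(store, "GET", "/api/v1/molecules/search")$status,
               400L)
})

test_that("conversion endpoint mirrors the dispatcher contract", {
  store <- chem_store()
  body <- jsonlite::toJSON(list(input = write_xyz(canonical_water()),
                                inputFormat = "xyz"), auto_unbox = TRUE)
  res <- api_handle(store, "POST", "/api/v1/molecules/conversions/cjson",
                    body = body)
  expect_equal(res$status, 200L)
  out <- as_json(res)
  expect_equal(atom_count(parse_cjson(out$output)$molecule), 3L)

  bad_pair <- api_handle(store, "POST",
                         "/api/v1/molecules/conversions/chemlog", body = body)
  expect_equal(bad_pair$status, 400L)
  expect_match(as_json(bad_pair)$error, "unsupported")

  mangled <- jsonlite::toJSON(list(input = "2\nbroken\nO 0 0 0\n",
                                   inputFormat = "xyz"), auto_unbox = TRUE)
  broken <- api_handle(store, "POST", "/api/v1/molecules/conversions/cjson",
                       body = mangled)
  expect_equal(broken$status, 422L)
})

test_that("calculation upload deduplicates molecules and keeps integrity", {
  store <- chem_store(seed = 7L)
  doc <- parse_nwchem_log(generate_nwchem_log(log_fixture_spec(
    canonical_water(),
    tasks = list(list(type = "scf", basis = "sto-3g", energy = -76.0),
                 list(type = "freq", theory = "dft", basis = "6-31g",
                      energy = -76.4, frequencies = c(1595, 3650, 3750),
                      intensities = c(65, 4, 50))))))
  text <- write_chemlog(doc)

  up1 <- as_json(api_handle(store, "POST", "/api/v1/calculations", body = text))
  expect_length(up1$calculationIds, 2L)
  expect_length(unique(unlist(up1$moleculeIds)), 1L)

  # re-upload: same molecule id, fresh calculation ids
  up2 <- as_json(api_handle(store, "POST", "/api/v1/calculations", body = text))
  expect_identical(up2$moleculeId, up1$moleculeId)
  expect_length(intersect(unlist(up1$calculationIds),
                          unlist(up2$calculationIds)), 0L)
  expect_length(store$mol_order, 1L)
  expect_length(store$calc_order, 4L)
  expect_true(store_integrity_ok(store))

  dangling <- sub("\"Molecule.1\"", "\"Molecule.9\"",
                  text, fixed = TRUE)
  res <- api_handle(store, "POST", "/api/v1/calculations", body = dangling)
  expect_equal(res$status, 422L)
})

test_that("calculation summaries expose the five provenance fields", {
  store <- chem_store(seed = 7L)
  doc <- parse_nwchem_log(generate_nwchem_log(random_log_spec(12)))
  up <- store_upload_calculations(store, doc)
  res <- api_handle(store, "GET", "/api/v1/calculations",
                    query = list(moleculeId = up$moleculeId))
  summaries <- as_json(res)
  expect_gte(length(summaries), 1L)
  for (s in summaries) {
    expect_true(all(c("_id", "code", "theory", "calculationTypes", "fileId")
                    %in% names(s)))
    expect_identical(s$code, "NWChem")
  }
  none <- api_handle(store, "GET", "/api/v1/calculations",
                     query = list(moleculeId = "ffffffffffffffffffffffff"))
  expect_identical(none$body, "[]")
  expect_equal(api_handle(store, "GET", "/api/v1/calculations")$status, 400L)
})

test_that("calculation resources serve cjson, vibrations and cube data", {
  store <- chem_store(seed = 9L)
  doc <- parse_nwchem_log(generate_nwchem_log(log_fixture_spec(
    canonical_water(),
    tasks = list(list(type = "freq", theory = "scf", basis = "sto-3g",
                      energy = -76.0, frequencies = c(1595, 3650, 3750)),
                 list(type = "scf", basis = "sto-3g", energy = -76.01)))))
  up <- store_upload_calculations(store, doc)
  freq_id <- up$calculationIds[1]
  scf_id <- up$calculationIds[2]

  cj <- api_handle(store, "GET",
                   sprintf("/api/v1/calculations/%s/cjson", freq_id))
  expect_equal(cj$status, 200L)
  parsed <- parse_cjson(cj$body)
  expect_equal(atom_count(parsed$molecule), 3L)
  expect_length(parsed$vibrations$frequencies, 3L)

  vib <- api_handle(store, "GET",
                    sprintf("/api/v1/calculations/%s/vibrations", freq_id))
  expect_equal(vib$status, 200L)
  vb <- as_json(vib)
  expect_length(vb$frequencies, 3L)
  expect_length(vb$intensities, 3L)

  # a calculation without vibrational data 404s on the vibrations resource
  expect_equal(api_handle(store, "GET",
    sprintf("/api/v1/calculations/%s/vibrations", scf_id))$status, 404L)

  # attach a volume and fetch it as cube text
  rec <- store_get_calculation(store, scf_id)
  rec$volumes <- list(volumetric_data(c(0, 0, 0), c(0.5, 0.5, 0.5),
                                      c(2, 2, 2), 1:8, "HOMO"))
  store$calcs[[scf_id]] <- rec
  cube <- api_handle(store, "GET",
                     sprintf("/api/v1/calculations/%s/cube/1", scf_id))
  expect_equal(cube$status, 200L)
  expect_match(cube$body, "HOMO")
  expect_equal(api_handle(store, "GET",
    sprintf("/api/v1/calculations/%s/cube/2", scf_id))$status, 404L)
  expect_equal(api_handle(store, "GET",
    "/api/v1/calculations/ffffffffffffffffffffffff/cjson")$status, 404L)
})

test_that("journal persistence replays the store from disk", {
  path <- tempfile(fileext = ".ndjson")
  on.exit(unlink(path))
  store <- chem_store(path = path, seed = 5L)
  store_add_molecule(store, canonical_water())
  doc <- parse_nwchem_log(generate_nwchem_log(random_log_spec(3)))
  store_upload_calculations(store, doc)

  reopened <- chem_store(path = path, seed = 5L)
  expect_identical(reopened$mol_order, store$mol_order)
  expect_identical(reopened$calc_order, store$calc_order)
  expect_true(store_integrity_ok(reopened))
})

test_that("route listing and unknown paths behave", {
  store <- chem_store()
  idx <- api_handle(store, "GET", "/api/v1")
  expect_equal(idx$status, 200L)
  expect_match(idx$body, "molecules/search")
  expect_equal(api_handle(store, "GET", "/api/v2/molecules")$status, 404L)
  expect_equal(api_handle(store, "GET", "/api/v1/nothing")$status, 404L)
})
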