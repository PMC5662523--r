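test_that("xyz writer emits count, comment and fixed-width atom lines", {
  txt <- write_xyz(canonical_water())
  lines <- strsplit(txt, "\n")[[1]]
  expect_identical(lines[1], "3")
  expect_identical(lines[2], "water")
  expect_match(lines[3], "^O\\s+0\\.000000\\s+0\\.000000\\s+0\\.000000")
  expect_equal(length(lines), 5L)
})

test_that("xyz read/write is the identity on elements and coordinates", {
  for (seed in 1:100) {
    mol <- random_molecule(seed)
    out <- read_xyz(write_xyz(mol))
    expect_identical(out$atomic_numbers, mol$atomic_numbers)
    expect_lt(max(abs(out$coords - mol$coords), 0), 1e-6)
  }
})

test_that("xyz parser rejects malformed input", {
  expect_error(read_xyz("4\ncomment\nO 0 0 0\nH 1 0 0\nH 0 1 0\n"),
               "claims 4 atoms but 3")
  expect_error(read_xyz("1\nx\nXx 0 0 0\n"), "unknown element")
  expect_error(read_xyz("1\nx\nO 0 zero 0\n"), "non-numeric")
  expect_error(read_xyz("abc\nx\n"), "count line")
})

test_that("cml subset round-trips elements, coordinates and bonds", {
  w <- canonical_water()
  txt <- write_cml(w)
  expect_match(txt, "atomArray")
  expect_equal(length(gregexpr("<atom ", txt)[[1]]), 3L)
  expect_equal(length(gregexpr("<bond ", txt)[[1]]), 2L)
  expect_match(txt, "order=\"1\"")
  out <- read_cml(txt)
  expect_coords_equal(out, w)
  expect_identical(bond_set(out), bond_set(w))
  for (seed in c(2, 9, 31, 77)) {
    mol <- random_molecule(seed)
    out <- read_cml(write_cml(mol))
    expect_coords_equal(out, mol)
    expect_identical(bond_set(out), bond_set(mol))
  }
})

test_that("cml parser rejects unknown atom references and bad XML", {
  bad <- paste0(
    "<molecule><atomArray>",
    "<atom id=\"a1\" elementType=\"O\" x3=\"0\" y3=\"0\" z3=\"0\"/>",
    "<atom id=\"a2\" elementType=\"H\" x3=\"1\" y3=\"0\" z3=\"0\"/>",
    "<atom id=\"a3\" elementType=\"H\" x3=\"0\" y3=\"1\" z3=\"0\"/>",
    "</atomArray><bondArray><bond atomRefs2=\"a1 a9\" order=\"1\"/>",
    "</bondArray></molecule>")
  expect_error(read_cml(bad), "unknown atom id")
  expect_error(read_cml("<molecule><atomArray>"), ".")
})

test_that("chemlog maps to cjson preserving geometry and vibrations", {
  spec <- log_fixture_spec(
    canonical_water(),
    tasks = list(list(type = "freq", theory = "scf", basis = "sto-3g",
                      energy = -74.965901,
                      frequencies = c(1595.0, 3650.1, 3750.2),
                      intensities = c(65, 4, 50))))
  doc <- parse_nwchem_log(generate_nwchem_log(spec))
  cj <- chemlog_to_cjson(doc, 1L)
  expect_length(cj$vibrations$frequencies, 3L)
  parsed <- parse_cjson(cjson_text(cj))
  ref <- extract_molecule(doc, 1L)
  expect_lt(max(abs(parsed$molecule$coords - ref$coords)), 1e-9)
  expect_identical(cj$metadata$code, "NWChem")
  expect_identical(cj$metadata$theory, "scf")
  # a calculation without vibrations maps to a document without the section
  spec2 <- log_fixture_spec(canonical_water(),
                            tasks = list(list(type = "scf", basis = "sto-3g",
                                              energy = -74.9)))
  cj2 <- chemlog_to_cjson(parse_nwchem_log(generate_nwchem_log(spec2)), 1L)
  expect_null(cj2$vibrations)
})

test_that("conversion lattice preserves atoms and coordinates", {
  pairs <- expand.grid(from = c("xyz", "cml", "cjson"),
                       to = c("xyz", "cml", "cjson"),
                       stringsAsFactors = FALSE)
  for (seed in c(3, 14, 59)) {
    mol <- random_molecule(seed)
    inputs <- list(xyz = write_xyz(mol), cml = write_cml(mol),
                   cjson = write_cjson(mol))
    for (k in seq_len(nrow(pairs))) {
      f <- pairs$from[k]; g <- pairs$to[k]
      once <- chem_convert(inputs[[f]], f, g)
      back <- chem_convert(once$text, g, f)
      final <- switch(f, xyz = read_xyz(back$text), cml = read_cml(back$text),
                      cjson = parse_cjson(back$text)$molecule)
      expect_identical(final$atomic_numbers, mol$atomic_numbers)
      expect_lt(max(abs(final$coords - mol$coords), 0), 1e-6)
      # bond loss only on paths through xyz, and flagged there
      through_xyz <- "xyz" %in% c(f, g)
      if (!through_xyz) {
        expect_identical(bond_set(final), bond_set(mol))
      } else if (g == "xyz" && f != "xyz" && nrow(mol$bonds) > 0) {
        expect_true(any(grepl("bond", once$lossy)))
      }
    }
  }
})

test_that("conversion dispatcher enforces the supported pairs", {
  expect_error(chem_convert("x", "xyz", "chemlog"), "unsupported conversion target")
  expect_error(chem_convert("x", "sdf", "xyz"), "unknown format")
  # identity conversion is semantically identical
  w <- canonical_water()
  out <- chem_convert(write_cjson(w), "cjson", "cjson")
  expect_identical(parse_cjson(out$text)$molecule$coords, w$coords)
  # chemlog is read-only as a source: first calculation is selected
  doc <- parse_nwchem_log(generate_nwchem_log(random_log_spec(4)))
  conv <- chem_convert(write_chemlog(doc), "chemlog", "xyz")
  got <- read_xyz(conv$text)
  want <- extract_molecule(doc, 1L)
  expect_lt(max(abs(got$coords - want$coords)), 1e-6)
})

test_that("vibration frames follow the sinusoidal loop exactly", {
  w <- canonical_water()
  d <- c(1, rep(0, 8))
  vib <- vibrational_data(1595, modes = list(d))
  frames <- vibration_frames(w, vib, 1L, amplitude = 0.25, n_frames = 4L)
  disp <- lapply(frames, function(f) f - w$coords)
  expect_identical(disp[[1]], numeric(9))           # frame 0 == equilibrium
  expect_identical(disp[[2]], 0.25 * d)             # +A exactly
  expect_identical(disp[[3]], numeric(9))           # 0 exactly (sinpi)
  expect_identical(disp[[4]], -0.25 * d)            # -A exactly
  # amplitude 0: every frame equals the equilibrium geometry
  frames0 <- vibration_frames(w, vib, 1L, amplitude = 0, n_frames = 7L)
  for (f in frames0) expect_identical(f, w$coords)
  # antisymmetry: frame k and frame n-k displaced oppositely
  n <- 10L
  fr <- vibration_frames(w, vib, 1L, amplitude = 0.5, n_frames = n)
  for (k in 1:4) {
    expect_equal(fr[[k + 1L]] - w$coords, -(fr[[n - k + 1L]] - w$coords))
  }
  # displacement vector is max-norm normalized before scaling
  vib2 <- vibrational_data(100, modes = list(c(2, rep(0, 8))))
  fr2 <- vibration_frames(w, vib2, 1L, amplitude = 1, n_frames = 4L)
  expect_identical(max(abs(fr2[[2]] - w$coords)), 1)
  expect_error(vibration_frames(w, vib, 2L, 0.1, 4L), "out of range")
})
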