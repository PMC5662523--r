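# Hand-built two-calculation fixture: calculation 1 defines Molecule.2 (bohr
# coordinates) and BasisSet.1 inline; calculation 2 references both and adds a
# per-atom property pointing at Atom.1.Mol.2.
chemlog_fixture <- function() {
  atoms <- list(
    list(id = "Atom.1.Mol.2", element = "O",
         coordinates = list(value = list(0, 0, 0), units = "bohr")),
    list(id = "Atom.2.Mol.2", element = "H",
         coordinates = list(value = list(1.43042, 1.10739, 0), units = "bohr")),
    list(id = "Atom.3.Mol.2", element = "H",
         coordinates = list(value = list(-1.43042, 1.10739, 0), units = "bohr")))
  list(
    simulation = list(code = "NWChem", version = "7.0"),
    calculations = list(
      list(id = "Calculation.1",
           calculationSetup = list(id = "Setup.1", theory = "scf",
                                   task = "energy",
                                   basisSet = list(id = "BasisSet.1",
                                                   name = "6-31g")),
           molecule = list(id = "Molecule.2", atoms = atoms),
           calculationResults = list(
             totalEnergy = list(value = -76.02676, units = "hartree"))),
      list(id = "Calculation.2",
           calculationSetup = list(id = "Setup.2", theory = "dft",
                                   task = "energy",
                                   basisSet = "BasisSet.1"),
           molecule = "Molecule.2",
           calculationResults = list(
             totalEnergy = list(value = -76.40123, units = "hartree"),
             atomicCharges = list(
               list(atom = "Atom.1.Mol.2",
                    value = -0.82, units = "dimensionless"))))))
}

test_that("id-tag references resolve to the first-mention object", {
  doc <- chemlog_document(chemlog_fixture())
  mol2 <- resolve_reference(doc, "Molecule.2")
  expect_identical(mol2$id, "Molecule.2")
  # calculation 2's molecule is the object defined in calculation 1
  expect_identical(chemtrove:::chemlog_deref(doc, doc$calculations[[2]]$molecule),
                   doc$calculations[[1]]$molecule)
  atom <- resolve_reference(doc, "Atom.1.Mol.2")
  expect_identical(atom$element, "O")
  # resolving the same tag twice returns the identical object
  expect_identical(resolve_reference(doc, "Molecule.2"),
                   resolve_reference(doc, "Molecule.2"))
  expect_error(resolve_reference(doc, "Molecule.9"), "Molecule.9")
  expect_error(resolve_reference(doc, ""), "resolve")
})

test_that("dangling, forward and duplicate id-tags are rejected", {
  tree <- chemlog_fixture()
  tree$calculations[[2]]$molecule <- "Molecule.9"
  expect_error(chemlog_document(tree), "unresolved reference \"Molecule.9\"")

  # forward reference: calc 1 references the molecule calc 2 defines later
  fwd <- chemlog_fixture()
  molobj <- fwd$calculations[[1]]$molecule
  fwd$calculations[[1]]$molecule <- "Molecule.2"
  fwd$calculations[[2]]$molecule <- molobj
  expect_error(chemlog_document(fwd), "unresolved reference")

  dup <- chemlog_fixture()
  dup$calculations[[2]]$molecule <-
    list(id = "Molecule.2", atoms = list()) # different object, same tag
  expect_error(chemlog_document(dup), "duplicate id-tag")
})

test_that("registry construction is order-deterministic across re-parses", {
  text <- write_chemlog(chemlog_document(chemlog_fixture()))
  k1 <- names(parse_chemlog(text)$registry)
  k2 <- names(parse_chemlog(text)$registry)
  expect_identical(k1, k2)
  expect_true(all(c("Calculation.1", "Molecule.2", "BasisSet.1",
                    "Atom.1.Mol.2") %in% k1))
})

test_that("writer serializes each shared object once, later uses as tags", {
  # build a tree where the shared molecule is inlined twice
  tree <- chemlog_fixture()
  tree$calculations[[2]]$molecule <- tree$calculations[[1]]$molecule
  doc <- chemlog_document(chemtrove:::chemlog_dedup(tree))
  text <- write_chemlog(doc)
  expect_equal(length(gregexpr("\"Molecule.2\"", text, fixed = TRUE)[[1]]) >= 1,
               TRUE)
  reparsed <- parse_chemlog(text)
  # second occurrence became a reference string
  expect_identical(reparsed$calculations[[2]]$molecule, "Molecule.2")
  # the molecule object itself appears exactly once
  expect_equal(sum(gregexpr("Atom.2.Mol.2", text, fixed = TRUE)[[1]] > 0), 1L)
})

test_that("parse of write reproduces the document structurally", {
  d1 <- parse_chemlog(write_chemlog(chemlog_document(chemlog_fixture())))
  d2 <- parse_chemlog(write_chemlog(d1))
  expect_identical(d1$tree, d2$tree)
  expect_identical(names(d1$registry), names(d2$registry))
  # single-calculation document emits no reference strings
  single <- chemlog_fixture()
  single$calculations <- single$calculations[1]
  txt <- write_chemlog(chemlog_document(single))
  expect_false(grepl("\"molecule\"\\s*:\\s*\"Molecule", txt))
})

test_that("extract_molecule converts declared units to angstrom", {
  doc <- chemlog_document(chemlog_fixture())
  mol <- extract_molecule(doc, 1L)
  expect_identical(mol$atomic_numbers, c(8L, 1L, 1L))
  expect_equal(atom_position(mol, 1L), c(0.757, 0.586, 0), tolerance = 1e-4)
  # bohr -> angstrom uses the CODATA factor
  expect_equal(mol$coords[4], 1.43042 * 0.529177210903, tolerance = 1e-12)
  # a molecule given as a reference extracts identically to the inline one
  expect_identical(extract_molecule(doc, 2L)$coords, mol$coords)
  expect_error(extract_molecule(doc, 3L), "out of range")
  expect_error(extract_molecule(doc, 0L), "out of range")
})

test_that("angstrom coordinates pass through unchanged", {
  tree <- chemlog_fixture()
  tree$calculations[[1]]$molecule$atoms <- lapply(
    tree$calculations[[1]]$molecule$atoms, function(a) {
      a$coordinates$units <- "angstrom"
      a
    })
  doc <- chemlog_document(tree)
  mol <- extract_molecule(doc, 1L)
  expect_equal(mol$coords[4], 1.43042)
})
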