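# Independent oracles used by the property tests. These deliberately avoid
# the code paths they check: the query oracle walks the AST with its own
# field derivations, and the formula oracle re-implements Hill ordering from
# the element table alone.

oracle_hill <- function(mol) {
  if (length(mol$atomic_numbers) == 0L) return("")
  tab <- table(element_symbol(mol$atomic_numbers))
  syms <- sort(names(tab))
  if ("C" %in% syms) syms <- c(intersect(c("C", "H"), syms),
                               setdiff(syms, c("C", "H")))
  paste0(mapply(function(s, k) if (k == 1) s else paste0(s, k),
                syms, as.integer(tab[syms])), collapse = "")
}

oracle_field <- function(mol, field) {
  switch(field,
         mass = sum(atomic_weight(mol$atomic_numbers)),
         atomCount = length(mol$atomic_numbers),
         heavyAtomCount = sum(mol$atomic_numbers != 1L),
         name = mol$name,
         inchi = mol$inchi,
         inchikey = mol$inchikey,
         formula = oracle_hill(mol))
}

oracle_eval <- function(ast, mol) {
  if (ast$node == "and") {
    return(oracle_eval(ast$left, mol) && oracle_eval(ast$right, mol))
  }
  if (ast$node == "or") {
    return(oracle_eval(ast$left, mol) || oracle_eval(ast$right, mol))
  }
  v <- oracle_field(mol, ast$field)
  if (is.null(v)) return(FALSE)
  if (is.numeric(ast$value)) {
    switch(ast$op,
           "<" = v < ast$value, "<=" = v <= ast$value,
           ">" = v > ast$value, ">=" = v >= ast$value,
           "=" = v == ast$value, "!=" = v != ast$value)
  } else {
    switch(ast$op,
           "=" = tolower(v) == tolower(ast$value),
           "~" = grepl(tolower(ast$value), tolower(v), fixed = TRUE))
  }
}

# Convenience: a small fixed store of named molecules for search tests.
fixture_trio <- function() {
  methane <- molecule(c(6L, 1L, 1L, 1L, 1L), numeric(15), name = "methane")
  ammonia <- molecule(c(7L, 1L, 1L, 1L), numeric(12), name = "ammonia")
  list(water = canonical_water(), methane = methane, ammonia = ammonia)
}

expect_coords_equal <- function(a, b, tol = 1e-6) {
  expect_equal(length(a$coords), length(b$coords))
  expect_lt(max(abs(a$coords - b$coords), 0), tol)
  expect_identical(a$atomic_numbers, b$atomic_numbers)
}

bond_set <- function(mol) {
  bt <- mol$bonds
  if (nrow(bt) == 0L) return(character())
  sort(sprintf("%d-%d:%d", pmin(bt$a, bt$b), pmax(bt$a, bt$b), bt$order))
}
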