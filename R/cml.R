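# CML codec: the attribute-form subset of the Chemical Markup Language —
# molecule / atomArray / atom(@id @elementType @x3 @y3 @z3) and
# bondArray / bond(@atomRefs2 @order). Atom ids are written a1..aN.

#' Read a CML document (subset)
#'
#' @param text CML/XML text.
#' @return A \code{\link{molecule}}.
#' @export
read_cml <- function(text) {
  xml <- xml2::read_xml(text)
  # strip any namespace so the subset works with or without the CML xmlns
  xml2::xml_ns_strip(xml)
  atom_nodes <- xml2::xml_find_all(xml, ".//atomArray/atom")
  if (length(atom_nodes) == 0L) {
    stop("CML document contains no atomArray/atom elements", call. = FALSE)
  }
  ids <- xml2::xml_attr(atom_nodes, "id")
  symbols <- xml2::xml_attr(atom_nodes, "elementType")
  if (anyNA(symbols)) stop("CML atom missing elementType", call. = FALSE)
  z <- atomic_number(symbols)
  get_coord <- function(attr) {
    v <- suppressWarnings(as.numeric(xml2::xml_attr(atom_nodes, attr)))
    if (anyNA(v)) stop(sprintf("CML atom missing or non-numeric @%s", attr),
                       call. = FALSE)
    v
  }
  coords <- as.numeric(rbind(get_coord("x3"), get_coord("y3"), get_coord("z3")))
  bond_nodes <- xml2::xml_find_all(xml, ".//bondArray/bond")
  bonds <- NULL
  if (length(bond_nodes) > 0) {
    refs <- strsplit(trimws(xml2::xml_attr(bond_nodes, "atomRefs2")), "\\s+")
    if (any(lengths(refs) != 2L)) {
      stop("CML bond atomRefs2 must name exactly two atoms", call. = FALSE)
    }
    a <- match(vapply(refs, `[`, character(1), 1L), ids)
    b <- match(vapply(refs, `[`, character(1), 2L), ids)
    if (anyNA(a) || anyNA(b)) {
      stop("CML bond atomRefs2 names an unknown atom id", call. = FALSE)
    }
    ord <- suppressWarnings(as.integer(xml2::xml_attr(bond_nodes, "order")))
    ord[is.na(ord)] <- 1L
    bonds <- bond_table(a - 1L, b - 1L, ord)
  }
  title <- xml2::xml_attr(xml, "title")
  molecule(z, coords, bonds = bonds,
           name = if (is.na(title)) NULL else title)
}

#' Write a CML document (subset)
#'
#' @param mol A \code{\link{molecule}}.
#' @return CML text; atom ids are a1..aN.
#' @export
write_cml <- function(mol) {
  validate_molecule(mol)
  n <- atom_count(mol)
  root <- xml2::xml_new_root("molecule")
  if (!is.null(mol$name)) xml2::xml_set_attr(root, "title", mol$name)
  aa <- xml2::xml_add_child(root, "atomArray")
  for (i in seq_len(n)) {
    p <- atom_position(mol, i - 1L)
    xml2::xml_add_child(aa, "atom",
                        id = paste0("a", i),
                        elementType = element_symbol(mol$atomic_numbers[i]),
                        x3 = format(p[1], digits = 15),
                        y3 = format(p[2], digits = 15),
                        z3 = format(p[3], digits = 15))
  }
  bt <- mol$bonds
  if (nrow(bt) > 0) {
    ba <- xml2::xml_add_child(root, "bondArray")
    for (k in seq_len(nrow(bt))) {
      xml2::xml_add_child(ba, "bond",
                          atomRefs2 = sprintf("a%d a%d", bt$a[k] + 1L,
                                              bt$b[k] + 1L),
                          order = as.character(bt$order[k]))
    }
  }
  as.character(root)
}
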