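# Molecule search query language.
#
# Grammar (AND binds tighter than OR; keywords case-insensitive):
#   expr       := term (OR term)*
#   term       := factor (AND factor)*
#   factor     := '(' expr ')' | comparison | bareword
#   comparison := field op literal
# Numeric fields: mass, atomCount, heavyAtomCount with < <= > >= = !=
# String fields: name, inchi, inchikey, formula with = (case-insensitive
# exact) and ~ (case-insensitive substring).
# A bareword desugars to `name ~ bareword`.

.query_numeric_fields <- c("mass", "atomcount", "heavyatomcount")
.query_string_fields <- c("name", "inchi", "inchikey", "formula")
.query_field_canon <- c(mass = "mass", atomcount = "atomCount",
                        heavyatomcount = "heavyAtomCount", name = "name",
                        inchi = "inchi", inchikey = "inchikey",
                        formula = "formula")

query_tokenize <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) { push(ch, ch, i); i <- i + 1L; next }
    rest <- substr(text, i, n)
    m <- regmatches(rest, regexpr("^(<=|>=|!=|<|>|=|~)", rest))
    if (length(m)) { push("op", m, i); i <- i + nchar(m); next }
    if (ch == "\"" || ch == "'") {
      m <- regmatches(rest, regexpr(paste0("^", ch, "[^", ch, "]*", ch), rest))
      if (!length(m)) {
        stop(sprintf("query syntax error at position %d: unterminated string",
                     i), call. = FALSE)
      }
      push("string", substr(m, 2L, nchar(m) - 1L), i)
      i <- i + nchar(m)
      next
    }
    m <- regmatches(rest, regexpr("^[^\\s()<>=!~\"']+", rest, perl = TRUE))
    if (!length(m)) {
      stop(sprintf("query syntax error at position %d: unexpected \"%s\"",
                   i, ch), call. = FALSE)
    }
    if (tolower(m) %in% c("and", "or")) {
      push(tolower(m), m, i)
    } else if (grepl("^[-+]?(\\d+\\.?\\d*|\\.\\d+)([eE][-+]?\\d+)?$", m)) {
      push("number", as.numeric(m), i)
    } else {
      push("word", m, i)
    }
    i <- i + nchar(m)
  }
  tokens
}

#' Parse a molecule search query
#'
#' Parses the boolean/comparison query language used by molecule search into
#' an abstract syntax tree. AND binds tighter than OR; parentheses group; a
#' bare word is shorthand for a case-insensitive substring match on the
#' molecule name.
#'
#' @param text Query text, e.g. \code{"mass>17 and mass<19"}.
#' @return A \code{query_ast} node: a list with \code{node} being one of
#'   \code{"and"}, \code{"or"} (with \code{left}, \code{right}) or
#'   \code{"cmp"} (with \code{field}, \code{op}, \code{value}).
#' @export
parse_query <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("query must be a non-empty string", call. = FALSE)
  }
  tokens <- query_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { t <- peek(); pos <<- pos + 1L; t }
  fail <- function(t, what) {
    where <- if (is.null(t)) "end of query" else sprintf("position %d", t$pos)
    stop(sprintf("query syntax error at %s: %s", where, what), call. = FALSE)
  }

  cmp_node <- function(field, op, value) {
    structure(list(node = "cmp", field = field, op = op, value = value),
              class = "query_ast")
  }

  parse_factor <- function() {
    t <- peek()
    if (is.null(t)) fail(t, "expected a comparison or bareword")
    if (t$type == "(") {
      advance()
      e <- parse_expr()
      close <- advance()
      if (is.null(close) || close$type != ")") fail(close, "expected )")
      return(e)
    }
    if (t$type %in% c("word", "string", "number")) {
      nxt <- if (pos + 1L <= length(tokens)) tokens[[pos + 1L]] else NULL
      if (!is.null(nxt) && nxt$type == "op") {
        field_tok <- advance()
        field_l <- tolower(as.character(field_tok$value))
        op <- advance()$value
        lit <- advance()
        if (is.null(lit)) fail(lit, "expected a literal after operator")
        if (!(field_l %in% c(.query_numeric_fields, .query_string_fields))) {
          stop(sprintf("unknown query field \"%s\"", field_tok$value),
               call. = FALSE)
        }
        field <- .query_field_canon[[field_l]]
        if (field_l %in% .query_numeric_fields) {
          if (!(op %in% c("<", "<=", ">", ">=", "=", "!="))) {
            stop(sprintf("operator \"%s\" not valid for numeric field \"%s\"",
                         op, field), call. = FALSE)
          }
          if (lit$type != "number") {
            stop(sprintf("field \"%s\" requires a numeric literal", field),
                 call. = FALSE)
          }
          return(cmp_node(field, op, lit$value))
        }
        if (!(op %in% c("=", "~"))) {
          stop(sprintf("operator \"%s\" not valid for string field \"%s\"",
                       op, field), call. = FALSE)
        }
        return(cmp_node(field, op, as.character(lit$value)))
      }
      # bareword: substring match on name
      advance()
      return(cmp_node("name", "~", as.character(t$value)))
    }
    fail(t, sprintf("unexpected token \"%s\"", t$value))
  }

  parse_term <- function() {
    left <- parse_factor()
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      right <- parse_factor()
      left <- structure(list(node = "and", left = left, right = right),
                        class = "query_ast")
    }
    left
  }

  parse_expr <- function() {
    left <- parse_term()
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      right <- parse_term()
      left <- structure(list(node = "or", left = left, right = right),
                        class = "query_ast")
    }
    left
  }

  ast <- parse_expr()
  t <- peek()
  if (!is.null(t)) fail(t, sprintf("unexpected trailing token \"%s\"", t$value))
  ast
}

#' Canonical printer for a query AST
#'
#' Prints an AST back to query text with explicit parentheses; parsing the
#' output reproduces the AST (print/parse fixpoint).
#'
#' @param ast A \code{query_ast}.
#' @return Query text.
#' @export
format_query <- function(ast) {
  stopifnot(inherits(ast, "query_ast"))
  switch(ast$node,
    cmp = {
      lit <- if (is.numeric(ast$value)) {
        format(ast$value, digits = 15)
      } else {
        paste0("\"", ast$value, "\"")
      }
      paste0(ast$field, ast$op, lit)
    },
    and = paste0("(", format_query(ast$left), " and ",
                 format_query(ast$right), ")"),
    or = paste0("(", format_query(ast$left), " or ",
                format_query(ast$right), ")"))
}

#' @export
print.query_ast <- function(x, ...) {
  cat(format_query(x), "\n")
  invisible(x)
}

query_field_value <- function(mol, field) {
  switch(field,
         mass = molecular_mass(mol),
         atomCount = atom_count(mol),
         heavyAtomCount = heavy_atom_count(mol),
         name = mol$name,
         inchi = mol$inchi,
         inchikey = mol$inchikey,
         formula = hill_formula(mol))
}

#' Evaluate a query against one molecule
#'
#' Numeric fields are derived from the molecule (mass, atom count, heavy-atom
#' count); string comparisons are case-insensitive. A comparison against a
#' missing optional field (e.g. a molecule without an InChI) is false.
#'
#' @param ast A \code{query_ast} from \code{\link{parse_query}}.
#' @param mol A \code{\link{molecule}}.
#' @return TRUE or FALSE.
#' @export
evaluate_query <- function(ast, mol) {
  stopifnot(inherits(ast, "query_ast"))
  switch(ast$node,
    and = evaluate_query(ast$left, mol) && evaluate_query(ast$right, mol),
    or = evaluate_query(ast$left, mol) || evaluate_query(ast$right, mol),
    cmp = {
      v <- query_field_value(mol, ast$field)
      if (is.null(v)) return(FALSE)
      if (is.numeric(ast$value)) {
        switch(ast$op,
               "<" = v < ast$value, "<=" = v <= ast$value,
               ">" = v > ast$value, ">=" = v >= ast$value,
               "=" = v == ast$value, "!=" = v != ast$value)
      } else {
        a <- tolower(v); b <- tolower(ast$value)
        switch(ast$op,
               "=" = a == b,
               "~" = grepl(b, a, fixed = TRUE))
      }
    })
}

#' Search a molecule collection
#'
#' Linear scan: every molecule for which the query evaluates true is
#' returned, in insertion order, as a summary record. No match yields an
#' empty list.
#'
#' @param mols Named list of molecules (names are the stored ids) or an
#'   unnamed list (ids fall back to the list position).
#' @param query Query text.
#' @return A list of records, each with \code{id}, \code{inchikey} (possibly
#'   NULL) and \code{name} (possibly NULL).
#' @export
search_molecules <- function(mols, query) {
  ast <- parse_query(query)
  ids <- names(mols)
  if (is.null(ids)) ids <- as.character(seq_along(mols))
  out <- list()
  for (k in seq_along(mols)) {
    if (isTRUE(evaluate_query(ast, mols[[k]]))) {
      out[[length(out) + 1L]] <- list(id = ids[k],
                                      inchikey = mols[[k]]$inchikey,
                                      name = mols[[k]]$name)
    }
  }
  out
}

#' Generate a random query AST
#'
#' Seeded generator used in the oracle-equivalence property tests: random
#' comparisons over the searchable fields combined with AND/OR to a bounded
#' depth.
#'
#' @param seed Integer seed.
#' @param max_depth Maximum nesting depth.
#' @return A \code{query_ast}.
#' @export
random_query_ast <- function(seed, max_depth = 3L) {
  gen <- function(depth) {
    if (depth >= max_depth || stats::runif(1) < 0.4) {
      if (stats::runif(1) < 0.7) {
        field <- sample(c("mass", "atomCount", "heavyAtomCount"), 1L)
        op <- sample(c("<", "<=", ">", ">=", "=", "!="), 1L)
        value <- switch(field,
                        mass = round(stats::runif(1, 1, 200), 1),
                        sample(0:12, 1L))
        structure(list(node = "cmp", field = field, op = op,
                       value = as.numeric(value)), class = "query_ast")
      } else {
        field <- sample(c("name", "formula", "inchikey"), 1L)
        op <- sample(c("=", "~"), 1L)
        value <- sample(c("random", "H2O", "C", "O2", "benzene", "x"), 1L)
        structure(list(node = "cmp", field = field, op = op, value = value),
                  class = "query_ast")
      }
    } else {
      structure(list(node = sample(c("and", "or"), 1L),
                     left = gen(depth + 1L), right = gen(depth + 1L)),
                class = "query_ast")
    }
  }
  with_seed(seed, gen(0L))
}
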