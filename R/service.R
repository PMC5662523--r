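# REST-style data service: a pure request router over a chem_store, plus an
# optional httpuv-backed server for live use. The router is a plain function
# from (method, path, query, body) to (status, content type, body text), so
# the full endpoint contract is testable in-process; the HTTP layer is a thin
# adapter.
#
# Endpoints (all under /api/v1):
#   GET  /molecules?name=|inchi=|inchikey=         summary list (exactly one
#                                                  parameter)
#   GET  /molecules/search?q=QUERY                 query-language search
#   GET  /molecules/inchikey/{key}                 full record by InChIKey
#   GET  /molecules/{id}/{xyz|cml|cjson}           formatted retrieval
#   POST /molecules/conversions/{format}           format conversion
#   GET  /calculations?moleculeId=ID               calculation summaries
#   GET  /calculations/{id}/{cjson|vibrations}     calculation resources
#   GET  /calculations/{id}/cube/{n}               volumetric data as cube text
#   POST /calculations                             upload a ChemLog document

api_json <- function(status, data) {
  list(status = status, content_type = "application/json",
       body = as.character(jsonlite::toJSON(data, auto_unbox = TRUE,
                                            digits = NA, null = "null")))
}

api_error <- function(status, message) api_json(status, list(error = message))

api_text <- function(status, body, content_type = "text/plain") {
  list(status = status, content_type = content_type, body = body)
}

# jsonlite drops NULL list elements inside auto_unbox containers only for
# unnamed NULLs; normalize summaries so absent fields serialize as null.
null_to_na <- function(x) if (is.null(x)) NA else x

summary_record <- function(mol) {
  list(id = mol$id, inchikey = null_to_na(mol$inchikey),
       name = null_to_na(mol$name))
}

calc_summary <- function(rec) {
  list(`_id` = rec$id, code = rec$code, theory = rec$theory,
       calculationTypes = I(rec$calculation_types),
       fileId = null_to_na(rec$file_id))
}

#' Handle one request against the data service
#'
#' The complete service contract as a pure function; see the package
#' vignette for the endpoint table. Bodies are JSON except for the formatted
#' molecule retrievals (xyz is text/plain, cml is chemical/x-cml).
#'
#' @param store A \code{\link{chem_store}}.
#' @param method "GET" or "POST".
#' @param path Request path, e.g. \code{"/api/v1/molecules/abc123/xyz"}.
#' @param query Named list of query parameters.
#' @param body Request body text (POST endpoints).
#' @return A list with \code{status} (integer), \code{content_type} and
#'   \code{body} (text).
#' @export
api_handle <- function(store, method, path, query = list(), body = NULL) {
  seg <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  if (length(seg) < 2L || seg[1] != "api" || seg[2] != "v1") {
    return(api_error(404L, sprintf("unknown path %s", path)))
  }
  seg <- seg[-(1:2)]

  if (length(seg) == 0L) {
    if (method != "GET") return(api_error(405L, "method not allowed"))
    return(api_json(200L, list(routes = c(
      "GET /api/v1/molecules?name=|inchi=|inchikey=",
      "GET /api/v1/molecules/search?q=",
      "GET /api/v1/molecules/inchikey/{key}",
      "GET /api/v1/molecules/{id}/{xyz|cml|cjson}",
      "POST /api/v1/molecules/conversions/{output_format}",
      "GET /api/v1/calculations?moleculeId=",
      "GET /api/v1/calculations/{id}/{cjson|vibrations|cube/{n}}",
      "POST /api/v1/calculations"))))
  }

  if (seg[1] == "molecules") {
    rest <- seg[-1]

    if (length(rest) == 0L && method == "GET") {
      params <- intersect(names(query), c("name", "inchi", "inchikey"))
      if (length(params) != 1L) {
        return(api_error(400L,
          "exactly one of name, inchi or inchikey must be supplied"))
      }
      field <- params[1]
      want <- tolower(as.character(query[[field]]))
      hits <- Filter(function(mol) {
        v <- mol[[field]]
        !is.null(v) && tolower(v) == want
      }, store_molecules(store))
      return(api_json(200L, lapply(unname(hits), summary_record)))
    }

    if (length(rest) == 1L && rest[1] == "search" && method == "GET") {
      if (is.null(query$q)) return(api_error(400L, "missing query parameter q"))
      res <- tryCatch(search_molecules(store_molecules(store), query$q),
                      error = function(e) e)
      if (inherits(res, "error")) return(api_error(400L, conditionMessage(res)))
      return(api_json(200L, lapply(res, function(r) {
        list(id = r$id, inchikey = null_to_na(r$inchikey),
             name = null_to_na(r$name))
      })))
    }

    if (length(rest) == 2L && rest[1] == "inchikey" && method == "GET") {
      mols <- store_molecules(store)
      hit <- Filter(function(m) identical(m$inchikey, rest[2]), mols)
      if (length(hit) == 0L) {
        return(api_error(404L, sprintf("no molecule with InChIKey %s", rest[2])))
      }
      mol <- hit[[1]]
      return(api_json(200L, list(
        id = mol$id, inchikey = null_to_na(mol$inchikey),
        name = null_to_na(mol$name), formula = hill_formula(mol),
        mass = molecular_mass(mol), atomCount = atom_count(mol),
        heavyAtomCount = heavy_atom_count(mol))))
    }

    if (length(rest) == 2L && rest[1] == "conversions" && method == "POST") {
      out_format <- rest[2]
      req <- tryCatch(json_read(body), error = function(e) NULL)
      if (is.null(req) || is.null(req$input) || is.null(req$inputFormat)) {
        return(api_error(400L,
          "body must be JSON with fields input and inputFormat"))
      }
      conv <- tryCatch(chem_convert(req$input, req$inputFormat, out_format),
                       error = function(e) e)
      if (inherits(conv, "error")) {
        msg <- conditionMessage(conv)
        status <- if (grepl("unsupported|unknown format", msg)) 400L else 422L
        return(api_error(status, msg))
      }
      return(api_json(200L, list(output = conv$text,
                                 lossy = I(conv$lossy))))
    }

    if (length(rest) == 2L && method == "GET") {
      mol <- store_get_molecule(store, rest[1])
      if (is.null(mol)) {
        return(api_error(404L, sprintf("no molecule with id %s", rest[1])))
      }
      fmt <- tolower(rest[2])
      if (!(fmt %in% c("xyz", "cml", "cjson"))) {
        return(api_error(400L, sprintf("unknown format \"%s\"", rest[2])))
      }
      return(switch(fmt,
        xyz = api_text(200L, write_xyz(mol)),
        cml = api_text(200L, write_cml(mol), "chemical/x-cml"),
        cjson = api_text(200L, write_cjson(mol), "application/json")))
    }

    return(api_error(404L, sprintf("unknown path %s", path)))
  }

  if (seg[1] == "calculations") {
    rest <- seg[-1]

    if (length(rest) == 0L && method == "GET") {
      if (is.null(query$moleculeId)) {
        return(api_error(400L, "missing query parameter moleculeId"))
      }
      recs <- store_calculations_for(store, query$moleculeId)
      return(api_json(200L, lapply(recs, calc_summary)))
    }

    if (length(rest) == 0L && method == "POST") {
      doc <- tryCatch(parse_chemlog(body), error = function(e) e)
      if (inherits(doc, "error")) {
        return(api_error(422L, conditionMessage(doc)))
      }
      res <- store_upload_calculations(store, doc)
      return(api_json(200L, list(moleculeId = res$moleculeId,
                                 moleculeIds = I(res$moleculeIds),
                                 calculationIds = I(res$calculationIds))))
    }

    if (length(rest) >= 2L && method == "GET") {
      rec <- store_get_calculation(store, rest[1])
      if (is.null(rec)) {
        return(api_error(404L, sprintf("no calculation with id %s", rest[1])))
      }
      resource <- rest[2]
      if (resource == "cjson" && length(rest) == 2L) {
        return(api_text(200L, cjson_text(rec$cjson), "application/json"))
      }
      if (resource == "vibrations" && length(rest) == 2L) {
        vib <- rec$vibrations
        if (is.null(vib)) {
          return(api_error(404L, "calculation has no vibrational data"))
        }
        out <- list(frequencies = I(vib$frequencies))
        if (!is.null(vib$intensities)) out$intensities <- I(vib$intensities)
        if (!is.null(vib$modes)) out$eigenVectors <- lapply(vib$modes, I)
        return(api_json(200L, out))
      }
      if (resource == "cube" && length(rest) == 3L) {
        idx <- suppressWarnings(as.integer(rest[3]))
        if (is.na(idx) || idx < 1L || idx > length(rec$volumes)) {
          return(api_error(404L, sprintf(
            "calculation has %d volume(s); index %s not available",
            length(rec$volumes), rest[3])))
        }
        mol <- store_get_molecule(store, rec$molecule_id)
        return(api_text(200L, write_cube(mol, rec$volumes[[idx]])))
      }
      return(api_error(404L, sprintf("unknown resource \"%s\"", resource)))
    }

    return(api_error(404L, sprintf("unknown path %s", path)))
  }

  api_error(404L, sprintf("unknown path %s", path))
}

#' Serve the data service over HTTP
#'
#' Thin adapter running \code{\link{api_handle}} behind httpuv (declared in
#' Suggests). Blocks until interrupted.
#'
#' @param store A \code{\link{chem_store}}.
#' @param port TCP port.
#' @param host Bind address.
#' @return Never returns normally; runs the event loop.
#' @export
api_serve <- function(store, port = 8080L, host = "127.0.0.1") {
  if (!requireNamespace("httpuv", quietly = TRUE)) {
    stop("the httpuv package is required for api_serve()", call. = FALSE)
  }
  app <- list(call = function(req) {
    query <- list()
    qs <- req$QUERY_STRING
    if (!is.null(qs) && nzchar(qs)) {
      qs <- sub("^\\?", "", qs)
      for (pair in strsplit(qs, "&", fixed = TRUE)[[1]]) {
        kv <- strsplit(pair, "=", fixed = TRUE)[[1]]
        if (length(kv) == 2L) query[[utils::URLdecode(kv[1])]] <- utils::URLdecode(kv[2])
      }
    }
    body <- NULL
    if (!is.null(req$rook.input)) {
      body <- rawToChar(req$rook.input$read())
    }
    res <- api_handle(store, req$REQUEST_METHOD, req$PATH_INFO, query, body)
    list(status = res$status,
         headers = list("Content-Type" = res$content_type),
         body = res$body)
  })
  message(sprintf("chemtrove service listening on http://%s:%d/api/v1",
                  host, port))
  httpuv::runServer(host, port, app)
}
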