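# XMLBIF 0.3 serialization. The XMLBIF table convention used here: for each
# DEFINITION, probabilities are listed with the node's outcomes varying
# fastest, and parent configurations iterated lexicographically in GIVEN order
# (first GIVEN slowest). Schema metadata XMLBIF cannot carry (variable
# category, clinic applicability, fit diagnostics) goes to a JSON sidecar.

#' Write / read a network as XMLBIF
#'
#' Lossless round-trip of an [rt_network()]: structure, state vocabularies and
#' CPT entries (full precision) go to an XMLBIF 0.3 file; variable categories,
#' clinic applicability and EM fit diagnostics to a JSON sidecar next to it
#' (`<path>.meta.json`). A file whose CPT rows do not sum to one within
#' `1e-9` is rejected on load.
#'
#' @param network an `rt_bn`.
#' @param path file path for the XMLBIF document.
#' @param name network name to embed (write only).
#' @param sidecar path of the JSON sidecar; `NULL` on read means "use the
#'   default path if it exists, else fall back to `schema`".
#' @param schema fallback schema used on read when no sidecar is available.
#' @return `write_xmlbif()` returns `path` invisibly; `read_xmlbif()` an
#'   `rt_bn`.
#' @export
write_xmlbif <- function(network, path, name = "planreview",
                         sidecar = paste0(path, ".meta.json")) {
  doc <- xml2::xml_new_root("BIF", VERSION = "0.3")
  net <- xml2::xml_add_child(doc, "NETWORK")
  xml2::xml_add_child(net, "NAME", name)
  for (v in network$nodes) {
    var <- xml2::xml_add_child(net, "VARIABLE", TYPE = "nature")
    xml2::xml_add_child(var, "NAME", v)
    for (s in network$states[[v]]) xml2::xml_add_child(var, "OUTCOME", s)
  }
  for (v in network$nodes) {
    cp <- network$cpts[[v]]
    def <- xml2::xml_add_child(net, "DEFINITION")
    xml2::xml_add_child(def, "FOR", v)
    for (p in cp$parents) xml2::xml_add_child(def, "GIVEN", p)
    tab <- cpt_to_file_order(cp$prob, network, v)
    xml2::xml_add_child(def, "TABLE", paste(sprintf("%.17g", tab), collapse = " "))
  }
  xml2::write_xml(doc, path)
  if (!is.null(sidecar)) {
    meta <- list(
      variables = lapply(seq_len(nrow(network$schema)), function(i) list(
        variable = network$schema$variable[i],
        category = network$schema$category[i],
        applicable = as.list(network$schema$applicable[[i]])
      )),
      fit = network$fit
    )
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

# internal layout: rows iterate with the FIRST parent fastest; file layout:
# first GIVEN slowest. The permutation maps between the two.
file_row_order <- function(network, node) {
  ps <- network$cpts[[node]]$parents
  if (!length(ps)) return(1L)
  grid <- expand.grid(lapply(ps, function(p) seq_along(network$states[[p]])),
                      KEEP.OUT.ATTRS = FALSE)
  do.call(order, as.list(grid))
}

cpt_to_file_order <- function(prob, network, node) {
  as.vector(t(prob[file_row_order(network, node), , drop = FALSE]))
}

#' @rdname write_xmlbif
#' @export
read_xmlbif <- function(path, sidecar = NULL, schema = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    abort(paste0("malformed XMLBIF file ", path, ": ", conditionMessage(e)),
          class = "planreviewr_parse_error"))
  vars <- xml2::xml_find_all(doc, ".//VARIABLE")
  if (length(vars) == 0) abort(paste0("no VARIABLE elements in ", path),
                               class = "planreviewr_parse_error")
  names_ <- vapply(vars, function(v)
    xml2::xml_text(xml2::xml_find_first(v, "./NAME")), character(1))
  states <- setNames(lapply(vars, function(v)
    xml2::xml_text(xml2::xml_find_all(v, "./OUTCOME"))), names_)

  defs <- xml2::xml_find_all(doc, ".//DEFINITION")
  cpts <- list(); edges_from <- character(0); edges_to <- character(0)
  for (d in defs) {
    v <- xml2::xml_text(xml2::xml_find_first(d, "./FOR"))
    given <- xml2::xml_text(xml2::xml_find_all(d, "./GIVEN"))
    tab <- as.numeric(strsplit(trimws(
      xml2::xml_text(xml2::xml_find_first(d, "./TABLE"))), "\\s+")[[1]])
    r <- length(states[[v]])
    q <- prod(vapply(given, function(p) length(states[[p]]), numeric(1)))
    if (length(tab) != q * r) {
      abort(paste0("TABLE for ", v, " has ", length(tab), " entries, expected ",
                   q * r), class = "planreviewr_parse_error")
    }
    prob_file <- matrix(tab, nrow = q, ncol = r, byrow = TRUE)
    # invert the file row order back to internal layout
    if (length(given)) {
      grid <- expand.grid(lapply(given, function(p) seq_along(states[[p]])),
                          KEEP.OUT.ATTRS = FALSE)
      ord <- do.call(order, as.list(grid))
      prob <- prob_file
      prob[ord, ] <- prob_file
    } else prob <- prob_file
    cpts[[v]] <- list(parents = given, prob = prob)
    edges_from <- c(edges_from, given)
    edges_to <- c(edges_to, rep(v, length(given)))
  }
  edges <- tibble::tibble(from = edges_from, to = edges_to)

  meta_path <- sidecar %||% paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    mv <- vapply(meta$variables, function(x) x$variable, character(1))
    schema <- tibble::tibble(
      variable = names_,
      category = unname(vapply(names_, function(v)
        meta$variables[[match(v, mv)]]$category, character(1))),
      states = unname(states[names_]),
      applicable = lapply(names_, function(v) {
        app <- unlist(meta$variables[[match(v, mv)]]$applicable)
        if (identical(app, "all")) "all" else app
      })
    )
    fit <- meta$fit
  } else {
    if (is.null(schema)) {
      abort(paste0("no sidecar found at ", meta_path,
                   " and no fallback schema given"),
            class = "planreviewr_parse_error")
    }
    schema <- dplyr::filter(schema, .data$variable %in% names_)
    schema$states <- unname(states[schema$variable])
    fit <- NULL
  }
  net <- rt_network(edges, cpts, schema)
  if (!is.null(fit)) {
    fit$log_lik_trace <- unlist(fit$log_lik_trace)
    net$fit <- fit
  }
  net
}
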