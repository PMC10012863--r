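# Network structure: the expert-built DAG over the 24 plan variables.

#' Default network structure
#'
#' The shipped expert-style DAG over the 24 plan variables: 41 directed edges
#' in which the diagnostic variables (staging, tumor location, intent) drive
#' prescription choices, the prescription determines total dose, and technique
#' and anatomy drive the geometric and complexity planning variables. The two
#' plan-complexity surrogates (MU/cGy, MU/degree) hang off technique and beam
#' count, mirroring their role as complexity summaries of a non-VMAT plan.
#'
#' @return A tibble of directed edges with columns `from` (parent) and `to`
#'   (child).
#' @export
#' @examples
#' nrow(default_structure())  # 41
default_structure <- function() {
  e <- matrix(c(
    "tumor_location",      "t_stage",
    "tumor_location",      "n_stage",
    "tumor_location",      "m_stage",
    "m_stage",             "treatment_intent",
    "t_stage",             "treatment_intent",
    "tumor_location",      "treatment_intent",
    "tumor_location",      "laterality",
    "tumor_location",      "treatment_technique",
    "treatment_intent",    "treatment_technique",
    "treatment_intent",    "image_guidance",
    "treatment_technique", "image_guidance",
    "treatment_intent",    "number_of_fractions",
    "tumor_location",      "number_of_fractions",
    "treatment_intent",    "dose_per_fraction",
    "tumor_location",      "dose_per_fraction",
    "number_of_fractions", "ptv_dose",
    "dose_per_fraction",   "ptv_dose",
    "treatment_technique", "radiation_type",
    "radiation_type",      "beam_energy",
    "treatment_technique", "beam_energy",
    "treatment_technique", "number_of_beams",
    "tumor_location",      "number_of_beams",
    "treatment_technique", "gantry_angle",
    "laterality",          "gantry_angle",
    "treatment_technique", "collimator_angle",
    "tumor_location",      "collimator_angle",
    "radiation_type",      "ssd",
    "treatment_technique", "ssd",
    "tumor_location",      "bolus",
    "radiation_type",      "bolus",
    "tumor_location",      "patient_orientation",
    "patient_orientation", "table_angle",
    "treatment_technique", "table_angle",
    "treatment_technique", "tolerance_table",
    "radiation_type",      "tolerance_table",
    "treatment_technique", "mu_per_cgy",
    "number_of_beams",     "mu_per_cgy",
    "treatment_technique", "mu_per_degree",
    "mu_per_cgy",          "mu_per_degree",
    "treatment_technique", "wedge",
    "tumor_location",      "wedge"
  ), ncol = 2, byrow = TRUE)
  tibble::tibble(from = e[, 1], to = e[, 2])
}

structure_nodes <- function(edges, nodes = NULL) {
  union(nodes %||% character(0), union(edges$from, edges$to))
}

#' Validate a network structure
#'
#' Checks that the directed graph is acyclic, reports node and edge counts and
#' any orphan (disconnected) nodes. A detected cycle is a hard failure and the
#' offending nodes are listed.
#'
#' @param edges edge tibble/data frame with columns `from`, `to`.
#' @param nodes optional full node list (to include isolated nodes).
#' @param strict error (rather than report) on a cycle. Default `TRUE`.
#' @return A list of class `rt_structure_report`: `valid`, `n_nodes`,
#'   `n_edges`, `orphans`, `cycle` (character vector of nodes on a cycle, if
#'   any).
#' @export
validate_structure <- function(edges, nodes = NULL, strict = TRUE) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  nodes <- structure_nodes(edges, nodes)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = TRUE, vertices = nodes)
  cyc <- character(0)
  if (!igraph::is_dag(g)) {
    # name the nodes on some cycle via the feedback vertex candidates:
    # nodes in a non-trivial strongly connected component
    comp <- igraph::components(g, mode = "strong")
    big <- which(tabulate(comp$membership) > 1)
    cyc <- sort(names(comp$membership)[comp$membership %in% big])
    if (strict) {
      abort(paste0("structure contains a cycle through: ",
                   paste(cyc, collapse = ", ")),
            class = "planreviewr_cycle_error")
    }
  }
  deg <- igraph::degree(g, mode = "all")
  out <- list(valid = length(cyc) == 0,
              n_nodes = length(nodes),
              n_edges = nrow(edges),
              orphans = names(deg)[deg == 0],
              cycle = cyc)
  class(out) <- "rt_structure_report"
  out
}

#' @export
print.rt_structure_report <- function(x, ...) {
  cat("Network structure: ", x$n_nodes, " nodes, ", x$n_edges, " edges — ",
      if (x$valid) "valid DAG" else "INVALID", "\n", sep = "")
  if (length(x$orphans)) cat("Orphan nodes:", paste(x$orphans, collapse = ", "), "\n")
  if (length(x$cycle)) cat("Cycle through:", paste(x$cycle, collapse = ", "), "\n")
  invisible(x)
}

# Parents of each node, in the edge-list order (stable, schema-independent).
structure_parents <- function(edges, nodes) {
  setNames(lapply(nodes, function(v) edges$from[edges$to == v]), nodes)
}

topological_order <- function(edges, nodes) {
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = TRUE, vertices = nodes)
  names(igraph::topo_sort(g, mode = "out"))
}

#' Read / write a structure as an edge-list text file
#'
#' One `parent -> child` pair per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @param edges edge tibble (for writing).
#' @return `read_structure()` returns an edge tibble; `write_structure()`
#'   returns `path` invisibly.
#' @export
read_structure <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  parts <- strsplit(ln, "->", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) abort(paste0("malformed edge line: ", ln[bad][1]),
                      class = "planreviewr_parse_error")
  tibble::tibble(from = trimws(vapply(parts, `[[`, "", 1L)),
                 to   = trimws(vapply(parts, `[[`, "", 2L)))
}

#' @rdname read_structure
#' @export
write_structure <- function(edges, path) {
  writeLines(paste(edges$from, "->", edges$to), path)
  invisible(path)
}
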