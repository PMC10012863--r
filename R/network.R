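# The discrete Bayesian network container: DAG structure plus one CPT per
# node. CPTs are matrices with one row per parent-state combination (first
# parent varying fastest) and one column per node state.

CPT_TOL <- 1e-9

#' Construct a Bayesian network
#'
#' Bundles a DAG, conditional probability tables and a variable schema into a
#' fitted-model-like object. Every CPT row must be a probability vector
#' (non-negative, summing to one within `1e-9`) and CPT parent lists must
#' match the structure exactly.
#'
#' @param edges edge tibble (`from`, `to`); see [default_structure()].
#' @param cpts named list, one entry per node: a list with elements `parents`
#'   (character) and `prob` (matrix, `prod(parent cardinalities)` rows in
#'   mixed-radix order with the first parent varying fastest, one column per
#'   node state).
#' @param schema schema tibble giving each node's ordered states.
#' @return An object of class `rt_bn`.
#' @export
rt_network <- function(edges, cpts, schema) {
  validate_schema(schema)
  nodes <- schema$variable
  miss <- setdiff(structure_nodes(edges), nodes)
  if (length(miss)) abort(paste0("edges mention unknown nodes: ",
                                 paste(miss, collapse = ", ")),
                          class = "planreviewr_bn_error")
  validate_structure(edges, nodes = nodes, strict = TRUE)
  parents <- structure_parents(edges, nodes)
  states <- setNames(schema$states, nodes)
  for (v in nodes) {
    cp <- cpts[[v]]
    if (is.null(cp)) abort(paste0("missing CPT for node ", v),
                           class = "planreviewr_bn_error")
    if (!identical(sort(cp$parents), sort(parents[[v]]))) {
      abort(paste0("CPT parents for ", v, " do not match structure"),
            class = "planreviewr_bn_error")
    }
    q <- prod(vapply(cp$parents, function(p) length(states[[p]]), numeric(1)))
    r <- length(states[[v]])
    if (!is.matrix(cp$prob) || nrow(cp$prob) != q || ncol(cp$prob) != r) {
      abort(paste0("CPT for ", v, " must be ", q, " x ", r),
            class = "planreviewr_bn_error")
    }
    if (any(cp$prob < 0) || any(abs(rowSums(cp$prob) - 1) > CPT_TOL)) {
      abort(paste0("CPT rows for ", v, " are not normalized probability vectors"),
            class = "planreviewr_bn_error")
    }
  }
  obj <- list(nodes = nodes, edges = tibble::as_tibble(edges[, c("from", "to")]),
              parents = parents, states = states,
              cpts = cpts[nodes], schema = schema,
              cache = new.env(parent = emptyenv()))
  class(obj) <- "rt_bn"
  obj
}

node_card <- function(network, vars) {
  vapply(vars, function(v) length(network$states[[v]]), integer(1))
}

# linear row index into a CPT from 1-based parent state indices (matrix or
# vector, one column per parent in CPT order)
parent_combo_index <- function(network, node, parent_states) {
  ps <- network$cpts[[node]]$parents
  if (length(ps) == 0) return(rep.int(1L, NROW(parent_states)))
  m <- matrix(as.integer(parent_states), ncol = length(ps))
  card <- node_card(network, ps)
  stride <- cumprod(c(1L, card[-length(card)]))
  as.integer(1L + (m - 1L) %*% stride)
}

cpt_factor <- function(network, node) {
  cp <- network$cpts[[node]]
  vars <- c(node, cp$parents)
  card <- node_card(network, vars)
  new_factor(vars, card, as.vector(t(cp$prob)))
}

state_index <- function(network, var, label) {
  i <- match(label, network$states[[var]])
  if (any(is.na(i))) {
    abort(paste0("unknown state '", label[is.na(i)][1], "' for variable ", var),
          class = "planreviewr_bn_error")
  }
  i
}

#' Joint probability of a complete assignment
#'
#' The product, over all nodes, of the CPT entry selected by the assignment —
#' the Bayesian-network factorization of the joint distribution.
#'
#' @param network an `rt_bn`.
#' @param assignment named character vector mapping every node to a state.
#' @return A probability in \[0, 1\].
#' @export
joint_probability <- function(network, assignment) {
  miss <- setdiff(network$nodes, names(assignment))
  if (length(miss)) abort(paste0("assignment incomplete; missing: ",
                                 paste(miss, collapse = ", ")),
                          class = "planreviewr_bn_error")
  p <- 1
  for (v in network$nodes) {
    cp <- network$cpts[[v]]
    s <- state_index(network, v, assignment[[v]])
    row <- if (length(cp$parents)) {
      parent_combo_index(network, v,
                         vapply(cp$parents, function(pp)
                           state_index(network, pp, assignment[[pp]]), integer(1)))
    } else 1L
    p <- p * cp$prob[row, s]
  }
  p
}

#' @export
print.rt_bn <- function(x, ...) {
  cat("<rt_bn> discrete Bayesian network: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  np <- vapply(x$parents, length, integer(1))
  cat("  max parents:", max(np), " | total CPT cells:",
      sum(vapply(x$cpts, function(cp) length(cp$prob), numeric(1))), "\n")
  invisible(x)
}

#' Tidy a Bayesian network into its CPT entries
#'
#' @param x an `rt_bn`.
#' @param ... unused.
#' @return A tibble with one row per CPT cell: `node`, `parent_config`
#'   (comma-separated `parent=state` string, empty for root nodes), `state`,
#'   `prob`.
#' @method tidy rt_bn
#' @export
tidy.rt_bn <- function(x, ...) {
  rows <- lapply(x$nodes, function(v) {
    cp <- x$cpts[[v]]
    st <- x$states[[v]]
    q <- nrow(cp$prob)
    cfg <- if (length(cp$parents)) {
      grids <- expand.grid(lapply(cp$parents, function(p) x$states[[p]]),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      apply(grids, 1, function(r) paste(cp$parents, r, sep = "=", collapse = ","))
    } else rep("", q)
    tibble::tibble(node = v,
                   parent_config = rep(cfg, times = length(st)),
                   state = rep(st, each = q),
                   prob = as.vector(cp$prob))
  })
  dplyr::bind_rows(rows)
}

#' @rdname tidy.rt_bn
#' @return `glance()` returns a one-row tibble with node/edge counts, the
#'   number of free parameters and, when the network was fitted with
#'   [fit_bn()], the EM iteration count and final penalized log-likelihood.
#' @method glance rt_bn
#' @export
glance.rt_bn <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    n_parameters = sum(vapply(x$cpts, function(cp)
      nrow(cp$prob) * (ncol(cp$prob) - 1L), numeric(1))),
    em_iterations = x$fit$iterations %||% NA_integer_,
    log_lik = x$fit$log_lik %||% NA_real_,
    converged = x$fit$converged %||% NA
  )
}
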