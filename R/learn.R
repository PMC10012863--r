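# EM parameter learning with Laplace smoothing. The pseudocount for every CPT
# cell of node i is alpha_i = 1/q_i, the multiplicative inverse of the node's
# number of parent-state combinations, so the total prior weight per node stays
# bounded regardless of table size.
#
# The E-step exploits that records are observed everywhere except their missing
# set: conditional on the observed values, the posterior over the missing
# variables factorizes over connected components of the "shared family" graph,
# and each component's posterior is a product of the (evidence-sliced) CPT
# factors touching it. Components and their observation keys are independent of
# the parameters, so they are precomputed once and memoized across records and
# iterations.

#' Fit the network CPTs by expectation-maximization
#'
#' Learns one CPT per node from (possibly incomplete) discretized plan records
#' by maximum penalized likelihood: EM with a per-cell Laplace pseudocount of
#' `1/q` (`q` = number of parent-state combinations of the node). On complete
#' data this converges in a single M-step to the closed form
#' `(N_ijk + 1/q_i) / (N_ij + r_i/q_i)`. Iteration stops when the relative
#' change of the penalized observed-data log-likelihood falls below
#' `convergence` or after `max_iter` iterations. The fit is deterministic:
#' initialization uses available-case counts, and no random restarts are
#' needed for this concave-per-step procedure.
#'
#' @param data plan records: a data frame with one row per plan and one
#'   character column per network variable (`NA` = missing). Extra columns
#'   (`plan_id`, `clinic`, ...) are ignored; variables absent from the data
#'   are treated as entirely missing.
#' @param structure edge tibble; defaults to [default_structure()].
#' @param schema schema tibble; defaults to [default_schema()].
#' @param convergence relative log-likelihood change tolerance (default
#'   `1e-4`).
#' @param max_iter iteration cap (default 200).
#' @return An [rt_network()] object whose `fit` element records `iterations`,
#'   `log_lik` (final penalized observed-data log-likelihood), `log_lik_trace`
#'   and `converged`.
#' @export
#' @examples
#' plans <- sample_plans(default_profiles(divergence = 0)[[1]], n = 200, seed = 1)
#' net <- fit_bn(plans)
#' glance(net)
fit_bn <- function(data, structure = default_structure(),
                   schema = default_schema(),
                   convergence = 1e-4, max_iter = 200L) {
  stopifnot(convergence >= 0, max_iter >= 1)
  validate_schema(schema)
  nodes <- schema$variable
  parents <- structure_parents(structure, nodes)
  validate_structure(structure, nodes = nodes, strict = TRUE)
  states <- setNames(schema$states, nodes)
  card <- vapply(nodes, function(v) length(states[[v]]), integer(1))

  n <- nrow(data)
  M <- matrix(NA_integer_, nrow = n, ncol = length(nodes),
              dimnames = list(NULL, nodes))
  for (v in intersect(nodes, names(data))) {
    M[, v] <- match(as.character(data[[v]]), states[[v]])
  }

  q <- vapply(nodes, function(v) prod(card[parents[[v]]]), numeric(1))
  alpha <- 1 / q
  r <- card
  pstride <- lapply(nodes, function(v) {
    ps <- parents[[v]]
    if (!length(ps)) return(numeric(0))
    setNames(cumprod(c(1, unname(card[ps])[-length(ps)])), ps)
  })
  names(pstride) <- nodes

  # fixed tabulation over fully-observed families
  counts_obs <- setNames(vector("list", length(nodes)), nodes)
  fam_members <- setNames(lapply(nodes, function(v) c(v, parents[[v]])), nodes)
  for (v in nodes) {
    mem <- fam_members[[v]]
    obs <- rowSums(is.na(M[, mem, drop = FALSE])) == 0L
    cm <- matrix(0, nrow = q[[v]], ncol = r[[v]])
    if (any(obs)) {
      row_idx <- if (length(parents[[v]])) {
        1L + as.integer((M[obs, parents[[v]], drop = FALSE] - 1L) %*% pstride[[v]])
      } else rep.int(1L, sum(obs))
      lin <- row_idx + q[[v]] * (M[obs, v] - 1L)
      tab <- tabulate(lin, nbins = q[[v]] * r[[v]])
      cm[] <- tab
    }
    counts_obs[[v]] <- cm
  }

  groups <- build_estep_groups(M, nodes, fam_members)

  init_prob <- function() {
    setNames(lapply(nodes, function(v) {
      cm <- counts_obs[[v]] + alpha[[v]]
      cm / rowSums(cm)
    }), nodes)
  }
  prob <- init_prob()

  prior_term <- function(prob) {
    sum(vapply(nodes, function(v) alpha[[v]] * sum(log(prob[[v]])), numeric(1)))
  }

  ll_trace <- numeric(0)
  ll_prev <- NA_real_
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    counts <- lapply(counts_obs, identity)
    ll <- sum(vapply(nodes, function(v)
      sum(counts_obs[[v]][counts_obs[[v]] > 0] *
            log(prob[[v]][counts_obs[[v]] > 0])), numeric(1)))

    for (g in groups) {
      eg <- estep_group(g, prob, q, r, pstride)
      ll <- ll + g$mult * log(eg$z)
      for (j in seq_along(g$fams)) {
        v <- g$fams[[j]]
        add <- eg$cell_weights[[j]]
        counts[[v]][add$cells] <- counts[[v]][add$cells] + g$mult * add$w
      }
    }

    ll_pen <- ll + prior_term(prob)
    ll_trace <- c(ll_trace, ll_pen)

    # M-step
    prob <- setNames(lapply(nodes, function(v) {
      cm <- counts[[v]] + alpha[[v]]
      cm / rowSums(cm)
    }), nodes)

    if (!is.na(ll_prev)) {
      rel <- abs(ll_pen - ll_prev) / (abs(ll_prev) + 1e-12)
      if (rel < convergence) { converged <- TRUE; break }
    }
    if (it >= max_iter) break
    ll_prev <- ll_pen
  }

  cpts <- setNames(lapply(nodes, function(v)
    list(parents = parents[[v]], prob = prob[[v]])), nodes)
  net <- rt_network(structure, cpts, schema)
  net$fit <- list(iterations = it, log_lik = ll_trace[length(ll_trace)],
                  log_lik_trace = ll_trace, converged = converged,
                  n = n, convergence = convergence)
  net
}

# Precompute E-step work units: for every record with missing values, split
# the missing set into components linked through shared families, and group
# identical (component, touched-family observations) keys with multiplicity.
build_estep_groups <- function(M, nodes, fam_members) {
  n <- nrow(M)
  if (n == 0) return(list())
  miss_rows <- which(rowSums(is.na(M)) > 0L)
  env <- new.env(parent = emptyenv())
  node_pos <- setNames(seq_along(nodes), nodes)

  for (i in miss_rows) {
    row <- M[i, ]
    miss <- nodes[is.na(row)]
    # touched families and component linking
    touched <- nodes[vapply(nodes, function(v)
      any(fam_members[[v]] %in% miss), logical(1))]
    comp_id <- setNames(seq_along(miss), miss)
    for (v in touched) {
      mm <- intersect(fam_members[[v]], miss)
      if (length(mm) > 1L) {
        tgt <- min(comp_id[mm])
        comp_id[comp_id %in% comp_id[mm]] <- tgt
      }
    }
    for (cid in unique(comp_id)) {
      C <- miss[comp_id == cid]
      fams <- touched[vapply(touched, function(v)
        any(fam_members[[v]] %in% C), logical(1))]
      obs_vars <- setdiff(unique(unlist(fam_members[fams], use.names = FALSE)), C)
      key <- paste(paste(C, collapse = ","), "|",
                   paste(row[obs_vars], collapse = ","), "|",
                   paste(fams, collapse = ","))
      g <- env[[key]]
      if (is.null(g)) {
        env[[key]] <- list(C = C, fams = fams, obs = row[obs_vars], mult = 1L)
      } else {
        g$mult <- g$mult + 1L
        env[[key]] <- g
      }
    }
  }
  keys <- sort(ls(env))  # sorted for a reproducible summation order
  lapply(keys, function(k) env[[k]])
}

# Posterior over one component's missing variables and the resulting expected
# CPT cell weights for each touched family.
estep_group <- function(g, prob, q, r, pstride) {
  C <- g$C
  grid <- as.matrix(expand.grid(lapply(C, function(v) seq_len(r[[v]])),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- C
  ncmb <- nrow(grid)
  getv <- function(v) {
    if (v %in% C) grid[, v] else rep.int(g$obs[[v]], ncmb)
  }
  w <- rep.int(1, ncmb)
  fam_cells <- vector("list", length(g$fams))
  for (j in seq_along(g$fams)) {
    v <- g$fams[[j]]
    row_idx <- if (length(pstride[[v]])) {
      ps <- names(pstride[[v]])
      pm <- vapply(ps, getv, integer(ncmb))
      if (!is.matrix(pm)) pm <- matrix(pm, nrow = ncmb)
      1L + as.integer((pm - 1L) %*% unname(pstride[[v]]))
    } else rep.int(1L, ncmb)
    sv <- getv(v)
    w <- w * prob[[v]][cbind(row_idx, sv)]
    fam_cells[[j]] <- row_idx + q[[v]] * (sv - 1L)
  }
  z <- sum(w)
  post <- w / z
  cell_weights <- vector("list", length(g$fams))
  for (j in seq_along(g$fams)) {
    agg <- rowsum(post, group = fam_cells[[j]], reorder = FALSE)
    cell_weights[[j]] <- list(cells = as.integer(rownames(agg)), w = as.numeric(agg))
  }
  list(z = z, cell_weights = cell_weights)
}
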