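# Independent oracles used across the suite. All of these deliberately avoid
# the package's inference/learning/ROC code paths: joints are built by direct
# products over CPT entries, EM by enumerating record completions, AUC by
# counting concordant pairs.

`%||%` <- function(x, y) if (is.null(x)) y else x

# --- random small networks ---------------------------------------------

rand_small_schema <- function(n_nodes, max_states = 4, seed = 1) {
  withr::with_seed(seed, {
    nm <- paste0("v", seq_len(n_nodes))
    tibble::tibble(
      variable = nm,
      category = sample(c("diagnostic", "patient_setup", "treatment_planning",
                          "dose_prescription"), n_nodes, replace = TRUE),
      states = lapply(nm, function(v) {
        k <- sample(2:max_states, 1)
        paste0(v, "_s", seq_len(k))
      }),
      applicable = rep(list("all"), n_nodes))
  })
}

rand_small_network <- function(seed, n_nodes = NULL, max_states = 4,
                               p_edge = 0.45) {
  withr::with_seed(seed, {
    n_nodes <- n_nodes %||% sample(2:6, 1)
    schema <- rand_small_schema(n_nodes, max_states, seed = seed + 1)
    nm <- schema$variable
    edges <- expand.grid(from = nm, to = nm, stringsAsFactors = FALSE)
    edges <- edges[match(edges$from, nm) < match(edges$to, nm), ]  # DAG by order
    edges <- edges[runif(nrow(edges)) < p_edge, , drop = FALSE]
    parents <- lapply(nm, function(v) edges$from[edges$to == v])
    names(parents) <- nm
    card <- vapply(schema$states, length, integer(1))
    names(card) <- nm
    cpts <- lapply(nm, function(v) {
      q <- prod(card[parents[[v]]])
      r <- card[[v]]
      w <- matrix(stats::rgamma(q * r, shape = 1.2), nrow = q)
      list(parents = parents[[v]], prob = w / rowSums(w))
    })
    names(cpts) <- nm
    rt_network(tibble::as_tibble(edges), cpts, schema)
  })
}

# --- joint enumeration (independent of the package's inference) --------

enum_joint <- function(network) {
  grid <- expand.grid(network$states, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  names(grid) <- network$nodes
  p <- rep(1, nrow(grid))
  for (v in network$nodes) {
    cp <- network$cpts[[v]]
    si <- match(grid[[v]], network$states[[v]])
    row <- rep(1L, nrow(grid))
    if (length(cp$parents)) {
      stride <- 1L
      for (pp in cp$parents) {
        row <- row + (match(grid[[pp]], network$states[[pp]]) - 1L) * stride
        stride <- stride * length(network$states[[pp]])
      }
    }
    p <- p * cp$prob[cbind(row, si)]
  }
  grid$prob <- p
  grid
}

enum_marginal <- function(network, target, evidence = character(0)) {
  j <- enum_joint(network)
  keep <- rep(TRUE, nrow(j))
  for (v in names(evidence)) keep <- keep & j[[v]] == evidence[[v]]
  j <- j[keep, , drop = FALSE]
  agg <- tapply(j$prob, factor(j[[target]], levels = network$states[[target]]),
                sum, default = 0)
  as.numeric(agg) / sum(j$prob)
}

# --- counting / EM oracles ---------------------------------------------

# closed-form Laplace-smoothed frequency estimate on complete data
count_oracle_cpts <- function(data, network_like) {
  nodes <- network_like$nodes
  out <- list()
  for (v in nodes) {
    cp <- network_like$cpts[[v]]
    r <- length(network_like$states[[v]])
    q <- prod(vapply(cp$parents, function(p)
      length(network_like$states[[p]]), numeric(1)))
    alpha <- 1 / q
    cnt <- matrix(0, nrow = q, ncol = r)
    for (i in seq_len(nrow(data))) {
      si <- match(data[[v]][i], network_like$states[[v]])
      row <- 1L; stride <- 1L
      for (pp in cp$parents) {
        row <- row + (match(data[[pp]][i], network_like$states[[pp]]) - 1L) * stride
        stride <- stride * length(network_like$states[[pp]])
      }
      cnt[row, si] <- cnt[row, si] + 1
    }
    out[[v]] <- (cnt + alpha) / (rowSums(cnt) + r * alpha)
  }
  out
}

# EM by brute-force enumeration of all completions of each partial record;
# initialization mirrors the documented convention (available-case counts
# plus the 1/q pseudocount), so trajectories are comparable iteration by
# iteration.
brute_em <- function(data, network_like, n_iter) {
  nodes <- network_like$nodes
  states <- network_like$states
  parents <- lapply(nodes, function(v) network_like$cpts[[v]]$parents)
  names(parents) <- nodes
  card <- vapply(nodes, function(v) length(states[[v]]), integer(1))
  q <- vapply(nodes, function(v) prod(card[parents[[v]]]), numeric(1))
  alpha <- 1 / q

  row_of <- function(assign, v) {
    row <- 1L; stride <- 1L
    for (pp in parents[[v]]) {
      row <- row + (match(assign[[pp]], states[[pp]]) - 1L) * stride
      stride <- stride * card[[pp]]
    }
    row
  }

  # init: available-case counts + alpha
  prob <- list()
  for (v in nodes) {
    cnt <- matrix(0, nrow = q[[v]], ncol = card[[v]])
    fam <- c(v, parents[[v]])
    for (i in seq_len(nrow(data))) {
      vals <- lapply(fam, function(x) data[[x]][i])
      names(vals) <- fam
      if (any(vapply(vals, is.na, logical(1)))) next
      cnt[row_of(vals, v), match(vals[[v]], states[[v]])] <-
        cnt[row_of(vals, v), match(vals[[v]], states[[v]])] + 1
    }
    prob[[v]] <- (cnt + alpha[[v]]) / (rowSums(cnt) + card[[v]] * alpha[[v]])
  }

  joint_p <- function(assign) {
    p <- 1
    for (v in nodes) {
      p <- p * prob[[v]][row_of(assign, v), match(assign[[v]], states[[v]])]
    }
    p
  }

  for (iter in seq_len(n_iter)) {
    cnt <- lapply(nodes, function(v) matrix(0, nrow = q[[v]], ncol = card[[v]]))
    names(cnt) <- nodes
    for (i in seq_len(nrow(data))) {
      rowvals <- lapply(nodes, function(v) data[[v]][i])
      names(rowvals) <- nodes
      miss <- nodes[vapply(rowvals, is.na, logical(1))]
      completions <- if (length(miss)) {
        g <- expand.grid(states[miss], KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
        lapply(seq_len(nrow(g)), function(k) {
          a <- rowvals; a[miss] <- as.list(g[k, , drop = FALSE]); a
        })
      } else list(rowvals)
      w <- vapply(completions, joint_p, numeric(1))
      w <- w / sum(w)
      for (k in seq_along(completions)) {
        a <- completions[[k]]
        for (v in nodes) {
          rr <- row_of(a, v); ss <- match(a[[v]], states[[v]])
          cnt[[v]][rr, ss] <- cnt[[v]][rr, ss] + w[k]
        }
      }
    }
    for (v in nodes) {
      prob[[v]] <- (cnt[[v]] + alpha[[v]]) / (rowSums(cnt[[v]]) + card[[v]] * alpha[[v]])
    }
  }
  prob
}

# --- AUC pair-counting oracle ------------------------------------------

pair_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p < neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# fully deterministic two-node chain (all CPT entries 0 or 1)
two_state_deterministic_net <- function() {
  schema <- tibble::tibble(variable = c("a", "b"), category = "treatment_planning",
                           states = list(c("a1", "a2"), c("b1", "b2")),
                           applicable = list("all", "all"))
  rt_network(tibble::tibble(from = "a", to = "b"),
             list(a = list(parents = character(0), prob = matrix(c(1, 0), 1)),
                  b = list(parents = "a", prob = rbind(c(1, 0), c(0, 1)))),
             schema)
}

# total-variation distance between fitted and true CPT rows, restricted to
# parent configurations with at least `min_obs` observations in `plans`
row_tv_with_support <- function(fit, truth, plans, min_obs = 20) {
  tvs <- numeric(0)
  for (v in truth$nodes) {
    cp <- truth$cpts[[v]]
    q <- nrow(cp$prob)
    row <- rep(1L, nrow(plans)); stride <- 1L
    ok <- rep(TRUE, nrow(plans))
    for (pp in cp$parents) {
      idx <- match(plans[[pp]], truth$states[[pp]])
      ok <- ok & !is.na(idx)
      idx[is.na(idx)] <- 1L
      row <- row + (idx - 1L) * stride
      stride <- stride * length(truth$states[[pp]])
    }
    ok <- ok & !is.na(plans[[v]])
    cnt <- tabulate(row[ok], nbins = q)
    keep <- which(cnt >= min_obs)
    if (length(keep)) {
      tvs <- c(tvs, 0.5 * rowSums(abs(fit$cpts[[v]]$prob[keep, , drop = FALSE] -
                                        cp$prob[keep, , drop = FALSE])))
    }
  }
  tvs
}

# small fully-observed cohort sampled from a network (complete data)
sample_complete <- function(network, n, seed) {
  prof <- structure(list(clinic_id = "toy", ground_truth = network,
                         inapplicable = character(0), missingness = numeric(0),
                         size_hint = n),
                    class = "rt_clinic_profile")
  sample_plans(prof, n = n, seed = seed)
}
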