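# Fast path for all-but-target scoring. With evidence on every assigned
# variable, P(target | evidence) depends only on the CPT factors touching the
# target and any missing variables connected to it through shared families;
# fully observed families are constants that cancel in the normalization.
# This avoids a full variable-elimination run per (plan, target).

bn_index <- function(network) {
  idx <- network$cache[["__bn_index__"]]
  if (!is.null(idx)) return(idx)
  nodes <- network$nodes
  members <- setNames(lapply(nodes, function(v) c(v, network$cpts[[v]]$parents)),
                      nodes)
  fam_of_var <- setNames(lapply(nodes, function(x)
    nodes[vapply(members, function(m) x %in% m, logical(1))]), nodes)
  card <- setNames(vapply(nodes, function(v) length(network$states[[v]]), integer(1)),
                   nodes)
  pstride <- setNames(lapply(nodes, function(v) {
    ps <- network$cpts[[v]]$parents
    if (!length(ps)) return(setNames(numeric(0), character(0)))
    setNames(cumprod(c(1, unname(card[ps])[-length(ps)])), ps)
  }), nodes)
  idx <- list(members = members, fam_of_var = fam_of_var, card = card,
              pstride = pstride,
              has_zero = any(vapply(network$cpts, function(cp)
                any(cp$prob == 0), logical(1))))
  network$cache[["__bn_index__"]] <- idx
  idx
}

# families whose fully observed CPT entry is exactly zero for this record;
# evidence containing such a family has probability zero under the model
zero_observed_families <- function(network, idx, s) {
  out <- character(0)
  for (v in names(idx$members)) {
    mem <- idx$members[[v]]
    if (anyNA(s[mem])) next
    st <- idx$pstride[[v]]
    row <- if (length(st)) 1 + sum((s[names(st)] - 1) * st) else 1
    if (network$cpts[[v]]$prob[row, s[[v]]] == 0) out <- c(out, v)
  }
  out
}

# the unobserved component containing `target`: target plus missing variables
# reachable through shared CPT families
target_component <- function(target, missing, fam_of_var, members) {
  comp <- target
  repeat {
    fams <- unique(unlist(fam_of_var[comp], use.names = FALSE))
    touch <- unique(unlist(members[fams], use.names = FALSE))
    add <- setdiff(intersect(touch, missing), comp)
    if (length(add) == 0) break
    comp <- c(comp, add)
  }
  comp
}

# P(target | all observed values) for one encoded plan row; `s` is a named
# integer vector of state indices with NA for missing
fast_posterior <- function(network, idx, s, target, comp) {
  fams <- unique(unlist(idx$fam_of_var[comp], use.names = FALSE))
  if (length(comp) == 1L) {
    r <- idx$card[[target]]
    w <- rep.int(1, r)
    for (v in fams) {
      cp <- network$cpts[[v]]
      st <- idx$pstride[[v]]
      if (v == target) {
        row <- if (length(st)) 1 + sum((s[names(st)] - 1) * st) else 1
        w <- w * cp$prob[row, ]
      } else {
        # target is a parent of v; v itself and its other parents are observed
        base <- 1
        for (p in names(st)) {
          base <- base + (if (p == target) 0 else (s[[p]] - 1)) * st[[p]]
        }
        rows <- base + st[[target]] * (0:(r - 1))
        w <- w * cp$prob[cbind(rows, s[[v]])]
      }
    }
  } else {
    grid <- as.matrix(expand.grid(lapply(comp, function(v)
      seq_len(idx$card[[v]])), KEEP.OUT.ATTRS = FALSE))
    colnames(grid) <- comp
    ncmb <- nrow(grid)
    w <- rep.int(1, ncmb)
    for (v in fams) {
      cp <- network$cpts[[v]]
      st <- idx$pstride[[v]]
      row <- rep.int(1, ncmb)
      for (p in names(st)) {
        pv <- if (p %in% comp) grid[, p] else rep.int(s[[p]], ncmb)
        row <- row + (pv - 1) * st[[p]]
      }
      sv <- if (v %in% comp) grid[, v] else rep.int(s[[v]], ncmb)
      w <- w * cp$prob[cbind(row, sv)]
    }
    # marginalize onto the target dimension
    w <- as.numeric(rowsum(w, group = grid[, target], reorder = TRUE))
  }
  z <- sum(w)
  if (!is.finite(z) || z <= 0) return(NULL)
  w / z
}

scores_all_but_target <- function(network, plans, targets_all, diagnostic_set) {
  idx <- bn_index(network)
  nodes <- network$nodes
  n <- nrow(plans)
  S <- matrix(NA_integer_, nrow = n, ncol = length(nodes),
              dimnames = list(NULL, nodes))
  for (v in intersect(nodes, names(plans))) {
    S[, v] <- match(plans[[v]], network$states[[v]])
  }
  out_plan <- character(0); out_var <- character(0); out_state <- character(0)
  out_score <- numeric(0); out_nev <- integer(0); out_imp <- logical(0)
  out_clinic <- character(0)
  for (i in seq_len(n)) {
    s <- S[i, ]
    missing <- nodes[is.na(s)]
    assigned <- setdiff(nodes, missing)
    tgs <- intersect(targets_all, assigned)
    zero_fams <- if (idx$has_zero) zero_observed_families(network, idx, s) else character(0)
    for (tg in tgs) {
      comp <- target_component(tg, missing, idx$fam_of_var, idx$members)
      if (length(zero_fams) &&
          length(setdiff(zero_fams,
                         unique(unlist(idx$fam_of_var[comp], use.names = FALSE))))) {
        # a fully observed family outside the target's component is
        # impossible, so the evidence itself has zero probability
        p <- NULL
      } else p <- if (prod(idx$card[comp]) > 20000) {
        # large unobserved component: summing a full grid would be wasteful,
        # let variable elimination integrate the missing variables out
        ev_vars <- setdiff(assigned, tg)
        ev <- setNames(vapply(ev_vars, function(v)
          network$states[[v]][s[[v]]], character(1)), ev_vars)
        res <- cached_marginal(network, tg, ev)
        if (res$impossible) NULL else unname(res$p)
      } else {
        fast_posterior(network, idx, s, tg, comp)
      }
      if (is.null(p)) {
        sc <- .Machine$double.xmin; imp <- TRUE
      } else {
        sc <- p[s[[tg]]]; imp <- FALSE
      }
      out_plan <- c(out_plan, plans$plan_id[i])
      out_clinic <- c(out_clinic, plans$clinic[i])
      out_var <- c(out_var, tg)
      out_state <- c(out_state, network$states[[tg]][s[[tg]]])
      out_score <- c(out_score, sc)
      out_nev <- c(out_nev, length(assigned) - 1L)
      out_imp <- c(out_imp, imp)
    }
  }
  tibble::tibble(plan_id = out_plan, clinic = out_clinic, variable = out_var,
                 state = out_state, score = out_score, n_evidence = out_nev,
                 impossible = out_imp)
}
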