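# Exact inference by variable elimination, with evidence slicing and barren
# node pruning. The network is small (24 nodes) and its moralized treewidth
# modest, so exact inference is cheap and fully reproducible; no sampling is
# used anywhere in scoring.

#' Posterior marginal of a target variable
#'
#' Computes the exact conditional distribution `P(target | evidence)` by
#' variable elimination: barren nodes (those outside the ancestral closure of
#' target and evidence) are pruned, evidence is sliced into the CPT factors,
#' and remaining variables are summed out in a greedy smallest-factor order.
#'
#' @param network an `rt_bn`.
#' @param target the variable whose posterior is requested (must not be in the
#'   evidence).
#' @param evidence named character vector of observed `variable = state`
#'   pairs; may be empty.
#' @return Named numeric vector over the target's states, summing to 1.
#'   Evidence with probability zero under the model raises a condition of
#'   class `planreviewr_impossible_evidence`.
#' @export
#' @examples
#' net <- base_network()
#' marginal(net, "number_of_fractions",
#'          c(tumor_location = "lung", treatment_intent = "palliative"))
marginal <- function(network, target, evidence = character(0)) {
  if (target %in% names(evidence)) {
    abort("target must not be part of the evidence",
          class = "planreviewr_bn_error")
  }
  post <- posterior_joint(network, target, evidence)
  p <- post$val
  names(p) <- network$states[[target]]
  p
}

#' Probability of the evidence
#'
#' @inheritParams marginal
#' @return `P(evidence)` under the network, a probability in \[0, 1\].
#' @export
evidence_probability <- function(network, evidence) {
  if (length(evidence) == 0) return(1)
  f <- ve_run(network, character(0), evidence)
  f$val
}

# Joint posterior over a set of query variables. Returns a factor over
# `targets` (in the given order), normalized.
posterior_joint <- function(network, targets, evidence = character(0)) {
  f <- ve_run(network, targets, evidence)
  z <- sum(f$val)
  if (!is.finite(z) || z <= 0) {
    abort("evidence has zero probability under the model",
          class = "planreviewr_impossible_evidence")
  }
  f$val <- f$val / z
  if (length(targets)) f_permute(f, targets) else f
}

ve_run <- function(network, targets, evidence) {
  ev_vars <- names(evidence)
  bad <- setdiff(c(targets, ev_vars), network$nodes)
  if (length(bad)) abort(paste0("unknown variables: ", paste(bad, collapse = ", ")),
                         class = "planreviewr_bn_error")
  ev_idx <- if (length(evidence)) {
    setNames(vapply(ev_vars, function(v)
      state_index(network, v, evidence[[v]]), integer(1)), ev_vars)
  } else integer(0)

  relevant <- ancestral_closure(network, union(targets, ev_vars))
  factors <- lapply(relevant, function(v) {
    key <- paste0("__factor__", v)
    f <- network$cache[[key]]
    if (is.null(f)) {
      f <- cpt_factor(network, v)
      network$cache[[key]] <- f
    }
    for (e in intersect(f$vars, ev_vars)) f <- f_reduce(f, e, ev_idx[[e]])
    f
  })

  elim <- setdiff(relevant, union(targets, ev_vars))
  scalar <- 1
  while (length(elim)) {
    v <- pick_elim_var(factors, elim)
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod_f <- Reduce(f_product, factors[touch])
    newf <- f_sumout(prod_f, v)
    factors <- factors[!touch]
    if (length(newf$vars) == 0) scalar <- scalar * newf$val else factors <- c(factors, list(newf))
    elim <- setdiff(elim, v)
  }
  out <- new_factor(character(0), integer(0), scalar)
  for (f in factors) out <- f_product(out, f)
  out
}

# greedy: eliminate the variable whose combined factor is smallest
pick_elim_var <- function(factors, candidates) {
  if (length(candidates) == 1L) return(candidates)
  cost <- vapply(candidates, function(v) {
    card <- integer(0)
    for (f in factors) if (v %in% f$vars) card <- c(card, f$card[setdiff(f$vars, names(card))])
    prod(card[unique(names(card))]) %||% 1
  }, numeric(1))
  candidates[which.min(cost)]
}

# nodes whose CPTs can influence P(keep): keep plus all its ancestors.
# Barren descendants sum to one and are dropped.
ancestral_closure <- function(network, keep) {
  if (length(keep) == 0) return(network$nodes)
  seen <- character(0)
  frontier <- keep
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(network$parents[frontier],
                                      use.names = FALSE)), seen)
  }
  # preserve node order for reproducible factor ordering
  intersect(network$nodes, seen)
}
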