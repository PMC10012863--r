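# Anomaly scoring: each assigned, non-diagnostic plan variable is scored by
# the exact conditional marginal probability of its observed state under one
# of two evidence strategies, then mapped to a pass / alert / warning tier.

#' Tier a score against the alert and warning thresholds
#'
#' A score at or above the alert (anomaly) threshold passes; below it but at
#' or above the warning threshold it raises an alert (uncommon but mostly
#' correct); below the warning threshold it raises a warning (rarely seen in
#' clinical data). Thresholds are configuration, not truth: the local QA team
#' chooses them to trade false alerts against missed errors.
#'
#' @param score probability in \[0, 1\] (vectorised).
#' @param alert alert threshold (default 0.05).
#' @param warning warning threshold, `< alert` (default 0.01).
#' @return Character vector: `"pass"`, `"alert"` or `"warning"`.
#' @export
assign_tier <- function(score, alert = 0.05, warning = 0.01) {
  stopifnot(warning > 0, warning < alert, alert < 1)
  dplyr::case_when(score >= alert ~ "pass",
                   score >= warning ~ "alert",
                   TRUE ~ "warning")
}

build_evidence <- function(plan, target, strategy, diagnostic_set, vars) {
  assigned <- vars[!is.na(unlist(plan[vars], use.names = FALSE))]
  ev_vars <- if (strategy == "diagnostic_only") {
    intersect(diagnostic_set, assigned)  # shrink when diagnostics are missing
  } else {
    setdiff(assigned, target)
  }
  ev_vars <- setdiff(ev_vars, target)
  setNames(vapply(ev_vars, function(v) as.character(plan[[v]]), character(1)),
           ev_vars)
}

#' Score the variables of one or many plans
#'
#' For every assigned non-diagnostic variable of every plan, computes
#' `P(observed state | evidence)` under the chosen evidence strategy:
#' `"diagnostic_only"` instantiates only the (assigned) diagnostic variables
#' as evidence; `"all_but_target"` instantiates every other assigned variable.
#' Diagnostic variables themselves are never scored — they are taken as
#' confirmed upstream. Repeated evidence configurations are cached on the
#' network object, so scoring large cohorts under `diagnostic_only` costs one
#' exact inference per distinct diagnostic profile.
#'
#' @param network an [rt_network()].
#' @param plans cohort tibble (or a single plan row).
#' @param strategy `"all_but_target"` (default) or `"diagnostic_only"`.
#' @param alert,warning tier thresholds, see [assign_tier()].
#' @param diagnostic_set evidence variables treated as trusted; defaults to
#'   the schema's diagnostic category.
#' @return A tibble with one row per (plan, scored variable): `plan_id`,
#'   `clinic`, `variable`, `state`, `score`, `tier`, `strategy`,
#'   `n_evidence`, `impossible` (TRUE when the evidence had zero model
#'   probability and the score was floored — cannot happen for EM-fitted
#'   networks, which are strictly positive).
#' @export
score_cohort <- function(network, plans,
                         strategy = c("all_but_target", "diagnostic_only"),
                         alert = 0.05, warning = 0.01,
                         diagnostic_set = NULL) {
  strategy <- match.arg(strategy)
  diagnostic_set <- diagnostic_set %||% diagnostic_variables(network$schema)
  vars <- intersect(network$nodes, names(plans))
  targets_all <- setdiff(vars, diagnostic_set)
  if (strategy == "all_but_target") {
    out <- scores_all_but_target(network, plans, targets_all, diagnostic_set)
    out$tier <- if (nrow(out)) assign_tier(out$score, alert, warning) else character(0)
    out$strategy <- rep(strategy, nrow(out))
    return(out[c("plan_id", "clinic", "variable", "state", "score", "tier",
                 "strategy", "n_evidence", "impossible")])
  }
  n <- nrow(plans)
  P <- as.matrix(plans[vars])  # character matrix of observed states
  mode(P) <- "character"
  ev_all <- if (strategy == "diagnostic_only") intersect(diagnostic_set, vars) else vars
  o_plan <- character(0); o_clinic <- character(0); o_var <- character(0)
  o_state <- character(0); o_score <- numeric(0); o_nev <- integer(0)
  o_imp <- logical(0)
  for (i in seq_len(n)) {
    row <- P[i, ]
    assigned <- targets_all[!is.na(row[targets_all])]
    if (length(assigned) == 0) next
    for (tg in assigned) {
      ev_vars <- setdiff(ev_all[!is.na(row[ev_all])], tg)
      ev <- row[ev_vars]
      res <- cached_marginal(network, tg, ev)
      o_plan <- c(o_plan, plans$plan_id[i])
      o_clinic <- c(o_clinic, plans$clinic[i])
      o_var <- c(o_var, tg)
      o_state <- c(o_state, row[[tg]])
      o_score <- c(o_score, unname(res$p[row[[tg]]]))
      o_nev <- c(o_nev, length(ev))
      o_imp <- c(o_imp, res$impossible)
    }
  }
  out <- tibble::tibble(plan_id = o_plan, clinic = o_clinic, variable = o_var,
                        state = o_state, score = o_score,
                        n_evidence = o_nev, impossible = o_imp)
  out$tier <- if (nrow(out)) assign_tier(out$score, alert, warning) else character(0)
  out$strategy <- rep(strategy, nrow(out))
  out[c("plan_id", "clinic", "variable", "state", "score", "tier",
        "strategy", "n_evidence", "impossible")]
}

#' @rdname score_cohort
#' @param plan a single plan (one-row cohort tibble).
#' @export
score_plan <- function(network, plan, ...) {
  stopifnot(nrow(plan) == 1L)
  score_cohort(network, plan, ...)
}

#' @rdname score_cohort
#' @param target single variable to score.
#' @export
score_variable <- function(network, plan, target,
                           strategy = c("all_but_target", "diagnostic_only"),
                           alert = 0.05, warning = 0.01,
                           diagnostic_set = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(nrow(plan) == 1L)
  if (is.na(plan[[target]])) {
    abort(paste0("target '", target, "' is not assigned in this plan"),
          class = "planreviewr_detector_error")
  }
  diagnostic_set <- diagnostic_set %||% diagnostic_variables(network$schema)
  vars <- intersect(network$nodes, names(plan))
  ev <- build_evidence(plan, target, strategy, diagnostic_set, vars)
  res <- cached_marginal(network, target, ev)
  s <- unname(res$p[plan[[target]]])
  tibble::tibble(plan_id = plan$plan_id, clinic = plan$clinic,
                 variable = target, state = as.character(plan[[target]]),
                 score = s, tier = assign_tier(s, alert, warning),
                 strategy = strategy, n_evidence = length(ev),
                 evidence = list(ev), impossible = res$impossible)
}

cached_marginal <- function(network, target, evidence) {
  key <- paste0(target, "\r", paste(names(evidence), evidence,
                                    sep = "\x1f", collapse = "\x1e"))
  hit <- network$cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- tryCatch(
    list(p = marginal(network, target, evidence), impossible = FALSE),
    planreviewr_impossible_evidence = function(e) {
      p <- rep(.Machine$double.xmin, length(network$states[[target]]))
      names(p) <- network$states[[target]]
      list(p = p, impossible = TRUE)
    })
  network$cache[[key]] <- res
  res
}
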