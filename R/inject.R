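# Failure-mode error injection for the three classic categories: patient
# setup, treatment planning, dose prescription. All injected values stay
# inside the binned state vocabulary, and every record satisfies
# injected != original.

#' Default error catalogue
#'
#' The injectable failure modes per category: table angle off by one
#' 10-degree bin, erroneous bolus involvement, orientation and tolerance-table
#' swaps (setup); gantry/collimator rotated by 20-30 degrees, abnormal plan
#' complexity forcing MU/cGy or MU/degree to an extreme bin, and swaps of beam
#' energy, radiation type, beam count, SSD and wedge (planning); and three
#' fractionation-scheme approaches (prescription).
#'
#' @param schema schema tibble.
#' @return A tibble with columns `category`, `variable`, `transform`.
#' @export
error_catalog <- function(schema = default_schema()) {
  tibble::tribble(
    ~category, ~variable, ~transform,
    "setup", "table_angle", "shift_one_angle_bin",
    "setup", "bolus", "swap_state",
    "setup", "patient_orientation", "swap_state",
    "setup", "tolerance_table", "swap_state",
    "planning", "gantry_angle", "shift_angle_20_30",
    "planning", "collimator_angle", "shift_angle_20_30",
    "planning", "mu_per_cgy", "extreme_bin",
    "planning", "mu_per_degree", "extreme_bin",
    "planning", "beam_energy", "swap_state",
    "planning", "radiation_type", "swap_state",
    "planning", "number_of_beams", "swap_state",
    "planning", "ssd", "swap_state",
    "planning", "wedge", "swap_state",
    "prescription", "prescription", "fractionation_scheme"
  )
}

PRESCRIPTION_VARS <- c("ptv_dose", "number_of_fractions", "dose_per_fraction")

empty_records <- function() {
  tibble::tibble(plan_id = character(0), variable = character(0),
                 original = character(0), injected = character(0),
                 category = character(0), approach = integer(0))
}

#' Inject simulated errors into a test cohort
#'
#' Modifies exactly `round(rate * n)` plans. For each selected plan,
#' `errors_per_plan` error events are applied: a category is drawn by weight,
#' then a compatible failure mode uniformly within it (falling back to any
#' compatible mode, then to a replacement plan, if nothing applies — logged in
#' the attached report). Unmodified plans are returned bit-identical.
#' Prescription events may alter two variables; one record is emitted per
#' actually-changed (plan, variable) cell.
#'
#' @param test cohort tibble.
#' @param specs error catalogue tibble; see [error_catalog()].
#' @param rate fraction of plans receiving errors, in \[0, 1\] (default 0.05).
#' @param category_weights named non-negative weights for
#'   `setup`/`planning`/`prescription` (default uniform).
#' @param errors_per_plan error events per selected plan (default 1).
#' @param seed integer seed; identical inputs and seed give identical output.
#' @param schema,binning schema and binning tables (defaults derived from the
#'   cohort).
#' @return A list: `plans` (the modified cohort) and `records` (tibble
#'   `plan_id`, `variable`, `original`, `injected`, `category`, `approach`).
#' @export
inject_errors <- function(test, specs = NULL, rate = 0.05,
                          category_weights = c(setup = 1, planning = 1, prescription = 1),
                          errors_per_plan = 1L, seed = 1L,
                          schema = NULL, binning = NULL) {
  if (rate < 0 || rate > 1) abort("rate must be in [0, 1]",
                                  class = "planreviewr_injector_error")
  if (any(category_weights < 0) || sum(category_weights) <= 0) {
    abort("category weights must be >= 0 and not all zero",
          class = "planreviewr_injector_error")
  }
  schema <- plan_schema(test, schema)
  binning <- binning %||% default_binning(schema)
  specs <- specs %||% error_catalog(schema)
  n_mod <- round(rate * nrow(test))
  if (n_mod == 0) {
    return(list(plans = test, records = empty_records(),
                report = list(n_target = 0L, redrawn_plans = character(0))))
  }

  out <- test
  records <- list()
  redrawn <- character(0)
  with_seed(seed, {
    order_pool <- sample.int(nrow(test))
    pool_pos <- 1L
    chosen <- 0L
    while (chosen < n_mod && pool_pos <= length(order_pool)) {
      i <- order_pool[pool_pos]; pool_pos <- pool_pos + 1L
      plan <- out[i, ]
      plan_recs <- list()
      ok <- TRUE
      for (e in seq_len(errors_per_plan)) {
        res <- inject_one(plan, specs, category_weights, schema, binning)
        if (is.null(res)) { ok <- FALSE; break }
        plan <- res$plan
        plan_recs[[e]] <- res$records
      }
      if (!ok) {
        redrawn <- c(redrawn, out$plan_id[i])
        next
      }
      out[i, ] <- plan
      records <- c(records, plan_recs)
      chosen <- chosen + 1L
    }
  })
  if (chosen < n_mod) {
    warn(paste0("only ", chosen, " of ", n_mod, " plans could receive errors"))
  }
  recs <- if (length(records)) dplyr::bind_rows(records) else empty_records()
  list(plans = out, records = recs,
       report = list(n_target = n_mod, n_modified = chosen,
                     redrawn_plans = redrawn, seed = seed))
}

# one error event; NULL when no failure mode applies to this plan
inject_one <- function(plan, specs, category_weights, schema, binning) {
  cats <- names(category_weights)[category_weights > 0]
  w <- category_weights[cats]
  cat_drawn <- sample(cats, 1L, prob = w / sum(w))
  compatible <- function(sp) {
    if (sp$transform == "fractionation_scheme") {
      all(!is.na(plan[PRESCRIPTION_VARS])) &&
        all(vapply(PRESCRIPTION_VARS, function(v)
          is_applicable(schema, v, plan$clinic), logical(1)))
    } else {
      v <- sp$variable
      v %in% names(plan) && !is.na(plan[[v]]) &&
        is_applicable(schema, v, plan$clinic) &&
        length(schema_states(schema, v)) > 1L
    }
  }
  try_specs <- function(sub) {
    sub <- sub[vapply(seq_len(nrow(sub)), function(k)
      compatible(sub[k, ]), logical(1)), , drop = FALSE]
    while (nrow(sub) > 0) {
      k <- if (nrow(sub) == 1L) 1L else sample.int(nrow(sub), 1L)
      res <- apply_transform(plan, sub[k, ], schema, binning)
      if (!is.null(res)) return(res)
      sub <- sub[-k, , drop = FALSE]
    }
    NULL
  }
  res <- try_specs(specs[specs$category == cat_drawn, , drop = FALSE])
  if (is.null(res)) res <- try_specs(specs[specs$category != cat_drawn, , drop = FALSE])
  res
}

apply_transform <- function(plan, spec, schema, binning) {
  switch(spec$transform,
         shift_one_angle_bin = shift_angle(plan, spec, schema, exact_bins = 1L),
         shift_angle_20_30 = shift_angle(plan, spec, schema, binning = binning),
         swap_state = swap_state(plan, spec, schema),
         extreme_bin = extreme_bin(plan, spec, schema),
         fractionation_scheme = prescription_error(plan,
                                                   approach = sample.int(3L, 1L),
                                                   schema = schema, binning = binning),
         abort(paste0("unknown transform: ", spec$transform),
               class = "planreviewr_injector_error"))
}

make_record <- function(plan, variable, original, injected, category,
                        approach = NA_integer_) {
  tibble::tibble(plan_id = plan$plan_id, variable = variable,
                 original = original, injected = injected,
                 category = category, approach = as.integer(approach))
}

shift_angle <- function(plan, spec, schema, exact_bins = NULL, binning = NULL) {
  v <- spec$variable
  st <- schema_states(schema, v)
  i <- match(plan[[v]], st)
  n <- length(st)
  dir <- if (runif(1) < 0.5) -1L else 1L
  if (!is.null(exact_bins)) {
    j <- ((i - 1L + dir * exact_bins) %% n) + 1L  # wraparound at 360
  } else {
    rule <- binning_rule(binning, v)
    mid <- state_midpoint(rule, plan[[v]])
    off <- dir * runif(1, 20, 30)
    j <- match(bin_value((mid + off) %% 360, rule), st)
  }
  if (is.na(j) || j == i) return(NULL)
  rec <- make_record(plan, v, st[i], st[j], spec$category)
  plan[[v]] <- st[j]
  list(plan = plan, records = rec)
}

swap_state <- function(plan, spec, schema) {
  v <- spec$variable
  st <- schema_states(schema, v)
  others <- setdiff(st, plan[[v]])
  if (length(others) == 0) return(NULL)
  new <- if (length(others) == 1L) others else sample(others, 1L)
  rec <- make_record(plan, v, plan[[v]], new, spec$category)
  plan[[v]] <- new
  list(plan = plan, records = rec)
}

extreme_bin <- function(plan, spec, schema) {
  v <- spec$variable
  st <- schema_states(schema, v)
  i <- match(plan[[v]], st)
  extremes <- setdiff(c(1L, length(st)), i)
  if (length(extremes) == 0) return(NULL)
  j <- if (length(extremes) == 1L) extremes else sample(extremes, 1L)
  rec <- make_record(plan, v, st[i], st[j], spec$category)
  plan[[v]] <- st[j]
  list(plan = plan, records = rec)
}

#' Apply a single setup / planning / prescription error to one plan
#'
#' Single-plan versions of the injector's transforms, mainly useful for
#' inspecting the failure modes. `setup_error()` and `planning_error()`
#' require a spec row of the matching category; `prescription_error()` takes
#' the approach directly: (1) change dose per fraction and fraction number
#' jointly so the total (PTV) dose bin is preserved; (2) change PTV dose and
#' fraction number with dose per fraction stable; (3) change PTV dose and
#' dose per fraction with the fraction number stable.
#'
#' @param plan one-row cohort tibble.
#' @param spec one row of [error_catalog()].
#' @param approach 1, 2 or 3.
#' @param seed optional seed (otherwise uses the current RNG stream).
#' @param schema,binning schema and binning tables.
#' @return A list `plan` (modified row) and `records`, or `NULL` when the
#'   failure mode does not apply (caller re-draws).
#' @export
setup_error <- function(plan, spec, seed = NULL, schema = plan_schema(plan),
                        binning = default_binning(schema)) {
  stopifnot(spec$category == "setup")
  run <- function() apply_transform(plan, spec, schema, binning)
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @rdname setup_error
#' @export
planning_error <- function(plan, spec, seed = NULL, schema = plan_schema(plan),
                           binning = default_binning(schema)) {
  stopifnot(spec$category == "planning")
  run <- function() apply_transform(plan, spec, schema, binning)
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @rdname setup_error
#' @export
prescription_error <- function(plan, approach, seed = NULL,
                               schema = plan_schema(plan),
                               binning = default_binning(schema)) {
  stopifnot(approach %in% 1:3)
  run <- function() prescription_apply(plan, approach, schema, binning)
  if (is.null(seed)) run() else with_seed(seed, run())
}

prescription_apply <- function(plan, approach, schema, binning) {
  if (any(is.na(plan[PRESCRIPTION_VARS]))) return(NULL)
  dpf_rule <- binning_rule(binning, "dose_per_fraction")
  nfx_rule <- binning_rule(binning, "number_of_fractions")
  ptv_rule <- binning_rule(binning, "ptv_dose")
  dpf_st <- schema_states(schema, "dose_per_fraction")
  nfx_st <- schema_states(schema, "number_of_fractions")
  ptv_st <- schema_states(schema, "ptv_dose")
  cur <- list(dpf = plan$dose_per_fraction, nfx = plan$number_of_fractions,
              ptv = plan$ptv_dose)

  set_vals <- function(dpf, nfx, ptv) {
    recs <- list()
    if (dpf != cur$dpf) recs <- c(recs, list(make_record(plan, "dose_per_fraction",
                                                         cur$dpf, dpf, "prescription", approach)))
    if (nfx != cur$nfx) recs <- c(recs, list(make_record(plan, "number_of_fractions",
                                                         cur$nfx, nfx, "prescription", approach)))
    if (ptv != cur$ptv) recs <- c(recs, list(make_record(plan, "ptv_dose",
                                                         cur$ptv, ptv, "prescription", approach)))
    if (length(recs) == 0) return(NULL)
    plan$dose_per_fraction <- dpf
    plan$number_of_fractions <- nfx
    plan$ptv_dose <- ptv
    list(plan = plan, records = dplyr::bind_rows(recs))
  }

  if (approach == 1L) {
    # keep the total-dose (PTV) bin; alter the (dose/fx, n fx) combination
    cand <- expand.grid(dpf = dpf_st, nfx = nfx_st, stringsAsFactors = FALSE)
    cand <- cand[!(cand$dpf == cur$dpf & cand$nfx == cur$nfx), ]
    tot <- vapply(seq_len(nrow(cand)), function(k)
      state_midpoint(dpf_rule, cand$dpf[k]) * state_midpoint(nfx_rule, cand$nfx[k]),
      numeric(1))
    keep <- bin_value(tot, ptv_rule) == cur$ptv
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    k <- if (nrow(cand) == 1L) 1L else sample.int(nrow(cand), 1L)
    return(set_vals(cand$dpf[k], cand$nfx[k], cur$ptv))
  }
  # approaches 2 and 3: a different combination of the two altered variables,
  # third variable stable; draws are independent, so the altered prescription
  # is generally no longer arithmetically consistent
  if (approach == 2L) {
    nfx_new <- sample(setdiff(nfx_st, cur$nfx), 1L)
    ptv_new <- sample(setdiff(ptv_st, cur$ptv), 1L)
    return(set_vals(cur$dpf, nfx_new, ptv_new))
  }
  dpf_new <- sample(setdiff(dpf_st, cur$dpf), 1L)
  ptv_new <- sample(setdiff(ptv_st, cur$ptv), 1L)
  set_vals(dpf_new, cur$nfx, ptv_new)
}
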