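# Plan cohorts: CSV IO, train/test splitting, merging and summaries.
# A cohort is an ordinary tibble, one row per plan, with `plan_id`, `clinic`
# and one character column per schema variable (NA = missing); the schema
# travels along as the "rt_schema" attribute.

plan_schema <- function(plans, schema = NULL) {
  schema %||% attr(plans, "rt_schema") %||% default_schema()
}

set_plan_schema <- function(plans, schema) {
  attr(plans, "rt_schema") <- schema
  plans
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic fan-out of one user seed into per-stage seeds (kept < 2^31)
derive_seed <- function(seed, stage) {
  (as.double(seed %% 1000003L) * 8191 + stage * 127 + 1) %% 2147483647
}

#' Read a plan table from CSV
#'
#' Reads a comma-separated plan table (UTF-8, header row required, empty
#' string = missing) against a schema. Cells whose value is not in the
#' variable's state vocabulary are coerced to missing and counted; columns for
#' variables structurally inapplicable at a plan's clinic are dropped to
#' missing with a warning. Unknown columns are ignored (or rejected).
#'
#' @param path CSV file path.
#' @param schema schema tibble; defaults to [default_schema()].
#' @param unknown_columns `"ignore"` (default) or `"error"`.
#' @return A cohort tibble carrying the schema and a load report (see
#'   [load_report()]). Errors on a missing `plan_id` column, duplicated
#'   `plan_id`s or an empty table.
#' @export
read_plans <- function(path, schema = default_schema(),
                       unknown_columns = c("ignore", "error")) {
  unknown_columns <- match.arg(unknown_columns)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  if (nrow(raw) == 0) abort("empty plan table", class = "planreviewr_io_error")
  if (!"plan_id" %in% names(raw)) abort("missing plan_id column",
                                        class = "planreviewr_io_error")
  if (anyDuplicated(raw$plan_id)) abort("duplicate plan_ids",
                                        class = "planreviewr_io_error")
  if (!"clinic" %in% names(raw)) raw$clinic <- "unknown"
  unknown <- setdiff(names(raw), c("plan_id", "clinic", schema$variable))
  if (length(unknown) && unknown_columns == "error") {
    abort(paste0("unknown columns: ", paste(unknown, collapse = ", ")),
          class = "planreviewr_io_error")
  }
  out <- raw[c("plan_id", "clinic")]
  coercions <- 0L; structural <- 0L
  for (v in schema$variable) {
    col <- if (v %in% names(raw)) raw[[v]] else rep(NA_character_, nrow(raw))
    st <- schema_states(schema, v)
    bad <- !is.na(col) & !col %in% st
    coercions <- coercions + sum(bad)
    col[bad] <- NA_character_
    inapp <- !vapply(raw$clinic, function(cl) is_applicable(schema, v, cl), logical(1))
    n_drop <- sum(inapp & !is.na(col))
    if (n_drop > 0) {
      warn(paste0(n_drop, " value(s) of '", v,
                  "' dropped: variable not applicable at the plan's clinic"))
      structural <- structural + n_drop
      col[inapp] <- NA_character_
    }
    out[[v]] <- col
  }
  out <- tibble::as_tibble(out)
  out <- set_plan_schema(out, schema)
  attr(out, "load_report") <- list(
    path = path, n_plans = nrow(out),
    n_missing_cells = sum(is.na(as.matrix(out[schema$variable]))),
    n_coerced = coercions, n_structural_dropped = structural,
    unknown_columns = unknown)
  out
}

#' Load report of a cohort read with [read_plans()]
#'
#' @param plans cohort tibble.
#' @return A list: plan count, missing-cell count, number of out-of-vocabulary
#'   cells coerced to missing, structurally dropped values, ignored columns.
#' @export
load_report <- function(plans) attr(plans, "load_report")

#' Write a plan table to CSV
#'
#' @param plans cohort tibble.
#' @param path output path; missing values are written as empty strings.
#' @export
write_plans <- function(plans, path) {
  readr::write_csv(plans, path, na = "")
  invisible(path)
}

#' Split a cohort into training and test partitions
#'
#' Draws a reproducible train/test partition, stratified by clinic when the
#' cohort spans several clinics (each clinic contributes
#' `round(train_fraction * n_clinic)` training plans).
#'
#' @param plans cohort tibble.
#' @param train_fraction proportion of plans assigned to training, in (0, 1\];
#'   default 0.8.
#' @param seed integer seed; the same cohort, fraction and seed always yield
#'   the same partition.
#' @return A list with cohort tibbles `train` and `test` (disjoint, jointly
#'   exhaustive).
#' @export
split_cohort <- function(plans, train_fraction = 0.8, seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction > 1) {
    abort("train_fraction must be in (0, 1]", class = "planreviewr_io_error")
  }
  if (nrow(plans) == 0) abort("cohort is empty", class = "planreviewr_io_error")
  idx_train <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(plans)), plans$clinic), function(ix) {
      k <- round(train_fraction * length(ix))
      sort(ix[sample.int(length(ix), k)])
    }), use.names = FALSE)
  })
  sch <- plan_schema(plans)
  list(train = set_plan_schema(plans[sort(idx_train), , drop = FALSE], sch),
       test  = set_plan_schema(plans[setdiff(seq_len(nrow(plans)), idx_train), , drop = FALSE], sch))
}

#' Merge cohorts from several clinics
#'
#' Concatenates cohorts under a union schema: per variable, the merged state
#' list is the ordered union of the input state lists and the applicability
#' sets are united (`"all"` dominates). Conflicting variable categories are an
#' error. If plan ids collide across cohorts they are namespaced by clinic
#' (`clinic/plan_id`); otherwise ids are kept as-is.
#'
#' @param ... cohort tibbles (or a single list of them).
#' @return A merged cohort tibble carrying the union schema.
#' @export
merge_cohorts <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && !is.data.frame(dots[[1]])) {
    dots <- dots[[1]]
  }
  stopifnot(length(dots) >= 1)
  schemas <- lapply(dots, plan_schema)
  merged_schema <- schemas[[1]]
  for (sch in schemas[-1]) {
    for (i in seq_len(nrow(sch))) {
      v <- sch$variable[i]
      j <- match(v, merged_schema$variable)
      if (is.na(j)) {
        merged_schema <- dplyr::bind_rows(merged_schema, sch[i, ])
      } else {
        if (merged_schema$category[j] != sch$category[i]) {
          abort(paste0("conflicting category for variable ", v),
                class = "planreviewr_schema_error")
        }
        merged_schema$states[[j]] <- union(merged_schema$states[[j]], sch$states[[i]])
        a <- merged_schema$applicable[[j]]; b <- sch$applicable[[i]]
        merged_schema$applicable[[j]] <-
          if (identical(a, "all") || identical(b, "all")) "all" else union(a, b)
      }
    }
  }
  out <- dplyr::bind_rows(dots)
  if (anyDuplicated(out$plan_id)) {
    out$plan_id <- paste(out$clinic, out$plan_id, sep = "/")
    if (anyDuplicated(out$plan_id)) {
      abort("duplicate plan_ids within a clinic; cannot merge",
            class = "planreviewr_io_error")
    }
  }
  set_plan_schema(out, merged_schema)
}

#' Summarize a cohort
#'
#' @param plans cohort tibble.
#' @param schema schema tibble (defaults to the cohort's own).
#' @return A list of tibbles: `frequencies` (variable, state, n, freq over
#'   observed values), `missingness` (variable, n_missing, rate) and `clinics`
#'   (clinic, n).
#' @export
describe_cohort <- function(plans, schema = NULL) {
  schema <- plan_schema(plans, schema)
  vars <- intersect(schema$variable, names(plans))
  if (nrow(plans) == 0 || length(vars) == 0) {
    return(list(frequencies = tibble::tibble(variable = character(0),
                                             state = character(0),
                                             n = integer(0), freq = numeric(0)),
                missingness = tibble::tibble(variable = character(0),
                                             n_missing = integer(0), rate = numeric(0)),
                clinics = dplyr::count(plans, .data$clinic)))
  }
  long <- tidyr::pivot_longer(plans[c("plan_id", vars)], -"plan_id",
                              names_to = "variable", values_to = "state")
  freq <- long |>
    dplyr::filter(!is.na(.data$state)) |>
    dplyr::count(.data$variable, .data$state, name = "n") |>
    dplyr::group_by(.data$variable) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  missing <- long |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(n_missing = sum(is.na(.data$state)),
                     rate = mean(is.na(.data$state)), .groups = "drop")
  list(frequencies = freq, missingness = missing,
       clinics = dplyr::count(plans, .data$clinic))
}
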