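# Variable schema: the discrete plan variables, their state vocabularies,
# clinical category and per-clinic applicability.

RT_CATEGORIES <- c("diagnostic", "patient_setup", "treatment_planning", "dose_prescription")

# Reserved state label for raw values falling outside a binning rule's domain.
OUT_OF_RANGE <- "__out_of_range__"

angle_labels <- function(width = 10) {
  lo <- seq(0, 360 - width, by = width)
  sprintf("[%d,%d)", lo, lo + width)
}

interval_labels <- function(boundaries) {
  n <- length(boundaries) - 1L
  vapply(seq_len(n), function(i) {
    lo <- boundaries[i]; hi <- boundaries[i + 1L]
    if (is.infinite(hi)) sprintf(">=%g", lo) else sprintf("[%g,%g)", lo, hi)
  }, character(1))
}

#' Default plan-variable schema
#'
#' The 24 discrete variables reviewed during the initial plan check, grouped
#' into diagnostic, patient-setup, treatment-planning and dose-prescription
#' categories. Each variable carries an ordered state vocabulary (binned where
#' the raw quantity is numeric) and the set of clinics where it is applicable
#' (`"all"`, or an explicit clinic-id vector for variables that some clinics
#' cannot record, such as wedges on a wedge-free linac fleet).
#'
#' State vocabularies are deliberately overridable: replace the `states`
#' list-column (together with matching [default_binning()] rules) to match a
#' local clinic's vocabulary.
#'
#' @return A tibble with one row per variable and columns `variable`,
#'   `category`, `states` (list of character vectors) and `applicable`
#'   (list; `"all"` or clinic ids).
#' @export
#' @examples
#' default_schema()
default_schema <- function() {
  spec <- list(
    # diagnostic
    t_stage             = list("diagnostic", c("T1", "T2", "T3", "T4"), "all"),
    n_stage             = list("diagnostic", c("N0", "N1", "N2"), "all"),
    m_stage             = list("diagnostic", c("M0", "M1"), "all"),
    tumor_location      = list("diagnostic", c("breast", "lung", "prostate", "head_neck", "rectum", "brain"), "all"),
    treatment_intent    = list("diagnostic", c("curative", "palliative"), "all"),
    # patient setup
    bolus               = list("patient_setup", c("yes", "no"), c("clinic_A", "clinic_C")),
    patient_orientation = list("patient_setup", c("HFS", "HFP", "FFS"), "all"),
    table_angle         = list("patient_setup", angle_labels(), "all"),
    tolerance_table     = list("patient_setup", c("standard", "srs", "electron", "clinical"), c("clinic_B", "clinic_C")),
    # treatment planning
    laterality          = list("treatment_planning", c("left", "right", "midline"), "all"),
    treatment_technique = list("treatment_planning", c("VMAT", "IMRT", "3DCRT", "electrons"), "all"),
    image_guidance      = list("treatment_planning", c("CBCT", "planar_kV", "none"), "all"),
    beam_energy         = list("treatment_planning", c("6MV", "10MV", "15MV", "6FFF", "10FFF", "6MeV", "9MeV", "12MeV"), "all"),
    radiation_type      = list("treatment_planning", c("photon", "electron"), "all"),
    number_of_beams     = list("treatment_planning", c("1", "2", "3", "4", "5-6", "7-8", ">8"), "all"),
    ssd                 = list("treatment_planning", interval_labels(c(0, 80, 90, 95, 100, 105, Inf)), "all"),
    collimator_angle    = list("treatment_planning", angle_labels(), "all"),
    gantry_angle        = list("treatment_planning", angle_labels(), "all"),
    wedge               = list("treatment_planning", c("none", "physical", "dynamic"), c("clinic_B", "clinic_C")),
    mu_per_cgy          = list("treatment_planning", interval_labels(c(0, 1, 1.5, 2.5, 4, Inf)), "all"),
    mu_per_degree       = list("treatment_planning", interval_labels(c(0, 1, 2, 4, 8, Inf)), "all"),
    # dose prescription
    ptv_dose            = list("dose_prescription", interval_labels(c(seq(0, 8000, by = 500), Inf)), "all"),
    number_of_fractions = list("dose_prescription", c("1-5", "6-10", "11-15", "16-20", "21-25", "26-30", "31-35", "36-40", ">40"), "all"),
    dose_per_fraction   = list("dose_prescription", interval_labels(c(seq(0, 500, by = 50), Inf)), "all")
  )
  tibble::tibble(
    variable   = names(spec),
    category   = unname(vapply(spec, `[[`, character(1), 1L)),
    states     = unname(lapply(spec, `[[`, 2L)),
    applicable = unname(lapply(spec, `[[`, 3L))
  )
}

#' Diagnostic evidence variables
#'
#' The staging and intent variables taken as trusted evidence (confirmed
#' upstream of planning) and therefore never themselves scored: T, N and M
#' stage, anatomic tumor location and treatment intent.
#'
#' @param schema a schema tibble, see [default_schema()].
#' @return Character vector of variable names.
#' @export
diagnostic_variables <- function(schema = default_schema()) {
  schema$variable[schema$category == "diagnostic"]
}

validate_schema <- function(schema) {
  stopifnot(is.data.frame(schema),
            all(c("variable", "category", "states", "applicable") %in% names(schema)))
  if (anyDuplicated(schema$variable)) {
    abort("schema has duplicated variable names", class = "planreviewr_schema_error")
  }
  bad_cat <- setdiff(unique(schema$category), RT_CATEGORIES)
  if (length(bad_cat)) {
    abort(paste0("unknown categories: ", paste(bad_cat, collapse = ", ")),
          class = "planreviewr_schema_error")
  }
  for (i in seq_len(nrow(schema))) {
    st <- schema$states[[i]]
    if (length(st) < 2 || anyDuplicated(st)) {
      abort(paste0("variable '", schema$variable[i],
                   "' needs >= 2 unique states"),
            class = "planreviewr_schema_error")
    }
  }
  invisible(schema)
}

schema_states <- function(schema, variable) {
  i <- match(variable, schema$variable)
  if (is.na(i)) abort(paste0("unknown variable: ", variable),
                      class = "planreviewr_schema_error")
  schema$states[[i]]
}

#' Is a variable applicable at a clinic?
#'
#' Variables whose `applicable` entry is `"all"` apply everywhere; otherwise a
#' clinic must be listed explicitly. Structurally inapplicable variables are
#' kept missing in plan records and excluded from that clinic's evaluation.
#'
#' @param schema schema tibble.
#' @param variable variable name.
#' @param clinic clinic identifier.
#' @return Logical scalar.
#' @export
is_applicable <- function(schema, variable, clinic) {
  i <- match(variable, schema$variable)
  if (is.na(i)) return(FALSE)
  app <- schema$applicable[[i]]
  identical(app, "all") || clinic %in% app
}

# ---- binning -----------------------------------------------------------

#' Default binning rules
#'
#' Maps raw plan values onto the schema's state bins: angles in 10-degree bins
#' over \[0, 360); dose per fraction in 50 cGy bins up to 500 cGy with one open
#' top bin; PTV dose in 500 cGy bins; number of fractions in 5-fraction bands;
#' MU/cGy and MU/degree in fixed complexity bands; categorical variables pass
#' through unchanged. The 10-degree angle bins guarantee that a 10-degree table
#' shift, or a 20-30 degree gantry/collimator shift, always changes the state.
#'
#' @param schema schema tibble the rules must match.
#' @return A tibble with columns `variable`, `kind`
#'   (`"categorical_passthrough"` or `"numeric_interval"`), `boundaries`
#'   (list of increasing cut points, half-open lower-inclusive intervals),
#'   `labels` (list, one per interval) and `unit`.
#' @export
default_binning <- function(schema = default_schema()) {
  ang <- seq(0, 360, by = 10)
  num <- list(
    table_angle         = list(ang, "degree"),
    collimator_angle    = list(ang, "degree"),
    gantry_angle        = list(ang, "degree"),
    ssd                 = list(c(0, 80, 90, 95, 100, 105, Inf), "cm"),
    mu_per_cgy          = list(c(0, 1, 1.5, 2.5, 4, Inf), "MU/cGy"),
    mu_per_degree       = list(c(0, 1, 2, 4, 8, Inf), "MU/degree"),
    ptv_dose            = list(c(seq(0, 8000, by = 500), Inf), "cGy"),
    number_of_fractions = list(c(1, 6, 11, 16, 21, 26, 31, 36, 41, Inf), "fractions"),
    dose_per_fraction   = list(c(seq(0, 500, by = 50), Inf), "cGy")
  )
  rows <- lapply(schema$variable, function(v) {
    if (v %in% names(num)) {
      b <- num[[v]][[1]]
      tibble::tibble(variable = v, kind = "numeric_interval",
                     boundaries = list(b), labels = list(schema_states(schema, v)),
                     unit = num[[v]][[2]])
    } else {
      tibble::tibble(variable = v, kind = "categorical_passthrough",
                     boundaries = list(numeric(0)),
                     labels = list(schema_states(schema, v)), unit = NA_character_)
    }
  })
  out <- dplyr::bind_rows(rows)
  for (i in which(out$kind == "numeric_interval")) {
    stopifnot(length(out$boundaries[[i]]) == length(out$labels[[i]]) + 1L,
              !is.unsorted(out$boundaries[[i]], strictly = TRUE))
  }
  out
}

#' Bin a raw value into a state label
#'
#' Deterministic, total on the declared domain: intervals are half-open and
#' lower-inclusive, so e.g. a table angle of exactly 10 degrees falls in
#' `[10,20)`, never `[0,10)`. Values outside the covered domain map to the
#' reserved out-of-range label (never silently to missing).
#'
#' @param raw a raw numeric value (for `numeric_interval` rules) or a state
#'   label (for `categorical_passthrough`). Vectorised.
#' @param rule one row of a binning table, see [default_binning()].
#' @return Character vector of state labels.
#' @export
#' @examples
#' rules <- default_binning()
#' bin_value(c(0, 9.99, 10), rules[rules$variable == "table_angle", ])
bin_value <- function(raw, rule) {
  stopifnot(is.data.frame(rule), nrow(rule) == 1L)
  labels <- rule$labels[[1]]
  if (rule$kind == "categorical_passthrough") {
    out <- as.character(raw)
    out[!out %in% labels] <- OUT_OF_RANGE
    return(out)
  }
  b <- rule$boundaries[[1]]
  x <- suppressWarnings(as.numeric(raw))
  idx <- findInterval(x, b, rightmost.closed = FALSE, left.open = FALSE)
  out <- rep(OUT_OF_RANGE, length(x))
  ok <- !is.na(x) & idx >= 1L & idx <= length(labels)
  out[ok] <- labels[idx[ok]]
  out
}

# Representative raw value for a binned state: interval midpoint, with an
# open-top interval represented by its lower bound plus half the previous
# interval's width. Used by the prescription-error arithmetic.
state_midpoint <- function(rule, label) {
  stopifnot(rule$kind == "numeric_interval")
  b <- rule$boundaries[[1]]
  labels <- rule$labels[[1]]
  i <- match(label, labels)
  if (is.na(i)) return(NA_real_)
  lo <- b[i]; hi <- b[i + 1L]
  if (is.infinite(hi)) {
    w <- if (i > 1) b[i] - b[i - 1L] else 1
    lo + w / 2
  } else {
    (lo + hi) / 2
  }
}

# ---- YAML serialization -----------------------------------------------

#' Read / write schema and binning configuration as YAML
#'
#' The on-disk form mirrors the tibbles: one entry per variable with
#' `category`, `states`, `applicable` (and for binning rules `kind`,
#' `boundaries`, `labels`, `unit`). `Inf` boundaries are written as the
#' string `".inf"` understood by YAML.
#'
#' @param path YAML file path.
#' @param schema,binning tibbles to serialize.
#' @return Readers return the corresponding tibble; writers return `path`
#'   invisibly.
#' @export
write_schema_yaml <- function(schema, path, binning = NULL) {
  obj <- list(variables = lapply(seq_len(nrow(schema)), function(i) list(
    variable = schema$variable[i], category = schema$category[i],
    states = as.list(schema$states[[i]]),
    applicable = as.list(schema$applicable[[i]]))))
  if (!is.null(binning)) {
    obj$binning <- lapply(seq_len(nrow(binning)), function(i) list(
      variable = binning$variable[i], kind = binning$kind[i],
      boundaries = as.list(binning$boundaries[[i]]),
      labels = as.list(binning$labels[[i]]), unit = binning$unit[i]))
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_schema_yaml
#' @export
read_schema_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  schema <- tibble::tibble(
    variable = vapply(obj$variables, `[[`, character(1), "variable"),
    category = vapply(obj$variables, `[[`, character(1), "category"),
    states = lapply(obj$variables, function(x) as.character(unlist(x$states))),
    applicable = lapply(obj$variables, function(x) as.character(unlist(x$applicable))))
  validate_schema(schema)
  if (is.null(obj$binning)) return(schema)
  binning <- tibble::tibble(
    variable = vapply(obj$binning, `[[`, character(1), "variable"),
    kind = vapply(obj$binning, `[[`, character(1), "kind"),
    boundaries = lapply(obj$binning, function(x) as.numeric(unlist(x$boundaries))),
    labels = lapply(obj$binning, function(x) as.character(unlist(x$labels))),
    unit = vapply(obj$binning, function(x) x$unit %||% NA_character_, character(1)))
  list(schema = schema, binning = binning)
}

binning_rule <- function(binning, variable) {
  r <- binning[binning$variable == variable, , drop = FALSE]
  if (nrow(r) != 1L) abort(paste0("no binning rule for ", variable),
                           class = "planreviewr_schema_error")
  r
}
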