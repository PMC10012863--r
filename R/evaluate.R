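# Evaluation harness: detection instances, ROC/AUC by threshold sweep, and
# the four multi-site experiment designs (single-site, cross-site,
# two-train-one-test, pooled).

#' Label detection instances with injection ground truth
#'
#' Joins per-(plan, variable) scores with injection records: an instance is
#' positive when that exact cell was injected. Diagnostic variables are never
#' present (they are never scored). Records referring to cells that were not
#' scored (e.g. a variable made missing after injection) are counted in the
#' `unmatched_records` attribute rather than silently dropped.
#'
#' @param scores tibble from [score_cohort()].
#' @param records tibble from [inject_errors()].
#' @return Instances tibble: `plan_id`, `clinic`, `variable`, `score`, `label`.
#' @export
collect_instances <- function(scores, records) {
  key <- function(d) paste(d$plan_id, d$variable, sep = "\r")
  inj <- unique(key(records))
  out <- tibble::tibble(plan_id = scores$plan_id, clinic = scores$clinic,
                        variable = scores$variable, score = scores$score,
                        label = as.integer(key(scores) %in% inj))
  attr(out, "unmatched_records") <- setdiff(inj, key(scores))
  out
}

#' ROC curve and AUC of an instance list
#'
#' Lower marginal probability means more anomalous, so an instance is flagged
#' positive when its score falls at or below the threshold. The curve sweeps
#' every distinct score; the AUC is the trapezoidal area, which equals the
#' Mann-Whitney statistic on negated scores with ties counted one half.
#'
#' @param instances tibble with `score` and `label` columns (1 = injected).
#' @return An `rt_roc`: `points` (threshold, sensitivity, specificity),
#'   `auc`, `n_pos`, `n_neg`. Errors if only one class is present.
#' @export
roc_curve <- function(instances) {
  lab <- instances$label
  sc <- instances$score
  n_pos <- sum(lab == 1); n_neg <- sum(lab == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC undefined: need at least one positive and one negative instance",
          class = "planreviewr_eval_error")
  }
  thr <- sort(unique(sc))
  tp <- vapply(thr, function(t) sum(sc <= t & lab == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(sc <= t & lab == 0), numeric(1))
  sens <- tp / n_pos
  fpr <- fp / n_neg
  pts <- tibble::tibble(threshold = c(-Inf, thr),
                        sensitivity = c(0, sens),
                        specificity = c(1, 1 - fpr))
  x <- c(0, fpr); y <- c(0, sens)
  if (x[length(x)] < 1 || y[length(y)] < 1) { x <- c(x, 1); y <- c(y, 1) }
  auc <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "rt_roc")
}

#' @export
print.rt_roc <- function(x, ...) {
  cat("<rt_roc> AUC = ", format(x$auc, digits = 4), " (", x$n_pos,
      " positives, ", x$n_neg, " negatives)\n", sep = "")
  invisible(x)
}

#' @method tidy rt_roc
#' @export
tidy.rt_roc <- function(x, ...) x$points

#' @method glance rt_roc
#' @export
glance.rt_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

# AUC per variable plus a pooled overall row (pooled instances, not a mean of
# per-variable AUCs)
auc_table <- function(instances) {
  per_var <- instances |>
    dplyr::group_by(.data$variable) |>
    dplyr::group_modify(function(d, g) {
      if (sum(d$label == 1) == 0 || sum(d$label == 0) == 0) {
        return(tibble::tibble(auc = NA_real_, n_pos = sum(d$label == 1),
                              n_neg = sum(d$label == 0)))
      }
      glance(roc_curve(d))
    }) |>
    dplyr::ungroup()
  overall <- glance(roc_curve(instances))
  dplyr::bind_rows(per_var,
                   tibble::tibble(variable = "overall", auc = overall$auc,
                                  n_pos = overall$n_pos, n_neg = overall$n_neg))
}

#' Experiment configuration
#'
#' Bundles and validates the knobs of one multi-site experiment. Setups
#' mirror the four designs: `single_site` (train = test, one clinic),
#' `cross_site` (train on some clinics, test on disjoint others),
#' `two_train_one_test` (two training clinics, one held-out) and `pooled`
#' (train and test everywhere).
#'
#' @param setup one of the four designs.
#' @param train_clinics,test_clinics clinic id vectors (defaults follow the
#'   setup over `clinics`).
#' @param clinics the full clinic roster used to build profiles.
#' @param strategy evidence strategy for scoring.
#' @param n_per_clinic plans sampled per clinic.
#' @param divergence clinic CPT divergence, see [build_profiles()].
#' @param rate injected-error rate on each test partition.
#' @param train_fraction train split fraction.
#' @param seed master seed; all stage seeds derive from it.
#' @param alert,warning tier thresholds.
#' @param convergence,max_iter EM controls.
#' @return A validated config list of class `rt_experiment_config`.
#' @export
experiment_config <- function(setup = c("single_site", "cross_site",
                                        "two_train_one_test", "pooled"),
                              train_clinics = NULL, test_clinics = NULL,
                              clinics = c("clinic_A", "clinic_B", "clinic_C"),
                              strategy = c("all_but_target", "diagnostic_only"),
                              n_per_clinic = 2000L, divergence = 1.5,
                              rate = 0.05, train_fraction = 0.8, seed = 1L,
                              alert = 0.05, warning = 0.01,
                              convergence = 1e-4, max_iter = 200L) {
  setup <- match.arg(setup)
  strategy <- match.arg(strategy)
  train_clinics <- train_clinics %||% switch(setup,
    single_site = clinics[1], cross_site = clinics[1],
    two_train_one_test = clinics[1:2], pooled = clinics)
  test_clinics <- test_clinics %||% switch(setup,
    single_site = train_clinics, cross_site = setdiff(clinics, train_clinics),
    two_train_one_test = setdiff(clinics, train_clinics), pooled = clinics)
  ok <- switch(setup,
    single_site = length(train_clinics) == 1 && identical(train_clinics, test_clinics),
    cross_site = length(intersect(train_clinics, test_clinics)) == 0 &&
      length(train_clinics) >= 1 && length(test_clinics) >= 1,
    two_train_one_test = length(train_clinics) == 2 && length(test_clinics) == 1 &&
      length(intersect(train_clinics, test_clinics)) == 0,
    pooled = setequal(train_clinics, clinics) && setequal(test_clinics, clinics))
  if (!ok) abort(paste0("clinic lists inconsistent with setup '", setup, "'"),
                 class = "planreviewr_eval_error")
  if (!all(c(train_clinics, test_clinics) %in% clinics)) {
    abort("train/test clinics must be drawn from `clinics`",
          class = "planreviewr_eval_error")
  }
  structure(list(setup = setup, train_clinics = train_clinics,
                 test_clinics = test_clinics, clinics = clinics,
                 strategy = strategy, n_per_clinic = n_per_clinic,
                 divergence = divergence, rate = rate,
                 train_fraction = train_fraction, seed = seed,
                 alert = alert, warning = warning,
                 convergence = convergence, max_iter = max_iter),
            class = "rt_experiment_config")
}

# generate cohorts, fit the network, inject errors; shared by both strategies
prepare_experiment <- function(config, profiles = NULL) {
  cfg <- config
  profiles <- profiles %||% build_profiles(
    base_network(), clinic_ids = cfg$clinics, divergence = cfg$divergence,
    seed = derive_seed(cfg$seed, 1L))
  names(profiles) <- vapply(profiles, `[[`, character(1), "clinic_id")
  used <- union(cfg$train_clinics, cfg$test_clinics)
  splits <- lapply(used, function(cl) {
    i <- match(cl, cfg$clinics)
    plans <- sample_plans(profiles[[cl]], n = cfg$n_per_clinic,
                          seed = derive_seed(cfg$seed, 10L + i))
    split_cohort(plans, train_fraction = cfg$train_fraction,
                 seed = derive_seed(cfg$seed, 20L + i))
  })
  names(splits) <- used
  train <- merge_cohorts(lapply(cfg$train_clinics, function(cl) splits[[cl]]$train))
  net <- fit_bn(train, convergence = cfg$convergence, max_iter = cfg$max_iter)
  tests <- lapply(cfg$test_clinics, function(cl) {
    i <- match(cl, cfg$clinics)
    inject_errors(splits[[cl]]$test, rate = cfg$rate,
                  seed = derive_seed(cfg$seed, 30L + i))
  })
  names(tests) <- cfg$test_clinics
  manifest <- list(
    config = unclass(cfg),
    seeds = list(profiles = derive_seed(cfg$seed, 1L),
                 sampling = setNames(lapply(used, function(cl)
                   derive_seed(cfg$seed, 10L + match(cl, cfg$clinics))), used),
                 split = setNames(lapply(used, function(cl)
                   derive_seed(cfg$seed, 20L + match(cl, cfg$clinics))), used),
                 injection = setNames(lapply(cfg$test_clinics, function(cl)
                   derive_seed(cfg$seed, 30L + match(cl, cfg$clinics))), cfg$test_clinics)),
    n_train = nrow(train),
    package_version = as.character(utils::packageVersion("planreviewr")))
  list(net = net, tests = tests, manifest = manifest)
}

evaluate_prepared <- function(prep, cfg, strategy) {
  insts <- lapply(names(prep$tests), function(cl) {
    tst <- prep$tests[[cl]]
    scores <- score_cohort(prep$net, tst$plans, strategy = strategy,
                           alert = cfg$alert, warning = cfg$warning)
    collect_instances(scores, tst$records)
  })
  names(insts) <- names(prep$tests)
  res <- lapply(names(insts), function(cl) {
    tab <- auc_table(insts[[cl]])
    tab$test_clinic <- cl
    tab
  })
  if (length(insts) > 1) {
    # the multi-clinic designs report one overall figure over the pooled
    # test instances of all test clinics
    tab <- auc_table(dplyr::bind_rows(insts))
    tab$test_clinic <- "all"
    res <- c(res, list(tab))
  }
  out <- dplyr::bind_rows(res)
  out$strategy <- strategy
  out[, c("test_clinic", "strategy", "variable", "auc", "n_pos", "n_neg")]
}

#' Run one multi-site experiment end to end
#'
#' Pipeline: build clinic profiles, sample a cohort per clinic, split each
#' clinic 80/20, pool the training partitions of the training clinics, fit
#' the network by EM, inject errors into each test clinic's test partition,
#' score under the configured evidence strategy, and compute per-variable and
#' pooled-overall AUC per test clinic. Every stage draws its seed from
#' `config$seed`, and the result carries a manifest of all of them.
#'
#' @param config an [experiment_config()].
#' @return An `rt_experiment`: `results` tibble (`test_clinic`, `strategy`,
#'   `variable` — including an `"overall"` row —, `auc`, `n_pos`, `n_neg`),
#'   `config` and `manifest`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "rt_experiment_config"))
  prep <- prepare_experiment(config)
  results <- evaluate_prepared(prep, config, config$strategy)
  structure(list(results = results, config = config, manifest = prep$manifest),
            class = "rt_experiment")
}

#' Compare the two evidence strategies on identical data
#'
#' Generates one set of cohorts, one fitted network and one injection per the
#' config, then scores it under both `diagnostic_only` and `all_but_target`,
#' so the strategy contrast is not confounded by sampling.
#'
#' @param config an [experiment_config()].
#' @return An `rt_experiment` whose `results` contains both strategies, plus
#'   a `delta` tibble of per-variable AUC differences
#'   (all_but_target - diagnostic_only).
#' @export
compare_strategies <- function(config) {
  stopifnot(inherits(config, "rt_experiment_config"))
  prep <- prepare_experiment(config)
  res <- dplyr::bind_rows(
    evaluate_prepared(prep, config, "diagnostic_only"),
    evaluate_prepared(prep, config, "all_but_target"))
  delta <- res |>
    dplyr::select("test_clinic", "strategy", "variable", "auc") |>
    tidyr::pivot_wider(names_from = "strategy", values_from = "auc") |>
    dplyr::mutate(delta = .data$all_but_target - .data$diagnostic_only)
  structure(list(results = res, delta = delta, config = config,
                 manifest = prep$manifest),
            class = "rt_experiment")
}

#' @export
print.rt_experiment <- function(x, ...) {
  cat("<rt_experiment> setup =", x$config$setup, "\n")
  ov <- dplyr::filter(x$results, .data$variable == "overall")
  print(as.data.frame(ov), row.names = FALSE)
  invisible(x)
}

#' Run the full multi-site validation protocol
#'
#' Orchestrates every experiment design over one shared preparation: clinic
#' profiles are built once, one cohort is sampled and split per clinic, one
#' error injection is applied to each clinic's test partition, and one
#' network is fitted per training set (each single clinic, each two-clinic
#' pool for `two_train_one_test`, and the full pool). Each fitted network is
#' then evaluated on the appropriate test partitions under the requested
#' evidence strategies. Sharing the preparation makes the design and strategy
#' contrasts paired rather than confounded by sampling, and avoids refitting
#' identical networks.
#'
#' @param seed master seed.
#' @param clinics clinic roster.
#' @param n_per_clinic plans sampled per clinic.
#' @param divergence clinic divergence, see [build_profiles()].
#' @param rate injected-error rate.
#' @param train_fraction per-clinic split fraction.
#' @param strategies evidence strategies to evaluate.
#' @param designs subset of
#'   `c("single_site", "cross_site", "two_train_one_test", "pooled")`.
#' @param alert,warning tier thresholds.
#' @param convergence,max_iter EM controls.
#' @return A tibble with one row per (design, train set, test clinic,
#'   strategy, variable): columns `design`, `train_clinics`
#'   (`+`-separated), `test_clinic` (a clinic id, or `"all"` for the pooled
#'   instance set of a multi-clinic design), `strategy`, `variable`
#'   (including `"overall"`), `auc`, `n_pos`, `n_neg`, `seed`.
#' @export
run_study <- function(seed = 1L, clinics = c("clinic_A", "clinic_B", "clinic_C"),
                      n_per_clinic = 2000L, divergence = 1.5, rate = 0.05,
                      train_fraction = 0.8,
                      strategies = c("diagnostic_only", "all_but_target"),
                      designs = c("single_site", "cross_site", "pooled"),
                      alert = 0.05, warning = 0.01,
                      convergence = 1e-4, max_iter = 200L) {
  designs <- match.arg(designs, c("single_site", "cross_site",
                                  "two_train_one_test", "pooled"),
                       several.ok = TRUE)
  profiles <- build_profiles(base_network(), clinic_ids = clinics,
                             divergence = divergence,
                             seed = derive_seed(seed, 1L))
  names(profiles) <- clinics
  splits <- lapply(seq_along(clinics), function(i) {
    plans <- sample_plans(profiles[[i]], n = n_per_clinic,
                          seed = derive_seed(seed, 10L + i))
    split_cohort(plans, train_fraction = train_fraction,
                 seed = derive_seed(seed, 20L + i))
  })
  names(splits) <- clinics
  tests <- lapply(seq_along(clinics), function(i) {
    inject_errors(splits[[clinics[i]]]$test, rate = rate,
                  seed = derive_seed(seed, 30L + i))
  })
  names(tests) <- clinics

  fit_on <- function(cls) {
    fit_bn(merge_cohorts(lapply(cls, function(cl) splits[[cl]]$train)),
           convergence = convergence, max_iter = max_iter)
  }
  nets <- list()
  need_single <- any(c("single_site", "cross_site") %in% designs)
  if (need_single) for (cl in clinics) nets[[cl]] <- fit_on(cl)
  if ("pooled" %in% designs) nets[["__pooled__"]] <- fit_on(clinics)
  if ("two_train_one_test" %in% designs) {
    for (hold in clinics) {
      nets[[paste0("__not_", hold)]] <- fit_on(setdiff(clinics, hold))
    }
  }

  eval_net <- function(net, test_cls, design, train_lab) {
    out <- list()
    for (st in strategies) {
      insts <- lapply(test_cls, function(cl) {
        sc <- score_cohort(net, tests[[cl]]$plans, strategy = st,
                           alert = alert, warning = warning)
        collect_instances(sc, tests[[cl]]$records)
      })
      names(insts) <- test_cls
      for (cl in test_cls) {
        tab <- auc_table(insts[[cl]])
        tab$test_clinic <- cl
        tab$strategy <- st
        out[[length(out) + 1L]] <- tab
      }
      if (length(test_cls) > 1) {
        tab <- auc_table(dplyr::bind_rows(insts))
        tab$test_clinic <- "all"
        tab$strategy <- st
        out[[length(out) + 1L]] <- tab
      }
    }
    res <- dplyr::bind_rows(out)
    res$design <- design
    res$train_clinics <- train_lab
    res
  }

  rows <- list()
  if ("single_site" %in% designs) {
    for (cl in clinics) {
      rows[[length(rows) + 1L]] <- eval_net(nets[[cl]], cl, "single_site", cl)
    }
  }
  if ("cross_site" %in% designs) {
    for (cl in clinics) {
      rows[[length(rows) + 1L]] <- eval_net(nets[[cl]], setdiff(clinics, cl),
                                            "cross_site", cl)
    }
  }
  if ("two_train_one_test" %in% designs) {
    for (hold in clinics) {
      rows[[length(rows) + 1L]] <- eval_net(nets[[paste0("__not_", hold)]], hold,
                                            "two_train_one_test",
                                            paste(setdiff(clinics, hold),
                                                  collapse = "+"))
    }
  }
  if ("pooled" %in% designs) {
    rows[[length(rows) + 1L]] <- eval_net(nets[["__pooled__"]], clinics,
                                          "pooled",
                                          paste(clinics, collapse = "+"))
  }
  out <- dplyr::bind_rows(rows)
  out$seed <- seed
  out[, c("design", "train_clinics", "test_clinic", "strategy", "variable",
          "auc", "n_pos", "n_neg", "seed")]
}

#' Read an experiment configuration from YAML
#'
#' The YAML keys are the arguments of [experiment_config()].
#'
#' @param path YAML file path.
#' @return An `rt_experiment_config`.
#' @export
read_experiment_config <- function(path) {
  obj <- yaml::read_yaml(path)
  keep <- intersect(names(obj), names(formals(experiment_config)))
  obj <- obj[keep]
  for (k in intersect(names(obj), c("train_clinics", "test_clinics", "clinics"))) {
    obj[[k]] <- as.character(unlist(obj[[k]]))
  }
  do.call(experiment_config, obj)
}

#' @method tidy rt_experiment
#' @export
tidy.rt_experiment <- function(x, ...) x$results

#' @method glance rt_experiment
#' @export
glance.rt_experiment <- function(x, ...) {
  ov <- dplyr::filter(x$results, .data$variable == "overall")
  dplyr::select(ov, "test_clinic", "strategy", overall_auc = "auc",
                "n_pos", "n_neg")
}
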