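mini_cohort <- function(n, clinic = "clinic_C", seed = 3) {
  prof <- build_profiles(base_network(), clinic_ids = clinic, divergence = 0,
                         missingness = numeric(0))[[1]]
  sample_plans(prof, n = n, seed = seed)
}

test_that("instances carry labels only where injections happened", {
  plans <- mini_cohort(60)
  net <- fit_bn(plans)
  sc <- score_cohort(net, plans, strategy = "all_but_target")
  inst0 <- collect_instances(sc, planreviewr:::empty_records())
  expect_true(all(inst0$label == 0))
  expect_length(intersect(inst0$variable, diagnostic_variables()), 0L)

  # single-variable failure modes only: one positive instance per injected plan
  cat1 <- error_catalog()
  cat1 <- cat1[cat1$transform == "swap_state", ]
  inj <- inject_errors(plans, specs = cat1, rate = 0.5, seed = 5,
                       category_weights = c(setup = 1, planning = 1, prescription = 0))
  sc1 <- score_cohort(net, inj$plans, strategy = "all_but_target")
  inst1 <- collect_instances(sc1, inj$records)
  expect_equal(sum(inst1$label), 30L)
  expect_length(attr(inst1, "unmatched_records"), 0L)

  # instance scores are the detector scores, row for row
  expect_identical(inst1$score, sc1$score)
})

test_that("ROC handles perfect separation, all-ties and single-class input", {
  perfect <- tibble::tibble(score = c(rep(0.001, 5), rep(0.9, 20)),
                            label = c(rep(1, 5), rep(0, 20)))
  expect_equal(roc_curve(perfect)$auc, 1)
  ties <- tibble::tibble(score = rep(0.4, 30), label = rep(c(1, 0), 15))
  expect_equal(roc_curve(ties)$auc, 0.5)
  expect_error(roc_curve(tibble::tibble(score = 1:3 / 10, label = c(1, 1, 1))),
               class = "planreviewr_eval_error")
})

test_that("trapezoidal AUC equals the pair-counting oracle (and pROC) on random lists", {
  withr::with_seed(77, {
    for (k in 1:12) {
      n <- sample(10:80, 1)
      sc <- round(runif(n), sample(c(1, 2, 3), 1))  # induce ties
      lb <- rbinom(n, 1, 0.3)
      if (sum(lb) == 0) lb[1] <- 1
      if (sum(lb) == n) lb[n] <- 0
      inst <- tibble::tibble(score = sc, label = lb)
      got <- roc_curve(inst)$auc
      expect_equal(got, pair_auc(sc, lb), tolerance = 1e-12)
      ref <- suppressMessages(pROC::auc(pROC::roc(lb, sc, direction = ">",
                                                  quiet = TRUE)))
      expect_equal(got, as.numeric(ref), tolerance = 1e-12)
    }
  })
  # ten hand-listed instances against explicit pair counting
  hand <- tibble::tibble(score = c(.01, .2, .2, .5, .9, .05, .2, .6, .7, .8),
                         label = c(1, 1, 0, 0, 0, 1, 1, 0, 0, 0))
  expect_equal(roc_curve(hand)$auc, pair_auc(hand$score, hand$label))
})

test_that("sensitivity is monotone along the threshold sweep", {
  withr::with_seed(5, {
    inst <- tibble::tibble(score = runif(60), label = rbinom(60, 1, 0.4))
  })
  pts <- tidy(roc_curve(inst))
  expect_true(all(diff(pts$sensitivity) >= 0))
  expect_true(all(diff(pts$specificity) <= 0))
})

test_that("experiment configs enforce setup-consistent clinic lists", {
  expect_error(experiment_config("single_site", train_clinics = "clinic_A",
                                 test_clinics = "clinic_B"),
               class = "planreviewr_eval_error")
  expect_error(experiment_config("cross_site", train_clinics = "clinic_A",
                                 test_clinics = c("clinic_A", "clinic_B")),
               class = "planreviewr_eval_error")
  expect_error(experiment_config("two_train_one_test",
                                 train_clinics = "clinic_A",
                                 test_clinics = "clinic_B"),
               class = "planreviewr_eval_error")
  cfg <- experiment_config("cross_site", train_clinics = "clinic_A")
  expect_setequal(cfg$test_clinics, c("clinic_B", "clinic_C"))
})

small_cfg <- function(...) {
  experiment_config(..., n_per_clinic = 300L, seed = 11)
}

test_that("a single-site run trains on the 80% split and tests on the rest", {
  cfg <- small_cfg("single_site", train_clinics = "clinic_A",
                   test_clinics = "clinic_A")
  res <- run_experiment(cfg)
  expect_s3_class(res, "rt_experiment")
  expect_equal(res$manifest$n_train, 240L)  # 0.8 * 300
  ov <- dplyr::filter(tidy(res), variable == "overall")
  expect_equal(ov$test_clinic, "clinic_A")
  expect_equal(ov$n_pos + ov$n_neg, nrow_scored <- ov$n_pos + ov$n_neg)
  expect_true(ov$auc >= 0 && ov$auc <= 1)
})

test_that("cross-site runs report one result block per test clinic plus a pooled row", {
  cfg <- small_cfg("cross_site", train_clinics = "clinic_A",
                   test_clinics = c("clinic_B", "clinic_C"))
  res <- run_experiment(cfg)
  ov <- dplyr::filter(tidy(res), variable == "overall")
  expect_setequal(ov$test_clinic, c("clinic_B", "clinic_C", "all"))
})

test_that("identical configs yield bit-identical results and manifests", {
  cfg <- small_cfg("single_site", train_clinics = "clinic_B",
                   test_clinics = "clinic_B")
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$results, r2$results)
  expect_identical(jsonlite::toJSON(r1$manifest, auto_unbox = TRUE, digits = NA),
                   jsonlite::toJSON(r2$manifest, auto_unbox = TRUE, digits = NA))
})

test_that("strategy comparison reuses the same cohorts and reports paired deltas", {
  cfg <- small_cfg("single_site", train_clinics = "clinic_C",
                   test_clinics = "clinic_C")
  cmp <- compare_strategies(cfg)
  expect_setequal(unique(cmp$results$strategy),
                  c("diagnostic_only", "all_but_target"))
  expect_true(all(c("diagnostic_only", "all_but_target", "delta") %in%
                    names(cmp$delta)))
  # both strategies saw identical instances: positives match exactly
  ov <- dplyr::filter(cmp$results, variable == "overall")
  expect_equal(ov$n_pos[1], ov$n_pos[2])
  expect_equal(ov$n_neg[1], ov$n_neg[2])
})

test_that("variables d-separated from the non-diagnostic evidence have zero strategy delta", {
  # site (diagnostic) -> fx; an isolated other variable cannot change the score
  schema <- tibble::tibble(
    variable = c("site", "fx", "other"),
    category = c("diagnostic", "dose_prescription", "treatment_planning"),
    states = list(c("lung", "breast"), c("few", "many"), c("u", "v")),
    applicable = list("all", "all", "all"))
  net <- rt_network(tibble::tibble(from = "site", to = "fx"),
                    list(site = list(parents = character(0), prob = matrix(c(.6, .4), 1)),
                         fx = list(parents = "site", prob = rbind(c(.7, .3), c(.1, .9))),
                         other = list(parents = character(0), prob = matrix(c(.5, .5), 1))),
                    schema)
  plan <- tibble::tibble(plan_id = "p", clinic = "x", site = "lung",
                         fx = "few", other = "u")
  s_diag <- score_variable(net, plan, "fx", strategy = "diagnostic_only")$score
  s_all <- score_variable(net, plan, "fx", strategy = "all_but_target")$score
  expect_equal(s_diag, s_all, tolerance = 1e-12)
  expect_equal(s_diag, 0.7)
})
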