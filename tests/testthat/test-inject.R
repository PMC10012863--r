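clean_cohort <- function(n, clinic = "clinic_C", seed = 17) {
  prof <- build_profiles(base_network(), clinic_ids = clinic, divergence = 0,
                         missingness = numeric(0))[[1]]
  sample_plans(prof, n = n, seed = seed)
}

test_that("the injector modifies exactly round(rate * n) plans and nothing else", {
  test <- clean_cohort(400)
  inj <- inject_errors(test, rate = 0.05, seed = 4)
  changed <- unique(inj$records$plan_id)
  expect_length(changed, 20L)  # round(0.05 * 400)
  # unmodified plans are bit-identical
  untouched <- setdiff(test$plan_id, changed)
  expect_identical(as.data.frame(inj$plans[match(untouched, inj$plans$plan_id), ]),
                   as.data.frame(test[match(untouched, test$plan_id), ]))
  # re-reading the output cohort at (plan, variable) yields the injected state
  for (k in seq_len(nrow(inj$records))) {
    r <- inj$records[k, ]
    expect_identical(inj$plans[[r$variable]][inj$plans$plan_id == r$plan_id],
                     r$injected)
    expect_false(r$injected == r$original)
  }
})

test_that("rate zero is the identity and equal seeds reproduce records exactly", {
  test <- clean_cohort(120)
  inj0 <- inject_errors(test, rate = 0, seed = 1)
  expect_identical(as.data.frame(inj0$plans), as.data.frame(test))
  expect_equal(nrow(inj0$records), 0L)
  i1 <- inject_errors(test, rate = 0.1, seed = 42)
  i2 <- inject_errors(test, rate = 0.1, seed = 42)
  expect_identical(i1$records, i2$records)
  expect_identical(as.data.frame(i1$plans), as.data.frame(i2$plans))
})

test_that("all injected states live in the schema vocabulary", {
  test <- clean_cohort(300, seed = 23)
  schema <- default_schema()
  inj <- inject_errors(test, rate = 0.2, seed = 5)
  for (k in seq_len(nrow(inj$records))) {
    r <- inj$records[k, ]
    expect_true(r$injected %in% planreviewr:::schema_states(schema, r$variable))
  }
})

test_that("setup errors move the table angle exactly one bin with wraparound and toggle bolus", {
  plan <- clean_cohort(1)[1, ]
  cat <- error_catalog()
  ta_spec <- cat[cat$variable == "table_angle", ]
  plan$table_angle <- "[0,10)"
  hits <- vapply(1:30, function(s) {
    setup_error(plan, ta_spec, seed = s)$records$injected
  }, character(1))
  expect_true(all(hits %in% c("[10,20)", "[350,360)")))
  expect_setequal(unique(hits), c("[10,20)", "[350,360)"))

  b_spec <- cat[cat$variable == "bolus", ]
  plan$bolus <- "yes"
  expect_equal(setup_error(plan, b_spec, seed = 1)$records$injected, "no")
})

test_that("planning errors shift gantry by 20-30 degrees and force complexity extremes", {
  plan <- clean_cohort(1)[1, ]
  cat <- error_catalog()
  g_spec <- cat[cat$variable == "gantry_angle", ]
  plan$gantry_angle <- "[0,10)"
  for (s in 1:20) {
    res <- planning_error(plan, g_spec, seed = s)
    i <- match(res$records$injected, planreviewr:::angle_labels())
    # 20-30 degrees from the bin midpoint lands 2-3 bins away (mod 36)
    d <- min(abs(i - 1), 36 - abs(i - 1))
    expect_true(d %in% 2:3)
  }
  mu_spec <- cat[cat$variable == "mu_per_degree", ]
  plan$mu_per_degree <- "[2,4)"  # middle bin
  inj <- vapply(1:20, function(s)
    planning_error(plan, mu_spec, seed = s)$records$injected, character(1))
  expect_true(all(inj %in% c("[0,1)", ">=8")))

  be_spec <- cat[cat$variable == "beam_energy", ]
  plan$beam_energy <- "6MV"
  swaps <- vapply(1:40, function(s)
    planning_error(plan, be_spec, seed = s)$records$injected, character(1))
  expect_false(any(swaps == "6MV"))
  expect_gt(length(unique(swaps)), 3)  # spread over the remaining states
})

test_that("the three prescription approaches respect their stability contracts", {
  plan <- clean_cohort(1)[1, ]
  plan$dose_per_fraction <- "[200,250)"   # ~200 cGy
  plan$number_of_fractions <- "26-30"     # ~28 fx
  plan$ptv_dose <- "[6000,6500)"          # consistent total
  rules <- default_binning()
  ptv_rule <- rules[rules$variable == "ptv_dose", ]
  dpf_rule <- rules[rules$variable == "dose_per_fraction", ]
  nfx_rule <- rules[rules$variable == "number_of_fractions", ]

  for (s in 1:10) {
    r1 <- prescription_error(plan, approach = 1, seed = s)
    expect_identical(r1$plan$ptv_dose, plan$ptv_dose)  # total-dose bin preserved
    tot <- planreviewr:::state_midpoint(dpf_rule, r1$plan$dose_per_fraction) *
      planreviewr:::state_midpoint(nfx_rule, r1$plan$number_of_fractions)
    expect_identical(bin_value(tot, ptv_rule), plan$ptv_dose)
    expect_false(identical(r1$plan$dose_per_fraction, plan$dose_per_fraction) &&
                   identical(r1$plan$number_of_fractions, plan$number_of_fractions))

    r2 <- prescription_error(plan, approach = 2, seed = s)
    expect_identical(r2$plan$dose_per_fraction, plan$dose_per_fraction)
    expect_false(identical(r2$plan$number_of_fractions, plan$number_of_fractions))

    r3 <- prescription_error(plan, approach = 3, seed = s)
    expect_identical(r3$plan$number_of_fractions, plan$number_of_fractions)
    expect_false(identical(r3$plan$dose_per_fraction, plan$dose_per_fraction))
  }
})

test_that("category frequencies follow the configured weights (chi-square, alpha = 0.01)", {
  test <- clean_cohort(2000, seed = 31)
  inj <- inject_errors(test, rate = 1, seed = 77,
                       category_weights = c(setup = 2, planning = 1, prescription = 1))
  per_plan <- inj$records |>
    dplyr::group_by(plan_id) |>
    dplyr::summarise(category = category[1], .groups = "drop")
  obs <- table(factor(per_plan$category,
                      levels = c("setup", "planning", "prescription")))
  gof <- suppressWarnings(stats::chisq.test(obs, p = c(2, 1, 1) / 4))
  expect_gt(gof$p.value, 0.01)
})

test_that("plans lacking a compatible variable trigger spec redraw rather than failure", {
  test <- clean_cohort(40, seed = 3)
  # strip the prescription variables so only setup/planning specs can apply
  test$ptv_dose <- NA_character_
  inj <- inject_errors(test, rate = 0.5, seed = 6,
                       category_weights = c(setup = 0, planning = 0, prescription = 1))
  # prescription impossible everywhere -> falls back to other categories
  expect_equal(length(unique(inj$records$plan_id)), 20L)
  expect_true(all(inj$records$category %in% c("setup", "planning")))
})
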