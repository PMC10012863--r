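make_cohort_csv <- function(df, path = withr::local_tempfile(fileext = ".csv",
                                                             .local_envir = parent.frame())) {
  readr::write_csv(df, path, na = "")
  path
}

small_cohort <- function(n = 6, clinic = "clinic_C", seed = 11) {
  prof <- build_profiles(base_network(), clinic_ids = clinic, divergence = 0,
                         missingness = numeric(0))[[1]]
  sample_plans(prof, n = n, seed = seed)
}

test_that("a clean CSV round-trips with no missing cells", {
  plans <- small_cohort(3)
  p <- make_cohort_csv(plans)
  back <- read_plans(p)
  expect_equal(nrow(back), 3L)
  rep <- load_report(back)
  expect_equal(rep$n_missing_cells, 0L)
  expect_equal(rep$n_coerced, 0L)
  attr(back, "load_report") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(plans))
})

test_that("out-of-vocabulary cells become missing and are counted", {
  plans <- small_cohort(3)
  plans$beam_energy[2] <- "PhotonX"
  back <- read_plans(make_cohort_csv(plans))
  expect_true(is.na(back$beam_energy[2]))
  expect_equal(load_report(back)$n_coerced, 1L)
})

test_that("values for structurally inapplicable variables are dropped with a warning", {
  plans <- small_cohort(3, clinic = "clinic_C")
  plans$clinic <- "clinic_A"  # wedge / tolerance_table not recorded there
  w <- capture_warnings(back <- read_plans(make_cohort_csv(plans)))
  expect_true(all(grepl("not applicable", w)))
  expect_length(w, 2L)  # wedge and tolerance_table both dropped
  expect_true(all(is.na(back$wedge)))
  expect_gt(load_report(back)$n_structural_dropped, 0L)
})

test_that("malformed plan tables are rejected", {
  plans <- small_cohort(3)
  expect_error(read_plans(make_cohort_csv(plans[, -1])),
               class = "planreviewr_io_error")  # no plan_id
  dup <- plans; dup$plan_id <- "same"
  expect_error(read_plans(make_cohort_csv(dup)), class = "planreviewr_io_error")
  expect_error(read_plans(make_cohort_csv(plans[0, ])),
               class = "planreviewr_io_error")
})

test_that("the default split assigns 80% to training, reproducibly and disjointly", {
  plans <- small_cohort(1000, seed = 5)
  sp <- split_cohort(plans, train_fraction = 0.8, seed = 7)
  expect_equal(nrow(sp$train), 800L)
  expect_equal(nrow(sp$test), 200L)
  expect_length(intersect(sp$train$plan_id, sp$test$plan_id), 0L)
  sp2 <- split_cohort(plans, train_fraction = 0.8, seed = 7)
  expect_identical(sp$train$plan_id, sp2$train$plan_id)
  all_in <- split_cohort(plans, train_fraction = 1, seed = 1)
  expect_equal(nrow(all_in$train), 1000L)
  expect_equal(nrow(all_in$test), 0L)
  expect_error(split_cohort(plans, train_fraction = 1.2),
               class = "planreviewr_io_error")
})

test_that("splits partition the cohort and stratify by clinic", {
  a <- small_cohort(300, clinic = "clinic_A", seed = 1)
  b <- small_cohort(100, clinic = "clinic_B", seed = 2)
  merged <- merge_cohorts(a, b)
  withr::with_seed(3, {
    for (k in 1:5) {
      f <- runif(1, 0.3, 0.95)
      sp <- split_cohort(merged, train_fraction = f, seed = k)
      expect_equal(nrow(sp$train) + nrow(sp$test), nrow(merged))
      expect_length(intersect(sp$train$plan_id, sp$test$plan_id), 0L)
      tr_a <- sum(sp$train$clinic == "clinic_A")
      expect_equal(tr_a, round(f * 300))
    }
  })
})

test_that("merging unions schemas and preserves counts and ids", {
  a <- small_cohort(100, clinic = "clinic_A", seed = 1)
  b <- small_cohort(50, clinic = "clinic_B", seed = 2)
  m <- merge_cohorts(a, b)
  expect_equal(nrow(m), 150L)
  expect_equal(anyDuplicated(m$plan_id), 0L)
  # filter-by-clinic recovers each input id set
  expect_setequal(m$plan_id[m$clinic == "clinic_A"], a$plan_id)
  expect_setequal(m$plan_id[m$clinic == "clinic_B"], b$plan_id)

  # state union across differing vocabularies
  sa <- attr(a, "rt_schema"); sb <- attr(b, "rt_schema")
  i <- match("beam_energy", sa$variable)
  sa$states[[i]] <- c("6MV", "10MV")
  sb$states[[match("beam_energy", sb$variable)]] <- c("6MV", "15MV")
  attr(a, "rt_schema") <- sa; attr(b, "rt_schema") <- sb
  m2 <- merge_cohorts(a, b)
  ms <- attr(m2, "rt_schema")
  expect_setequal(ms$states[[match("beam_energy", ms$variable)]],
                  c("6MV", "10MV", "15MV"))

  # conflicting categories are an error
  sb$category[match("beam_energy", sb$variable)] <- "patient_setup"
  attr(b, "rt_schema") <- sb
  expect_error(merge_cohorts(a, b), class = "planreviewr_schema_error")
})

test_that("identical-schema merge is plain concatenation with the schema unchanged", {
  a <- small_cohort(10, clinic = "clinic_A", seed = 1)
  b <- small_cohort(10, clinic = "clinic_B", seed = 2)
  m <- merge_cohorts(a, b)
  expect_equal(nrow(m), 20L)
  expect_equal(attr(m, "rt_schema")$states, attr(a, "rt_schema")$states)
})
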