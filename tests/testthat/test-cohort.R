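# Cohort selection cascade.

# 20 records spanning the decision grid: in/out of window, type, phases,
# status, site multiplicity
grid_records <- function() {
  specs <- list(
    list(1, "2016-05-31", "Interventional", "Phase 2", "Completed", 1),       # before window
    list(2, "2016-06-01", "Interventional", "Phase 2", "Completed", 1),       # boundary in
    list(3, "2021-02-19", "Interventional", "Phase 3", "Closed to Recruitment", 2),
    list(4, "2021-02-20", "Interventional", "Phase 3", "Completed", 1),       # after window
    list(5, "2018-01-01", "Observational", "Phase 2", "Completed", 1),
    list(6, "2018-02-01", "PMS", "Phase 3", "Completed", 1),
    list(7, "2018-03-01", "Interventional", "Phase 2/ Phase 3", "Completed", 3),
    list(8, "2018-04-01", "Interventional", "Phase 2/ Phase 3", "Open to Recruitment", 1),
    list(9, "2018-05-01", "Interventional", "Phase 3/ Phase 4", "Completed", 1),
    list(10, "2018-06-01", "Interventional", "Phase 1", "Completed", 1),
    list(11, "2018-07-01", "Interventional", "Phase 2", "Open to Recruitment", 1),
    list(12, "2018-08-01", "Interventional", "Phase 2", "Closed to Recruitment", 4),
    list(13, "2018-09-01", "Interventional", "Phase 3", "Completed", 1),
    list(14, "2018-10-01", "Interventional", "Phase 3", "Not Yet Recruiting", 1),
    list(15, "2019-01-01", "Interventional", "Phase 4", "Completed", 1),
    list(16, "2019-02-01", "Interventional", "Phase 2", "Completed", 2),
    list(17, "2019-03-01", "Interventional", "Phase 2/ Phase 3", "Closed to Recruitment", 1),
    list(18, "2019-04-01", "Observational", "Phase 3", "Completed", 2),
    list(19, "2019-05-01", "Interventional", "Phase 3", "Completed", 5),
    list(20, "2019-06-01", "Interventional", "Phase 2", "Completed", 1)
  )
  lapply(specs, function(s) {
    mini_record(s[[1]], n_sites = s[[6]], registration = as.Date(s[[2]]),
                trial_type = s[[3]], phase_label = s[[4]], status = s[[5]])
  })
}

# independent flat-table oracle over the same attributes
grid_oracle <- function() {
  df <- data.frame(
    reg = as.Date(c("2016-05-31", "2016-06-01", "2021-02-19", "2021-02-20",
                    "2018-01-01", "2018-02-01", "2018-03-01", "2018-04-01",
                    "2018-05-01", "2018-06-01", "2018-07-01", "2018-08-01",
                    "2018-09-01", "2018-10-01", "2019-01-01", "2019-02-01",
                    "2019-03-01", "2019-04-01", "2019-05-01", "2019-06-01")),
    type = c("Interventional", "Interventional", "Interventional", "Interventional",
             "Observational", "PMS", "Interventional", "Interventional",
             "Interventional", "Interventional", "Interventional", "Interventional",
             "Interventional", "Interventional", "Interventional", "Interventional",
             "Interventional", "Observational", "Interventional", "Interventional"),
    p2 = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE,
           TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
    p3 = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE,
           FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    done = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
             FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    multi = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
              FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  )
  df$in_win <- df$reg >= as.Date("2016-06-01") & df$reg <= as.Date("2021-02-19")
  df$iv <- df$in_win & df$type == "Interventional"
  df
}

test_that("empty input gives an all-zero cascade", {
  out <- select_cohort(list(), cohort_spec())
  expect_equal(out$cascade$n, rep(0L, nrow(out$cascade)))
  expect_length(out$cohort, 0)
})

test_that("cascade counts match a hand-enumerated oracle on a 20-record grid", {
  recs <- grid_records()
  df <- grid_oracle()
  out <- select_cohort(recs, cohort_spec())
  n <- function(step) out$cascade$n[out$cascade$step == step]

  expect_equal(n("1"), sum(df$in_win))
  expect_equal(n("2"), sum(df$iv))
  expect_equal(n("3"), sum(df$iv & df$p2))
  expect_equal(n("4"), sum(df$iv & df$p3))
  expect_equal(n("5"), sum(df$iv & df$p2 & df$done))
  expect_equal(n("6"), sum(df$iv & df$p3 & df$done))
  expect_equal(n("7_single"), sum(df$iv & df$p2 & df$done & !df$multi))
  expect_equal(n("7_multi"), sum(df$iv & df$p2 & df$done & df$multi))
  expect_equal(n("8_single"), sum(df$iv & df$p3 & df$done & !df$multi))
  expect_equal(n("8_multi"), sum(df$iv & df$p3 & df$done & df$multi))
  expect_equal(n("9"), sum(df$iv & (df$p2 | df$p3) & df$done))
  expect_equal(n("9_single"), sum(df$iv & (df$p2 | df$p3) & df$done & !df$multi))
  expect_equal(n("9_multi"), sum(df$iv & (df$p2 | df$p3) & df$done & df$multi))

  # overlap removed once: merged <= phase2 + phase3 survivors
  expect_lte(n("9"), n("5") + n("6"))
  ids <- vapply(out$cohort, function(r) r$ctri_id, character(1))
  expect_false(any(duplicated(ids)))
})

test_that("cascade is monotone along each filter chain", {
  gen <- generate_trials(generator_config(n_trials = 60, seed = 31))
  out <- select_cohort(gen$records, cohort_spec())
  n <- function(step) out$cascade$n[out$cascade$step == step]
  expect_lte(n("2"), n("1"))
  expect_lte(n("3"), n("2"))
  expect_lte(n("4"), n("2"))
  expect_lte(n("5"), n("3"))
  expect_lte(n("6"), n("4"))
  expect_lte(n("9"), n("5") + n("6"))
})

test_that("registration-date boundaries are inclusive", {
  recs <- list(
    mini_record(1, registration = as.Date("2016-06-01")),
    mini_record(2, registration = as.Date("2021-02-19"))
  )
  out <- select_cohort(recs, cohort_spec())
  expect_length(out$cohort, 2)
})

test_that("single/multi split is a partition with zero-site trials counted single", {
  recs <- list(
    mini_record(1, n_sites = 1),
    mini_record(2, n_sites = 3),
    mini_record(3, n_sites = 0, n_ecs = 1)
  )
  sp <- split_by_multiplicity(recs)
  expect_length(sp$single, 2)
  expect_length(sp$multi, 1)
  expect_equal(length(sp$single) + length(sp$multi), length(recs))
})

test_that("phase-specific cohort rules select their supersets", {
  recs <- grid_records()
  m <- select_cohort(recs, cohort_spec(phase_rule = "merged"))$cohort
  p2 <- select_cohort(recs, cohort_spec(phase_rule = "phase2"))$cohort
  p3 <- select_cohort(recs, cohort_spec(phase_rule = "phase3"))$cohort
  ids <- function(x) vapply(x, function(r) r$ctri_id, character(1))
  expect_true(all(ids(p2) %in% ids(m)))
  expect_true(all(ids(p3) %in% ids(m)))
  expect_setequal(ids(m), union(ids(p2), ids(p3)))
})
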