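# Site-EC matching: scoring evidence, exact assignment, elimination,
# ambiguity grading.

two_site_trial <- function(sites, ecs, serial = 900001) {
  trial_record(
    ctri_id = sprintf("CTRI/2019/01/%06d", serial),
    registration_date = as.Date("2019-01-10"),
    trial_type = "Interventional", phase_label = "Phase 3",
    recruitment_status_india = "Completed",
    sites = sites, ecs = ecs
  )
}

test_that("an identical site and committee organisation match directly", {
  tr <- two_site_trial(
    site_table("Ashwini Medical College", "1 Station Road, Pune", "Dr Asha Verma"),
    ec_table("Ashwini Medical College Institutional Ethics Committee, Pune (ECR/101/Inst/MH/2014)")
  )
  res <- match_trial(tr)
  expect_identical(res$trial_grade, "ALL_CLEAR")
  expect_equal(res$assignments$ec_index, 1L)
  expect_identical(res$assignments$status, "direct")
  expect_gte(res$assignments$score, 0.75)
})

test_that("matching a trial without ECs is refused with a pointer to classification", {
  tr <- mini_record(1, n_sites = 1, n_ecs = 0)
  expect_error(match_trial(tr), "classify_counts")
})

test_that("a shared acronym is disambiguated by the city listed in one EC", {
  tr <- two_site_trial(
    site_table(c("Kaveri Institute of Medical Sciences",
                 "Kanaka Institute of Medical Sciences"),
               c("5 Temple Road, Mysuru", "9 River Road, Kochi"),
               c("Dr Anil Shetty", "Dr Nisha Pillai")),
    ec_table(c("KIMS Institutional Ethics Committee, Kochi (ECR/909/Inst/KL/2015)",
               "KIMS Institutional Ethics Committee (ECR/910/Inst/KA/2015)"))
  )
  # the city-bearing EC must outscore its cross pairing
  s_match <- score_pair(2, 1, tr)$score   # Kochi site vs Kochi EC
  s_cross <- score_pair(1, 1, tr)$score   # Mysuru site vs Kochi EC
  expect_gt(s_match, s_cross)
  # and the crosswalk contributes on both
  expect_equal(score_pair(2, 1, tr)$evidence[["acronym_crosswalk"]], 1)
})

test_that("generic committee names stay below threshold without other evidence", {
  tr <- two_site_trial(
    site_table(c("Ashwini Medical College", "Bhavani Institute of Medical Sciences",
                 "Chetana General Hospital", "Devaki Medical College and Hospital"),
               c("1 Hill Road, Pune", "2 Lake Road, Mumbai",
                 "3 River Road, Chennai", "4 Garden Road, Delhi"),
               "Dr Asha Verma"),
    ec_table(rep("Institutional Ethics Committee", 2))
  )
  sp <- score_pair(1, 1, tr)
  expect_lte(sp$evidence[["name"]], 0.30)
  expect_lt(sp$score, 0.75)
  res <- match_trial(tr)
  expect_identical(res$trial_grade, "MULTI_UNCLEAR")
  expect_equal(nrow(res$unresolved), 4)
  expect_true(all(res$unresolved$reason == "no_candidate"))
})

test_that("a doctor's name in the EC links it to the matching site's PI", {
  tr <- two_site_trial(
    site_table(c("Ashwini Medical College", "Chetana General Hospital"),
               c("1 Hill Road, Pune", "3 River Road, Chennai"),
               c("Dr Arjun Sharma", "Dr Meena Rao")),
    ec_table(c("IEC Dr Arjun Sharma", "IEC Dr Meena Rao"))
  )
  sp_right <- score_pair(1, 1, tr)
  sp_wrong <- score_pair(2, 1, tr)
  expect_equal(sp_right$evidence[["pi"]], 0.35)
  expect_equal(sp_wrong$evidence[["pi"]], 0)
  expect_gt(sp_right$score, sp_wrong$score)
})

test_that("the last unassigned EC resolves by elimination and grades ONE_UNCLEAR", {
  tr <- two_site_trial(
    site_table(c("Ashwini Medical College", "Bhavani Institute of Medical Sciences"),
               c("1 Hill Road, Pune", "2 Lake Road, Mumbai"),
               c("Dr Asha Verma", "Dr Ravi Nair")),
    ec_table(c("Ashwini Medical College Institutional Ethics Committee, Pune (ECR/101/Inst/MH/2014)",
               "Institutional Ethics Committee"))
  )
  res <- match_trial(tr)
  expect_identical(res$trial_grade, "ONE_UNCLEAR")
  a <- res$assignments
  expect_identical(a$status[a$site_index == 1], "direct")
  expect_identical(a$status[a$site_index == 2], "by_elimination")
  expect_equal(a$ec_index[a$site_index == 2], 2L)

  # elimination off: the generic EC stays unresolved
  res2 <- match_trial(tr, match_config(enable_elimination = FALSE))
  expect_equal(nrow(res2$unresolved), 1)
})

test_that("Phase A equals the brute-force assignment optimum on random instances", {
  set.seed(55)
  for (k in 1:200) {
    ns <- sample(1:5, 1)
    ne <- sample(1:5, 1)
    sc <- matrix(runif(ns * ne), ns, ne)
    el <- sc >= 0.6
    got <- ctriaudit:::solve_assignment(sc, el)
    want <- brute_force_assignment_total(sc, el)
    expect_equal(got$total, want, tolerance = 1e-12)
    # injectivity
    used <- got$assignment[!is.na(got$assignment)]
    expect_false(any(duplicated(used)))
  }
})

test_that("assignments are one-to-one and exhaustive on synthetic trials", {
  gen <- generate_trials(generator_config(
    n_trials = 40, seed = 41,
    site_count_distribution = c(`2` = 0.3, `3` = 0.3, `4` = 0.2, `5` = 0.2),
    injection_rates = c(R06 = 0.3, R03 = 0.2)
  ))
  for (r in gen$records) {
    res <- match_trial(r)
    expect_false(any(duplicated(res$assignments$ec_index)))
    covered <- sort(c(res$assignments$site_index, res$unresolved$site_index))
    expect_equal(covered, seq_len(nrow(r$sites)))
  }
})

test_that("clean synthetic trials are fully recovered with ALL_CLEAR grades", {
  gen <- generate_trials(generator_config(n_trials = 60, seed = 42))
  res <- lapply(gen$records, match_trial)
  g <- grade_cohort(res)
  expect_equal(g$grades$n[g$grades$grade == "ALL_CLEAR"], 60)
  expect_equal(g$unmatched_fraction, 0)
  for (t in seq_along(res)) {
    a <- res[[t]]$assignments
    expect_equal(a$ec_index[order(a$site_index)], gen$truths[[t]]$true_mapping)
  }
})

test_that("raising the generic-name injection rate never improves the clear fraction", {
  frac_clear <- function(rate) {
    gen <- generate_trials(generator_config(
      n_trials = 80, seed = 43, injection_rates = c(R06 = rate)
    ))
    matchable <- Filter(function(r) nrow(r$ecs) > 0 && nrow(r$sites) > 0, gen$records)
    g <- grade_cohort(lapply(matchable, match_trial))
    g$grades$n[g$grades$grade == "ALL_CLEAR"] / g$n_trials
  }
  f <- vapply(c(0, 0.3, 0.6), frac_clear, numeric(1))
  # same seed means lower-rate injection sets nest inside higher-rate sets,
  # so the fraction is non-increasing exactly, not just on average
  expect_true(all(diff(f) <= 1e-9))
  expect_equal(f[1], 1)
})
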