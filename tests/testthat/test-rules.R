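# Deficiency rules: per-trial catalogue, cross-trial rules, registration
# validation.

test_that("the catalogue registers every rule with a scope and severity", {
  cat <- rule_catalogue()
  expect_setequal(cat$rule_id, c(sprintf("R%02d", 1:15), sprintf("C%02d", 1:3)))
  expect_true(all(cat$severity %in% c("error", "warning", "info")))
  expect_setequal(cat$rule_id[cat$severity == "error"], c("R01", "R04", "R07", "R08"))
})

test_that("a clean record yields no findings and passes validation", {
  gen <- generate_trials(generator_config(n_trials = 5, seed = 51))
  for (r in gen$records) {
    expect_equal(nrow(lint_trial(r)), 0)
    expect_true(validate_for_registration(r)$accept)
  }
})

test_that("linting is deterministic", {
  gen <- generate_trials(generator_config(
    n_trials = 20, seed = 52,
    injection_rates = c(R03 = 0.3, R06 = 0.3, R09 = 0.3)
  ))
  f1 <- lint_cohort(gen$records)
  f2 <- lint_cohort(gen$records)
  expect_identical(f1, f2)
})

test_that("error-severity rules block registration", {
  fx <- make_fixture_suite()
  by_id <- function(id) Filter(function(f) f$id == id, fx)[[1]]$record

  v_noec <- validate_for_registration(by_id("no-ec"))
  expect_false(v_noec$accept)
  expect_identical(v_noec$blocking$rule_id, "R01")

  v_dup <- validate_for_registration(by_id("site-twice-same-pi"))
  expect_false(v_dup$accept)
  expect_true("R04" %in% v_dup$blocking$rule_id)

  v_msg <- validate_for_registration(by_id("ec-message-text"))
  expect_false(v_msg$accept)
  expect_true("R07" %in% v_msg$blocking$rule_id)

  v_echo <- validate_for_registration(by_id("ec-is-site-echo"))
  expect_false(v_echo$accept)
  expect_true("R08" %in% v_echo$blocking$rule_id)

  # warnings alone do not block
  v_generic <- validate_for_registration(by_id("one-generic-ec-many-sites"))
  expect_true(v_generic$accept)
})

test_that("a shared file number across trials raises one cross-trial finding listing all ids", {
  fx <- make_fixture_suite()
  five <- Filter(function(f) grepl("^shared-file-number", f$id), fx)
  expect_length(five, 5)
  findings <- lint_cohort(lapply(five, function(f) f$record))
  c02 <- findings[findings$rule_id == "C02", ]
  expect_equal(nrow(c02), 1)
  ids <- vapply(five, function(f) f$record$ctri_id, character(1))
  for (id in ids) expect_match(c02$evidence, id, fixed = TRUE)

  # a single trial cannot raise cross-trial findings
  solo <- lint_cohort(list(five[[1]]$record))
  expect_false(any(solo$scope == "cross_trial"))
})

test_that("deliberate acronym-collision groups surface as C01 naming every organisation", {
  gen <- generate_trials(generator_config(
    n_trials = 80, seed = 53, institution_pool_size = 30,
    acronym_collision_groups = 1, collision_group_size = 4
  ))
  group <- gen$pool[gen$pool$group == 1, ]
  expect_equal(length(unique(group$acronym)), 1)
  findings <- lint_cohort(gen$records)
  c01 <- findings[findings$rule_id == "C01", ]
  expect_gte(nrow(c01), 1)
  hit <- c01[grepl(group$acronym[1], c01$evidence, fixed = TRUE), ]
  expect_equal(nrow(hit), 1)
  # every group member that was actually used as a site should be named
  used <- vapply(group$name, function(nm) {
    any(vapply(gen$records, function(r) nm %in% r$sites$name_raw, logical(1)))
  }, logical(1))
  for (nm in group$name[used]) {
    expect_match(hit$evidence, tolower(nm), fixed = TRUE)
  }
})

test_that("inconsistent naming of one organisation's committee is reported across trials", {
  r1 <- trial_record("CTRI/2019/02/030001", registration_date = as.Date("2019-02-01"),
                     trial_type = "Interventional", phase_label = "Phase 3",
                     recruitment_status_india = "Completed",
                     sites = site_table("Ashwini Medical College", "1 Hill Road, Pune", "Dr A Verma"),
                     ecs = ec_table("Ashwini Medical College Institutional Ethics Committee, Pune"))
  r2 <- trial_record("CTRI/2019/02/030002", registration_date = as.Date("2019-02-01"),
                     trial_type = "Interventional", phase_label = "Phase 3",
                     recruitment_status_india = "Completed",
                     sites = site_table("Ashwini Medical College", "1 Hill Road, Pune", "Dr R Nair"),
                     ecs = ec_table("Ethics Committee, Ashwini Medical College, Pune"))
  findings <- lint_cohort(list(r1, r2))
  c03 <- findings[findings$rule_id == "C03", ]
  expect_equal(nrow(c03), 1)
  expect_match(c03$evidence, "030001")
  expect_match(c03$evidence, "030002")
})

test_that("the shared-EC city rule only fires for post-2019 registrations with a city mismatch", {
  mk <- function(reg, ec_city) {
    trial_record("CTRI/2020/05/040001", registration_date = as.Date(reg),
                 trial_type = "Interventional", phase_label = "Phase 3",
                 recruitment_status_india = "Completed",
                 sites = site_table(
                   c("Ashwini Medical College", "Chetana General Hospital"),
                   c("1 Hill Road, Pune", "2 Marina Road, Chennai"),
                   c("Dr A Verma", "Dr R Nair")),
                 ecs = ec_table(sprintf(
                   "Ashwini Medical College Institutional Ethics Committee, %s (ECR/101/Inst/MH/2014)",
                   ec_city)))
  }
  f_new <- lint_trial(mk("2020-05-01", "Pune"))
  expect_true("R14" %in% f_new$rule_id)
  expect_equal(f_new$site_index[f_new$rule_id == "R14"], 2L)

  f_old <- lint_trial(mk("2018-05-01", "Pune"))
  expect_false("R14" %in% f_old$rule_id)

  # both sites covered by same-city committees: no finding
  same <- mk("2020-05-01", "Pune")
  same$sites$address_raw[2] <- "9 Hill Road, Pune"
  expect_false("R14" %in% lint_trial(same)$rule_id)
})

test_that("per-rule injection recovery is near-perfect on a small benchmark", {
  base <- generate_trials(generator_config(n_trials = 150, seed = 54))
  for (rule in c("R01", "R04", "R06", "R09", "R11", "R14")) {
    b <- rule_benchmark(rule, rate = 0.3, seed = 54, base = base)
    expect_gte(b$precision, 0.95)
    expect_gte(b$recall, 0.95)
  }
})
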