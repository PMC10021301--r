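# Curated fixture suite: one hand-built record per documented problem
# pattern (blank EC table, casual names, site echoes, unexpanded or
# misspelled acronyms, generic committees shared across sites, doctor-name
# committees, hospital chains, shared file numbers, duplicated rows,
# department-only site names, retrospective registration, ...), each with a
# manifest of the findings it is expected to raise and its count category.
# All names are fictitious.

fx_inst <- list(
  A = list(name = "Ashwini Medical College", city = "Pune",
           ecr = "ECR/101/Inst/MH/2014"),
  B = list(name = "Bhavani Institute of Medical Sciences", city = "Mumbai",
           ecr = "ECR/202/Inst/MH/2015"),
  C = list(name = "Chetana General Hospital", city = "Chennai",
           ecr = "ECR/303/Inst/TN/2016"),
  D = list(name = "Devaki Medical College and Hospital", city = "Delhi",
           ecr = "ECR/404/Inst/DL/2017"),
  E = list(name = "Ekta General Hospital", city = "Surat",
           ecr = "ECR/505/Inst/GJ/2016")
)

fx_ec <- function(inst) clean_ec_name(inst$name, inst$city, inst$ecr)

fx_record <- function(serial, sites, ecs,
                      registration = as.Date("2018-03-10"),
                      enrollment = as.Date("2018-06-01"),
                      phase_label = "Phase 3",
                      raw_fields = character(0)) {
  trial_record(
    ctri_id = sprintf("CTRI/2018/03/%06d", serial),
    registration_date = registration,
    enrollment_start_date = enrollment,
    trial_type = "Interventional",
    phase_label = phase_label,
    recruitment_status_india = "Completed",
    sites = sites,
    ecs = ecs,
    raw_fields = raw_fields
  )
}

fixture <- function(id, record, rules, category, note) {
  list(id = id, record = record, manifest = list(rules = sort(rules),
                                                 category = category),
       note = note)
}

#' The curated problem-pattern fixture suite
#'
#' @return A list of fixtures, each with `id`, `record`, `manifest`
#'   (`rules`: sorted expected per-trial rule ids, with multiplicity;
#'   `category`: expected count label) and `note`. The suite-level attribute
#'   `cohort_rules` lists the cross-trial rule ids expected from
#'   [lint_cohort()] on the full suite.
#' @export
make_fixture_suite <- function() {
  A <- fx_inst$A; B <- fx_inst$B; C <- fx_inst$C; D <- fx_inst$D; E <- fx_inst$E
  site_of <- function(inst, pi = "Dr Arjun Sharma") {
    site_table(inst$name, sprintf("12 Station Road, %s", inst$city), pi)
  }
  fixtures <- list(
    fixture("no-ec",
      fx_record(100001, site_of(A), ec_table()),
      c("R01"), "NO_EC",
      "interventional trial with a blank EC table"),

    fixture("casual-ec-reference",
      fx_record(100002, site_of(A), ec_table("Ethical Committee of the Council")),
      c("R06", "R10"), "EQUAL_SINGLE",
      "casual reference instead of a proper committee name"),

    fixture("ec-is-site-echo",
      fx_record(100003,
        rbind(site_of(A), site_of(B, "Dr Meena Rao")),
        ec_table(c(A$name, B$name))),
      c("R08", "R08", "R10", "R10"), "EQUAL_MULTI",
      "site names listed in place of the ECs"),

    fixture("unexpanded-ec-acronym",
      fx_record(100004,
        site_table("Sunrise Hospital", "4 Hill Road, Kochi", "Dr Ravi Nair"),
        ec_table("MOSC Institutional Ethics Committee, Kochi (ECR/515/Inst/KL/2015)")),
      c("R11"), "EQUAL_SINGLE",
      "EC acronym never spelled out in the record"),

    fixture("one-generic-ec-many-sites",
      fx_record(100005,
        rbind(site_of(A), site_of(B, "Dr Meena Rao"),
              site_of(C, "Dr Vikram Iyer"), site_of(D, "Dr Sunita Patel")),
        ec_table("Institutional Ethics Committee")),
      c("R02", "R06", "R10"), "MORE_SITES",
      "one generically named committee for four sites"),

    fixture("generic-ec-repeated",
      fx_record(100006,
        rbind(site_of(A), site_of(B, "Dr Meena Rao"),
              site_of(C, "Dr Vikram Iyer"), site_of(D, "Dr Sunita Patel")),
        ec_table(rep("Institutional Ethics Committee", 3))),
      c("R02", "R03", "R06", "R06", "R06", "R10", "R10", "R10"), "MORE_SITES",
      "the same generic committee name listed three times"),

    fixture("one-site-three-org-ecs",
      fx_record(100007, site_of(A),
        ec_table(c(fx_ec(B), fx_ec(C), fx_ec(D)))),
      c("R02"), "MORE_ECS",
      "a single site with committees from three organisations"),

    fixture("doctor-name-ecs",
      fx_record(100008,
        rbind(site_of(A, "Dr Arjun Sharma"), site_of(B, "Dr Meena Rao"),
              site_of(C, "Dr Vikram Iyer")),
        ec_table(c("IEC Dr Arjun Sharma", "IEC Dr Meena Rao",
                   "IEC Dr Vikram Iyer"))),
      c("R10", "R10", "R10", "R13", "R13", "R13"), "EQUAL_MULTI",
      "committees identified only by a doctor's name"),

    fixture("hospital-chain-repeated-ec",
      fx_record(100009,
        site_table(c("Lotus Hospital", "Lotus Hospital"),
                   c("2 Lake Road, Pune", "7 Lake Road, Delhi"),
                   c("Dr Arjun Sharma", "Dr Meena Rao")),
        ec_table(rep("Lotus Hospital Ethics Committee (ECR/616/Inst/MH/2016)", 2))),
      c("R03", "R05"), "EQUAL_MULTI",
      "a hospital chain: same name in two cities, committee repeated"),

    fixture("shared-file-number-1",
      fx_record(100010, site_of(A), ec_table("IEC/2019/0042")),
      c("R09", "R10"), "EQUAL_SINGLE", "EC file number instead of a name"),
    fixture("shared-file-number-2",
      fx_record(100011, site_of(B, "Dr Meena Rao"), ec_table("IEC/2019/0042")),
      c("R09", "R10"), "EQUAL_SINGLE", "same file number, second trial"),
    fixture("shared-file-number-3",
      fx_record(100012, site_of(C, "Dr Vikram Iyer"), ec_table("IEC/2019/0042")),
      c("R09", "R10"), "EQUAL_SINGLE", "same file number, third trial"),
    fixture("shared-file-number-4",
      fx_record(100013, site_of(D, "Dr Sunita Patel"), ec_table("IEC/2019/0042")),
      c("R09", "R10"), "EQUAL_SINGLE", "same file number, fourth trial"),
    fixture("shared-file-number-5",
      fx_record(100014, site_of(E, "Dr Mohan Gupta"), ec_table("IEC/2019/0042")),
      c("R09", "R10"), "EQUAL_SINGLE", "same file number, fifth trial"),

    fixture("single-site-ec-thrice",
      fx_record(100015, site_of(A), ec_table(rep(fx_ec(A), 3))),
      c("R02", "R03"), "MORE_ECS",
      "a single site that listed its committee three times"),

    fixture("multiple-iecs-single-cell",
      fx_record(100016,
        rbind(site_of(A), site_of(B, "Dr Meena Rao")),
        ec_table(c(fx_ec(A), paste0(
          "Institutional Ethics Committee I, II and III, ",
          B$name, ", ", B$city, " (", B$ecr, ")")))),
      character(0), "EQUAL_MULTI",
      "several numbered committees listed in one cell"),

    fixture("one-site-three-orgs-one-clear",
      fx_record(100017, site_of(A),
        ec_table(c(fx_ec(A), fx_ec(B), fx_ec(C)))),
      c("R02"), "MORE_ECS",
      "three organisations' committees, one clearly linked to the site"),

    fixture("site-duplicated-for-council-ec",
      fx_record(100018,
        rbind(site_of(A), site_of(A)),
        ec_table(c(fx_ec(A),
                   "Medical Research Council Ethics Committee, Delhi (ECR/717/Inst/DL/2013)"))),
      c("R04"), "EQUAL_MULTI",
      "site duplicated so a second (council) committee could be listed"),

    fixture("many-sites-one-implied-ec",
      fx_record(100019,
        {
          towns <- as.vector(outer(
            c("North", "South", "East", "West", "Upper", "Lower", "New"),
            c("Ganga", "Yamuna", "Kaveri", "Tapti", "Godavari", "Krishna"),
            paste))[1:38]
          rbind(
            site_of(A),
            site_table(paste(towns, "District Hospital"),
                       "1 Market Road, Nagpur", "Dr Rakesh Verma")
          )
        },
        ec_table(A$name)),
      c("R02", "R08", "R10"), "MORE_SITES",
      "39 sites with one committee implied by an organisation name"),

    fixture("misspelled-ec-acronym",
      fx_record(100020,
        site_table("Ashwini Institute of Medical Sciences",
                   "3 Garden Road, Pune", "Dr Deepa Joshi"),
        ec_table("AMIS Institutional Ethics Committee, Pune (ECR/808/Inst/MH/2014)")),
      c("R11"), "EQUAL_SINGLE",
      "spelling mistake inside the committee's acronym"),

    fixture("ec-acronym-expanded-by-site",
      fx_record(100021,
        site_table("Ashwini Institute of Medical Sciences",
                   "3 Garden Road, Pune", "Dr Deepa Joshi"),
        ec_table("AIMS Institutional Ethics Committee, Pune (ECR/808/Inst/MH/2014)")),
      character(0), "EQUAL_SINGLE",
      "acronym used in the EC but spelled out by the site name"),

    fixture("ec-message-text",
      fx_record(100022, site_of(A),
        ec_table(c(fx_ec(A), paste(
          "Conditional approval by the Institutional Ethics Committee was",
          "given on 29/10/2017 which is six months before enrolment of the",
          "first patient so please consider this submission")))),
      c("R02", "R07", "R10"), "MORE_ECS",
      "one of two apparent committees is just a message"),

    fixture("same-acronym-city-disambiguates",
      fx_record(100023,
        site_table(c("Kaveri Institute of Medical Sciences",
                     "Kanaka Institute of Medical Sciences"),
                   c("5 Temple Road, Mysuru", "9 River Road, Kochi"),
                   c("Dr Anil Shetty", "Dr Nisha Pillai")),
        ec_table(c("KIMS Institutional Ethics Committee, Kochi (ECR/909/Inst/KL/2015)",
                   "KIMS Institutional Ethics Committee (ECR/910/Inst/KA/2015)"))),
      character(0), "EQUAL_MULTI",
      "two sites sharing an acronym; only one EC lists its city"),

    fixture("long-acronym-site-name",
      fx_record(100024,
        site_table("PGIMSRC", "9 Sector Road, Chandigarh", "Dr Ajay Singh"),
        ec_table("PGIMSRC Institutional Ethics Committee, Chandigarh (ECR/111/Inst/CH/2014)")),
      c("R11", "R12"), "EQUAL_SINGLE",
      "an unexplained acronym standing in for the site name"),

    fixture("site-twice-same-pi",
      fx_record(100025, rbind(site_of(A), site_of(A)), ec_table(fx_ec(A))),
      c("R02", "R04"), "MORE_SITES",
      "site listed twice with the same PI, committee once"),

    fixture("site-twice-diff-pi",
      fx_record(100026,
        rbind(site_of(A, "Dr Arjun Sharma"), site_of(A, "Dr Meena Rao")),
        ec_table(fx_ec(A))),
      c("R02", "R05"), "MORE_SITES",
      "site listed twice with different PIs, committee once"),

    fixture("site-name-department-only",
      fx_record(100027,
        site_table("Department of Cardiology", "45 Marina Road, Chennai",
                   "Dr Vikram Iyer"),
        ec_table(fx_ec(C)),
        raw_fields = c("Public Title" = paste(
          "A study of heart failure at Chetana General Hospital Chennai"))),
      c("R12"), "EQUAL_SINGLE",
      "organisation name absent from the whole site entry"),

    fixture("site-ec-spelling-differs",
      fx_record(100028,
        site_table("Ashwini Medcal College", "12 Station Road, Pune",
                   "Dr Arjun Sharma"),
        ec_table(fx_ec(A))),
      character(0), "EQUAL_SINGLE",
      "spelling differs between site and committee entry"),

    fixture("generic-gmc-sites",
      fx_record(100029,
        site_table(rep("Government Medical College", 3),
                   c("1 College Road, Nagpur", "2 College Road, Chennai",
                     "3 College Road, Delhi"),
                   c("Dr Arjun Sharma", "Dr Meena Rao", "Dr Vikram Iyer")),
        ec_table(c(
          "Government Medical College Institutional Ethics Committee, Nagpur (ECR/121/Inst/MH/2013)",
          "Government Medical College Institutional Ethics Committee, Chennai (ECR/122/Inst/TN/2013)",
          "Government Medical College Institutional Ethics Committee, Delhi (ECR/123/Inst/DL/2013)"))),
      c("R05"), "EQUAL_MULTI",
      "several generically named colleges, resolvable only by address"),

    fixture("independent-ec-declared",
      fx_record(100030, site_of(A),
        ec_table("Suraksha Independent Ethics Committee, Pune (ECR/131/Indep/MH/2017)")),
      character(0), "EQUAL_SINGLE",
      "an independent committee that declares itself as such"),

    fixture("retrospective-shared-ec",
      fx_record(100031,
        rbind(site_of(A), site_of(C, "Dr Vikram Iyer")),
        ec_table(fx_ec(A)),
        registration = as.Date("2019-06-10"),
        enrollment = as.Date("2015-02-01")),
      c("R02", "R14", "R15"), "MORE_SITES",
      "post-2019 shared committee in a different city, registered retrospectively"),

    fixture("golden-clean",
      fx_record(100032, site_of(A), ec_table(fx_ec(A))),
      character(0), "EQUAL_SINGLE",
      "a clean single-site record")
  )
  # C02: the five shared-file-number trials. C01: the spelling-mistake
  # fixture makes the derived acronym AMC stand for two apparent
  # organisations ("Ashwini Medical College" / "Ashwini Medcal College") --
  # misspellings creating phantom organisations is precisely what the
  # acronym-collision rule is meant to surface.
  structure(fixtures, cohort_rules = c("C01", "C02"))
}
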