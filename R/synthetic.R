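# Synthetic registry records with ground truth.
#
# Clean records emulate the structures a registry audit sees: a pool of
# fictitious institutions (name, city, CDSCO registration number), one EC per
# site named "<Institution> Institutional Ethics Committee, <City> (<ECR>)",
# PI names, addresses carrying the city, and a public title elsewhere in the
# record that spells out the organisation. Deficiency injectors then rewrite
# records per rule semantics and log every edit as ground truth. All
# randomness flows through the configured seed; identical seeds give
# bit-identical output.

generator_city_table <- function() {
  tibble::tibble(
    city = c("Mumbai", "Pune", "Nagpur", "Delhi", "Chennai", "Vellore",
             "Madurai", "Bengaluru", "Mysuru", "Hubli", "Kolkata", "Hyderabad",
             "Lucknow", "Kanpur", "Varanasi", "Jaipur", "Jodhpur", "Ahmedabad",
             "Surat", "Bhopal", "Indore", "Patna", "Kochi", "Thiruvananthapuram",
             "Chandigarh", "Puducherry", "Guwahati", "Bhubaneswar", "Ranchi",
             "Raipur", "Dehradun", "Amritsar", "Rohtak", "Visakhapatnam",
             "Vijayawada"),
    state = c("MH", "MH", "MH", "DL", "TN", "TN",
              "TN", "KA", "KA", "KA", "WB", "TS",
              "UP", "UP", "UP", "RJ", "RJ", "GJ",
              "GJ", "MP", "MP", "BR", "KL", "KL",
              "CH", "Py", "AS", "OR", "JH",
              "CG", "UK", "PB", "HR", "AP",
              "AP")
  )
}

institution_prefixes <- c(
  "Ashwini", "Bhavani", "Chetana", "Devaki", "Ekta", "Falguni", "Gautami",
  "Himani", "Indira", "Jeevan", "Kalyani", "Lakshmi", "Madhav", "Nandini",
  "Omkara", "Prakash", "Rajani", "Sarala", "Tejaswi", "Ujwala", "Vasanta",
  "Yashoda", "Anandi", "Bharati", "Chandrika", "Darshana", "Eshwari",
  "Gokula", "Harsha", "Ishani", "Jyoti", "Kaveri", "Lavanya", "Mohini",
  "Narmada", "Padmini", "Ragini", "Sharada", "Tarini", "Upasana", "Vaidehi",
  "Anupama", "Bhagya", "Charulata", "Deepika", "Gayana", "Hemalata",
  "Ilavati", "Janaki", "Kamala"
)

institution_types <- c(
  "Medical College", "Institute of Medical Sciences", "General Hospital",
  "Medical College and Hospital", "Institute of Health Sciences"
)

pi_first_names <- c(
  "Arjun", "Meena", "Ravi", "Sunita", "Vikram", "Anita", "Suresh", "Priya",
  "Mohan", "Kavita", "Rakesh", "Deepa", "Anil", "Shanti", "Manoj", "Rekha",
  "Ajay", "Nisha", "Sanjay", "Lata", "Vinod", "Asha", "Prakash", "Usha"
)
pi_last_names <- c(
  "Sharma", "Rao", "Patel", "Iyer", "Mehta", "Deshmukh", "Kulkarni", "Nair",
  "Reddy", "Gupta", "Joshi", "Banerjee", "Chatterjee", "Singh", "Verma",
  "Pillai", "Naik", "Shetty", "Bhat", "Kaur"
)

#' Generator configuration
#'
#' Defaults emulate the structure of a recent phase-2/3 audit cohort: about
#' three quarters of trials are single-site (the 1012-of-1359 share), the
#' rest spread over 2-12 sites with a long thin tail.
#'
#' @param n_trials Number of records to generate.
#' @param site_count_distribution Named numeric: probability mass over site
#'   counts 1..12.
#' @param institution_pool_size Number of fictitious institutions available.
#' @param acronym_collision_groups Number of groups of institutions built to
#'   share a derived acronym across different cities (the "KIMS" pattern);
#'   default 0.
#' @param collision_group_size Institutions per collision group (default 4).
#' @param injection_rates Named numeric, rule id -> probability in `[0, 1]`.
#' @param typo_rate Probability of a single-character typo in one site or EC
#'   name per trial (default 0).
#' @param seed Integer seed; fully determines the output.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_trials = 100,
                             site_count_distribution = c(
                               `1` = 0.745, `2` = 0.080, `3` = 0.055,
                               `4` = 0.040, `5` = 0.025, `6` = 0.018,
                               `7` = 0.012, `8` = 0.010, `9` = 0.006,
                               `10` = 0.004, `11` = 0.003, `12` = 0.002
                             ),
                             institution_pool_size = 60,
                             acronym_collision_groups = 0,
                             collision_group_size = 4,
                             injection_rates = numeric(0),
                             typo_rate = 0,
                             seed = 1L) {
  if (any(injection_rates < 0 | injection_rates > 1)) {
    stop("injection_rates must lie in [0, 1]")
  }
  if (typo_rate < 0 || typo_rate > 1) stop("typo_rate must lie in [0, 1]")
  structure(
    list(
      n_trials = as.integer(n_trials),
      site_count_distribution = site_count_distribution / sum(site_count_distribution),
      institution_pool_size = as.integer(institution_pool_size),
      acronym_collision_groups = as.integer(acronym_collision_groups),
      collision_group_size = as.integer(collision_group_size),
      injection_rates = injection_rates,
      typo_rate = typo_rate,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Build the fictitious institution pool
#'
#' Names are fictitious by construction (no real hospital names); derived
#' acronyms are unique across the pool except inside deliberate collision
#' groups, which share the acronym across different cities.
#'
#' @param cfg A [generator_config()]; uses the current RNG state.
#' @return A tibble: `name`, `city`, `state`, `ecr`, `acronym`, `group`.
#' @keywords internal
make_institution_pool <- function(cfg) {
  cities <- generator_city_table()
  pool <- list()
  seen_names <- character(0)
  seen_acr <- character(0)
  serial <- 100L

  add_inst <- function(prefix, type, city_row, group) {
    name <- paste(prefix, type)
    acr <- derive_acronym(name)
    ecr <- sprintf("ECR/%d/Inst/%s/%d", serial, city_row$state,
                   sample(2013:2019, 1))
    serial <<- serial + sample(3:9, 1)
    pool[[length(pool) + 1]] <<- tibble::tibble(
      name = name, city = city_row$city, state = city_row$state,
      ecr = ecr, acronym = acr, group = group
    )
    seen_names <<- c(seen_names, name)
    seen_acr <<- c(seen_acr, acr)
  }

  # deliberate acronym-collision groups: same initial letter and type,
  # different prefixes and cities
  if (cfg$acronym_collision_groups > 0) {
    for (g in seq_len(cfg$acronym_collision_groups)) {
      letter <- LETTERS[sample(seq_along(LETTERS), 1)]
      candidates <- institution_prefixes[substr(institution_prefixes, 1, 1) == letter]
      while (length(candidates) < cfg$collision_group_size) {
        # synthesise extra prefixes with the same initial
        candidates <- c(candidates, paste0(letter, c("arini", "odaya", "ulasi",
                                                     "amini", "ohana")))
      }
      prefixes <- sample(candidates, cfg$collision_group_size)
      type <- sample(institution_types, 1)
      city_idx <- sample(nrow(cities), cfg$collision_group_size)
      for (m in seq_len(cfg$collision_group_size)) {
        add_inst(prefixes[m], type, cities[city_idx[m], ], group = g)
      }
    }
  }

  guard <- 0L
  while (length(pool) < cfg$institution_pool_size && guard < 10000L) {
    guard <- guard + 1L
    prefix <- sample(institution_prefixes, 1)
    type <- sample(institution_types, 1)
    name <- paste(prefix, type)
    acr <- derive_acronym(name)
    if (name %in% seen_names || acr %in% seen_acr) next
    add_inst(prefix, type, cities[sample(nrow(cities), 1), ], group = 0L)
  }
  do.call(rbind, pool)
}

clean_ec_name <- function(inst_name, city, ecr) {
  sprintf("%s Institutional Ethics Committee, %s (%s)", inst_name, city, ecr)
}

title_case <- function(x) {
  gsub("\\b([a-z])", "\\U\\1", x, perl = TRUE)
}

random_pi <- function() {
  sprintf("Dr %s %s", sample(pi_first_names, 1), sample(pi_last_names, 1))
}

random_address <- function(city) {
  # street names deliberately avoid institution keywords so that an address
  # identifies an organisation only when a site is on its premises
  streets <- c("Station", "Gandhi", "Nehru", "Lake", "Hill",
               "River", "Market", "Temple", "Garden", "Canal")
  sprintf("%d %s Road, %s", sample(5:220, 1), sample(streets, 1), city)
}

#' Generate synthetic registry records with ground truth
#'
#' Produces `cfg$n_trials` clean records (one EC per site, true mapping the
#' identity), then applies [inject_deficiencies()] at the configured rates.
#'
#' @param cfg A [generator_config()].
#' @return A list with `records` (list of `ctri_record`s), `truths` (one
#'   entry per record: `ctri_id`, `true_mapping`, `injected` tibble) and
#'   `pool` (the institution table).
#' @export
generate_trials <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  pool <- make_institution_pool(cfg)

  window_start <- as.Date("2016-06-01")
  window_end <- as.Date("2021-02-19")
  window_days <- as.integer(window_end - window_start)

  counts <- as.integer(names(cfg$site_count_distribution))
  records <- vector("list", cfg$n_trials)
  truths <- vector("list", cfg$n_trials)

  for (t in seq_len(cfg$n_trials)) {
    reg <- window_start + sample(0:window_days, 1)
    enr <- reg + sample(30:300, 1)
    k <- sample(counts, 1, prob = cfg$site_count_distribution)
    k <- min(k, nrow(pool))
    inst <- pool[sample(nrow(pool), k), ]
    id <- sprintf("CTRI/%d/%02d/%06d",
                  as.integer(format(reg, "%Y")), as.integer(format(reg, "%m")),
                  t)
    phase_label <- sample(
      c("Phase 2", "Phase 3", "Phase 2/ Phase 3", "Phase 3/ Phase 4"),
      1, prob = c(0.35, 0.40, 0.15, 0.10)
    )
    status <- sample(c("Completed", "Closed to Recruitment"), 1)
    pis <- vapply(seq_len(k), function(i) random_pi(), character(1))
    sites <- site_table(
      name_raw = inst$name,
      address_raw = vapply(inst$city, random_address, character(1)),
      pi_name_raw = pis
    )
    ecs <- ec_table(
      name_raw = mapply(clean_ec_name, inst$name, inst$city, inst$ecr,
                        USE.NAMES = FALSE),
      approval_status_raw = "Approved"
    )
    raw_fields <- c(
      "Public Title" = sprintf(
        "A randomised clinical study conducted at %s",
        paste(inst$name, collapse = " and ")
      ),
      "Primary Sponsor" = sprintf("%s Research Trust", sample(institution_prefixes, 1))
    )
    records[[t]] <- trial_record(
      ctri_id = id,
      registration_date = reg,
      enrollment_start_date = enr,
      trial_type = "Interventional",
      phase_label = phase_label,
      recruitment_status_india = status,
      sites = sites,
      ecs = ecs,
      raw_fields = raw_fields
    )
    truths[[t]] <- list(
      ctri_id = id,
      true_mapping = seq_len(k),
      injected = tibble::tibble(rule_id = character(0), locus_type = character(0),
                                locus_index = integer(0))
    )
  }

  out <- list(records = records, truths = truths, pool = pool)
  if (length(cfg$injection_rates) > 0 || cfg$typo_rate > 0) {
    out <- inject_deficiencies(out$records, out$truths,
                               rates = cfg$injection_rates,
                               typo_rate = cfg$typo_rate,
                               seed = cfg$seed + 7919L,
                               pool = pool)
    out$pool <- pool
  }
  out
}

#' Inject deficiencies into clean records
#'
#' For each rule with a positive rate, each trial is independently selected
#' with that probability (per-trial uniform draws, so for a fixed seed the
#' selected set at a lower rate is a subset of the set at a higher rate) and
#' rewritten per the rule's semantics; every edit is recorded in the truth.
#'
#' @param records,truths Output of [generate_trials()] before injection.
#' @param rates Named numeric, rule id (R01..R15) -> probability.
#' @param typo_rate Per-trial probability of a single-character typo in a
#'   site or EC name.
#' @param seed Integer seed for the injection draws.
#' @param pool Institution table (needed by the injectors that introduce new
#'   organisations).
#' @return A list with modified `records` and `truths`.
#' @export
inject_deficiencies <- function(records, truths, rates, typo_rate = 0,
                                seed = 1L, pool = NULL) {
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  set.seed(as.integer(seed))
  rule_ids <- sprintf("R%02d", 1:15)
  for (rule in rule_ids) {
    rate <- if (rule %in% names(rates)) rates[[rule]] else 0
    if (is.na(rate)) rate <- 0
    u <- runif(length(records))
    if (rate == 0) next
    for (t in which(u < rate)) {
      res <- inject_rule(records[[t]], truths[[t]], rule, pool)
      records[[t]] <- res$record
      truths[[t]] <- res$truth
    }
  }
  if (typo_rate > 0) {
    u <- runif(length(records))
    for (t in which(u < typo_rate)) {
      res <- inject_typo(records[[t]], truths[[t]])
      records[[t]] <- res$record
      truths[[t]] <- res$truth
    }
  }
  list(records = records, truths = truths)
}

log_injection <- function(truth, rule, locus_type, locus_index) {
  truth$injected <- rbind(
    truth$injected,
    tibble::tibble(rule_id = rule, locus_type = locus_type,
                   locus_index = as.integer(locus_index))
  )
  truth
}

inject_rule <- function(rec, truth, rule, pool) {
  n_sites <- nrow(rec$sites)
  n_ecs <- nrow(rec$ecs)
  needs_ec <- rule %in% c("R02", "R03", "R06", "R07", "R08", "R09", "R10", "R13", "R14")
  if (needs_ec && n_ecs == 0) return(list(record = rec, truth = truth))
  pick_ec <- function() sample(seq_len(n_ecs), 1)
  pick_site <- function() sample(seq_len(n_sites), 1)
  other_inst <- function() {
    if (is.null(pool)) stop("injector needs the institution pool")
    avail <- pool[!(pool$name %in% rec$sites$name_raw), ]
    avail[sample(nrow(avail), 1), ]
  }

  switch(rule,
    R01 = {
      rec$ecs <- ec_table()
      truth$true_mapping <- rep(NA_integer_, n_sites)
      truth <- log_injection(truth, "R01", "trial", NA)
    },
    R02 = {
      inst <- other_inst()
      rec$ecs <- rbind(rec$ecs, ec_table(clean_ec_name(inst$name, inst$city, inst$ecr)))
      truth <- log_injection(truth, "R02", "ec", n_ecs + 1)
    },
    R03 = {
      j <- pick_ec()
      rec$ecs <- rbind(rec$ecs, rec$ecs[j, ])
      truth <- log_injection(truth, "R03", "ec", j)
    },
    R04 = {
      i <- pick_site()
      rec$sites <- rbind(rec$sites, rec$sites[i, ])
      truth <- log_injection(truth, "R04", "site", i)
    },
    R05 = {
      i <- pick_site()
      dup <- rec$sites[i, ]
      repeat {
        dup$pi_name_raw <- random_pi()
        if (dup$pi_name_raw != rec$sites$pi_name_raw[i]) break
      }
      rec$sites <- rbind(rec$sites, dup)
      truth <- log_injection(truth, "R05", "site", i)
    },
    R06 = {
      j <- pick_ec()
      rec$ecs$name_raw[j] <- "Institutional Ethics Committee"
      truth <- log_injection(truth, "R06", "ec", j)
    },
    R07 = {
      j <- pick_ec()
      rec$ecs$name_raw[j] <- paste(
        "Conditional approval by the Institutional Ethics Committee was given",
        "on 29/10/2017 which is six months before enrolment of the first",
        "patient so please consider this submission"
      )
      truth <- log_injection(truth, "R07", "ec", j)
    },
    R08 = {
      j <- pick_ec()
      i <- min(j, n_sites)
      rec$ecs$name_raw[j] <- rec$sites$name_raw[i]
      truth <- log_injection(truth, "R08", "ec", j)
    },
    R09 = {
      j <- pick_ec()
      rec$ecs$name_raw[j] <- sprintf("IEC/%d/%04d", sample(2016:2020, 1),
                                     sample(10:9999, 1))
      truth <- log_injection(truth, "R09", "ec", j)
    },
    R10 = {
      j <- pick_ec()
      rec$ecs$name_raw[j] <- sub("\\s*\\(ECR[^)]*\\)", "", rec$ecs$name_raw[j])
      truth <- log_injection(truth, "R10", "ec", j)
    },
    R11 = {
      i <- pick_site()
      acr <- derive_acronym(rec$sites$name_raw[i])
      if (!is.na(acr)) {
        city <- normalize_text(rec$sites$address_raw[i])$city
        city_name <- if (is.na(city)) "Pune" else title_case(city)
        ecr <- detect_ecr(rec$ecs$name_raw[min(i, n_ecs)])
        rec$sites$name_raw[i] <- acr
        if (i <= n_ecs) {
          rec$ecs$name_raw[i] <- sprintf(
            "%s Institutional Ethics Committee, %s (%s)", acr, city_name,
            if (is.null(ecr)) "" else ecr$raw
          )
        }
        rec$raw_fields["Public Title"] <- "A randomised controlled clinical study"
        truth <- log_injection(truth, "R11", "site", i)
      }
    },
    R12 = {
      i <- pick_site()
      specialty <- sample(c("Cardiology", "Neurology", "Oncology", "Paediatrics",
                            "Dermatology", "Psychiatry"), 1)
      rec$sites$name_raw[i] <- paste("Department of", specialty)
      truth <- log_injection(truth, "R12", "site", i)
    },
    R13 = {
      j <- pick_ec()
      i <- min(j, n_sites)
      rec$ecs$name_raw[j] <- paste("IEC", rec$sites$pi_name_raw[i])
      truth <- log_injection(truth, "R13", "ec", j)
    },
    R14 = {
      # make the trial eligible (post-rule registration, >= 2 sites, fewer
      # ECs than sites), then force a city mismatch on site 2
      if (!is.na(rec$registration_date) && rec$registration_date < shared_ec_rule_date) {
        rec$registration_date <- shared_ec_rule_date + sample(10:600, 1)
        rec$enrollment_start_date <- rec$registration_date + sample(30:300, 1)
      }
      if (n_sites < 2) {
        inst <- other_inst()
        rec$sites <- rbind(rec$sites, site_table(inst$name,
                                                 random_address(inst$city),
                                                 random_pi()))
        n_sites <- nrow(rec$sites)
      }
      rec$ecs <- rec$ecs[1, , drop = FALSE]
      ec_city <- normalize_text(rec$ecs$name_raw[1])$city
      site2_city <- normalize_text(rec$sites$address_raw[2])$city
      if (!is.na(ec_city) && (is.na(site2_city) || identical(site2_city, ec_city))) {
        if (is.null(pool)) stop("injector needs the institution pool")
        diff_city <- pool[tolower(pool$city) != ec_city, ]
        inst <- diff_city[sample(nrow(diff_city), 1), ]
        rec$sites$name_raw[2] <- inst$name
        rec$sites$address_raw[2] <- random_address(inst$city)
      }
      truth$true_mapping <- c(1L, rep(NA_integer_, n_sites - 1))
      truth <- log_injection(truth, "R14", "site", 2)
    },
    R15 = {
      if (!is.na(rec$registration_date)) {
        rec$enrollment_start_date <- rec$registration_date - sample(200:2000, 1)
        truth <- log_injection(truth, "R15", "trial", NA)
      }
    },
    stop("unknown rule id: ", rule)
  )
  rec$norm <- NULL
  list(record = rec, truth = truth)
}

inject_typo <- function(rec, truth) {
  targets <- c(seq_len(nrow(rec$sites)), -seq_len(nrow(rec$ecs)))
  if (length(targets) == 0) return(list(record = rec, truth = truth))
  tgt <- sample(targets, 1)
  get_name <- function() if (tgt > 0) rec$sites$name_raw[tgt] else rec$ecs$name_raw[-tgt]
  nm <- get_name()
  letters_at <- which(strsplit(nm, "")[[1]] %in% c(letters, LETTERS))
  if (length(letters_at) < 4) return(list(record = rec, truth = truth))
  pos <- sample(letters_at, 1)
  mutated <- if (runif(1) < 0.5) {
    # substitution
    paste0(substr(nm, 1, pos - 1), sample(letters, 1), substr(nm, pos + 1, nchar(nm)))
  } else {
    # deletion
    paste0(substr(nm, 1, pos - 1), substr(nm, pos + 1, nchar(nm)))
  }
  if (tgt > 0) rec$sites$name_raw[tgt] <- mutated else rec$ecs$name_raw[-tgt] <- mutated
  truth <- log_injection(truth, "TYPO", if (tgt > 0) "site" else "ec", abs(tgt))
  rec$norm <- NULL
  list(record = rec, truth = truth)
}

#' Precision and recall of one rule on the synthetic benchmark
#'
#' Generates (or reuses) a clean cohort, injects a single deficiency type at
#' the given rate, lints every record, and compares rule hits against the
#' injected truth at trial granularity.
#'
#' @param rule_id One of R01..R15.
#' @param n Number of trials (default 1000).
#' @param rate Injection rate (default 0.3).
#' @param seed Seed for generation and injection.
#' @param base Optional pre-generated clean cohort (a [generate_trials()]
#'   result with no injections) to reuse across rules.
#' @return A list with `rule_id`, `precision`, `recall`, `tp`, `fp`, `fn`,
#'   `n`.
#' @export
rule_benchmark <- function(rule_id, n = 1000, rate = 0.3, seed = 42L,
                           base = NULL) {
  if (is.null(base)) {
    base <- generate_trials(generator_config(n_trials = n, seed = seed))
  }
  inj <- inject_deficiencies(base$records, base$truths,
                             rates = setNames(rate, rule_id),
                             seed = seed + 104729L, pool = base$pool)
  truth_ids <- vapply(inj$truths, function(tr) {
    if (any(tr$injected$rule_id == rule_id)) tr$ctri_id else NA_character_
  }, character(1))
  truth_ids <- truth_ids[!is.na(truth_ids)]
  hit_ids <- vapply(inj$records, function(r) {
    f <- lint_trial(r)
    if (any(f$rule_id == rule_id)) r$ctri_id else NA_character_
  }, character(1))
  hit_ids <- hit_ids[!is.na(hit_ids)]
  tp <- length(intersect(hit_ids, truth_ids))
  fp <- length(setdiff(hit_ids, truth_ids))
  fn <- length(setdiff(truth_ids, hit_ids))
  list(
    rule_id = rule_id,
    precision = if (tp + fp > 0) tp / (tp + fp) else 1,
    recall = if (tp + fn > 0) tp / (tp + fn) else 1,
    tp = tp, fp = fp, fn = fn, n = length(inj$records)
  )
}
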