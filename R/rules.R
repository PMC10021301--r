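# The deficiency linter.
#
# Per-trial rules R01-R15 cover the deficiency taxonomy observed in registry
# EC/site fields (blank EC tables, count mismatches, repeated rows, generic
# or casual committee names, message text, file numbers in place of names,
# missing CDSCO registration numbers, unexpanded acronyms, missing
# organisation names, person-name-only committees, the post-2019 same-city
# condition for shared committees, retrospective registration). Cross-trial
# rules C01-C03 need the whole collection. Severities are this package's
# own ranking: "error" marks entries that should block registration.

#' The rule catalogue
#'
#' @return A tibble with columns `rule_id`, `scope`, `severity`, `title`,
#'   `description`.
#' @export
rule_catalogue <- function() {
  tibble::tribble(
    ~rule_id, ~scope, ~severity, ~title, ~description,
    "R01", "trial", "error", "no_ec_listed",
    "Interventional trial with an empty EC table.",
    "R02", "trial", "warning", "count_mismatch",
    "Number of site rows differs from number of EC rows (EC table non-empty).",
    "R03", "ec", "warning", "repeated_ec",
    "The same committee name (canonical form) is listed more than once.",
    "R04", "site", "error", "repeated_site_same_pi",
    "A site is listed more than once with the same principal investigator.",
    "R05", "site", "warning", "repeated_site_diff_pi",
    "A site is listed more than once with different principal investigators.",
    "R06", "ec", "warning", "generic_ec_name",
    "Generic or casual committee name that does not identify an institution.",
    "R07", "ec", "error", "ec_is_message",
    "The committee field holds free-text correspondence, not a name.",
    "R08", "ec", "error", "ec_is_site_echo",
    "The committee field repeats a site name and carries no committee wording.",
    "R09", "ec", "warning", "ec_file_number_only",
    "What appears to be an EC file number is listed instead of the name.",
    "R10", "ec", "info", "missing_ecr",
    "No CDSCO EC registration number (ECR/...) accompanies the committee name.",
    "R11", "trial", "warning", "unexpanded_acronym",
    "An acronym in a site or EC name is not spelled out anywhere in the record.",
    "R12", "site", "warning", "site_name_missing_org",
    "Neither the site name nor the address identifies an organisation.",
    "R13", "ec", "info", "ec_person_name_only",
    "Only a doctor's name is linked to the committee.",
    "R14", "site", "warning", "shared_ec_city_rule",
    "Post 2019-03-25 trial sharing ECs across sites: a site's city matches no EC city.",
    "R15", "trial", "info", "retrospective_registration",
    "Enrollment started before the registry entry was created.",
    "C01", "cross_trial", "warning", "acronym_collision",
    "One acronym stands for two or more distinct organisations across trials.",
    "C02", "cross_trial", "warning", "shared_file_number",
    "The same EC file number appears in two or more trials.",
    "C03", "cross_trial", "info", "inconsistent_ec_naming",
    "The same organisation lists its committee under different names across trials.",
  )
}

shared_ec_rule_date <- as.Date("2019-03-25")

finding <- function(rule_id, ctri_id, scope, severity, evidence,
                    site_index = NA_integer_, ec_index = NA_integer_) {
  tibble::tibble(
    rule_id = rule_id, ctri_id = ctri_id, scope = scope, severity = severity,
    site_index = as.integer(site_index), ec_index = as.integer(ec_index),
    evidence = evidence
  )
}

empty_findings <- function() {
  tibble::tibble(
    rule_id = character(0), ctri_id = character(0), scope = character(0),
    severity = character(0), site_index = integer(0), ec_index = integer(0),
    evidence = character(0)
  )
}

#' Lint one trial record
#'
#' Applies every per-trial rule of the [rule_catalogue()] deterministically.
#'
#' @param trial A `ctri_record`.
#' @return A findings tibble (`rule_id`, `ctri_id`, `scope`, `severity`,
#'   `site_index`, `ec_index`, `evidence`); zero rows for a clean record.
#' @export
lint_trial <- function(trial) {
  trial <- normalize_record(trial)
  nrm <- trial$norm
  id <- trial$ctri_id
  n_sites <- nrow(trial$sites)
  n_ecs <- nrow(trial$ecs)
  out <- list()

  if (trial$trial_type == "Interventional" && n_ecs == 0) {
    out[[length(out) + 1]] <- finding(
      "R01", id, "trial", "error",
      sprintf("interventional trial with %d site(s) and no EC listed", n_sites)
    )
  }
  if (n_ecs > 0 && n_sites != n_ecs) {
    out[[length(out) + 1]] <- finding(
      "R02", id, "trial", "warning",
      sprintf("%d site(s) but %d EC(s)", n_sites, n_ecs)
    )
  }

  # repeated ECs (identical canonical names)
  ec_canon <- vapply(nrm$ecs, function(e) e$canonical, character(1))
  nz <- which(nzchar(ec_canon))
  if (length(nz) > 1) {
    for (cn in unique(ec_canon[nz][duplicated(ec_canon[nz])])) {
      idx <- which(ec_canon == cn)
      out[[length(out) + 1]] <- finding(
        "R03", id, "ec", "warning",
        sprintf("EC rows %s share the name '%s'", paste(idx, collapse = ","),
                trial$ecs$name_raw[idx[1]]),
        ec_index = idx[1]
      )
    }
  }

  # repeated sites, same vs different PI
  site_canon <- vapply(nrm$sites, function(s) s$canonical, character(1))
  pi_canon <- vapply(nrm$pis, function(p) p$canonical, character(1))
  nz <- which(nzchar(site_canon))
  if (length(nz) > 1) {
    for (cn in unique(site_canon[nz][duplicated(site_canon[nz])])) {
      idx <- which(site_canon == cn)
      same_pi <- length(unique(pi_canon[idx])) == 1
      out[[length(out) + 1]] <- finding(
        if (same_pi) "R04" else "R05", id, "site",
        if (same_pi) "error" else "warning",
        sprintf("site rows %s repeat '%s' with %s PI",
                paste(idx, collapse = ","), trial$sites$name_raw[idx[1]],
                if (same_pi) "the same" else "different"),
        site_index = idx[1]
      )
    }
  }

  for (j in seq_len(n_ecs)) {
    e <- nrm$ecs[[j]]
    raw <- trial$ecs$name_raw[j]
    if (e$is_generic_ec) {
      out[[length(out) + 1]] <- finding(
        "R06", id, "ec", "warning",
        sprintf("generic/casual EC name '%s'", raw), ec_index = j
      )
    }
    if (e$is_message) {
      out[[length(out) + 1]] <- finding(
        "R07", id, "ec", "error",
        sprintf("EC field holds message text: '%s'", substr(raw, 1, 80)),
        ec_index = j
      )
    }
    if (nzchar(e$canonical) && e$canonical %in% site_canon &&
        !any(e$tokens %in% ec_term_tokens)) {
      out[[length(out) + 1]] <- finding(
        "R08", id, "ec", "error",
        sprintf("EC field repeats site name '%s'", raw), ec_index = j
      )
    }
    if (e$is_file_number) {
      out[[length(out) + 1]] <- finding(
        "R09", id, "ec", "warning",
        sprintf("EC field appears to be a file number: '%s'", raw), ec_index = j
      )
    }
    if (!e$has_ecr && nzchar(raw)) {
      out[[length(out) + 1]] <- finding(
        "R10", id, "ec", "info",
        sprintf("no EC registration number (ECR) in '%s'", substr(raw, 1, 80)),
        ec_index = j
      )
    }
    person_only <- length(e$person_names) > 0 && ec_person_name_only(e)
    if (person_only) {
      out[[length(out) + 1]] <- finding(
        "R13", id, "ec", "info",
        sprintf("only a doctor's name identifies the EC: '%s'", raw), ec_index = j
      )
    }
  }

  # unexpanded acronyms: literal acronyms in site/EC names with no expansion
  # anywhere in the record
  acr <- unique(unlist(c(
    lapply(nrm$sites, function(s) s$acronyms),
    lapply(nrm$ecs, function(e) e$acronyms)
  )))
  if (length(acr) > 0) {
    expansions <- record_expansions(trial)
    for (a in acr) {
      if (!(a %in% expansions)) {
        out[[length(out) + 1]] <- finding(
          "R11", id, "trial", "warning",
          sprintf("acronym '%s' is not spelled out anywhere in the record", a)
        )
      }
    }
  }

  for (i in seq_len(n_sites)) {
    s <- nrm$sites[[i]]
    a <- nrm$addresses[[i]]
    if (!any(s$tokens %in% institution_keywords) &&
        !any(a$tokens %in% institution_keywords)) {
      out[[length(out) + 1]] <- finding(
        "R12", id, "site", "warning",
        sprintf("no organisation name in site name or address ('%s')",
                trial$sites$name_raw[i]),
        site_index = i
      )
    }
  }

  # post-2019 shared-EC city condition (city equality as the implementable
  # proxy for the same-city / 50 km requirement)
  if (!is.na(trial$registration_date) &&
      trial$registration_date >= shared_ec_rule_date &&
      n_ecs >= 1 && n_ecs < n_sites) {
    ec_cities <- nrm$ec_city[!is.na(nrm$ec_city)]
    if (length(ec_cities) > 0) {
      for (i in seq_len(n_sites)) {
        ct <- nrm$site_city[[i]]
        if (!is.na(ct) && !(ct %in% ec_cities)) {
          out[[length(out) + 1]] <- finding(
            "R14", id, "site", "warning",
            sprintf("site %d is in '%s' but the listed EC(s) are in '%s'",
                    i, ct, paste(unique(ec_cities), collapse = ", ")),
            site_index = i
          )
        }
      }
    }
  }

  if (!is.na(trial$registration_date) && !is.na(trial$enrollment_start_date) &&
      trial$enrollment_start_date < trial$registration_date) {
    out[[length(out) + 1]] <- finding(
      "R15", id, "trial", "info",
      sprintf("enrollment started %s, before registration on %s",
              format(trial$enrollment_start_date), format(trial$registration_date))
    )
  }

  if (length(out) == 0) empty_findings() else do.call(rbind, out)
}

# nothing identifies the committee once the doctor's name, honorifics and
# committee words are removed
ec_person_name_only <- function(e) {
  person_tokens <- unlist(lapply(e$person_names, function(p) {
    strsplit(canonicalize(p), " ", fixed = TRUE)[[1]]
  }))
  residual <- e$tokens[!(e$tokens %in% c(
    person_tokens, "dr", "prof", "professor", "mr", "mrs", "ms",
    ec_term_tokens, connective_tokens, roman_numeral_tokens
  ))]
  residual <- residual[!grepl("^[0-9]+$", residual)]
  length(residual) == 0
}

# every text in the record that could spell out an acronym, reduced to the
# acronyms it would generate
record_expansions <- function(trial) {
  texts <- c(
    trial$sites$name_raw, trial$sites$address_raw,
    trial$ecs$name_raw, unname(trial$raw_fields)
  )
  out <- character(0)
  for (tx in texts) {
    d <- derive_acronym(tx)
    if (!is.na(d)) out <- c(out, d)
    # also title-case runs inside longer text (e.g. the public title)
    runs <- regmatches(tx, gregexpr(
      "([A-Z][a-z]+(?:\\s+(?:of|and|the|for|in)\\s+|\\s+)){1,7}[A-Z][a-z]+", tx
    ))[[1]]
    for (r in runs) {
      d <- derive_acronym(r)
      if (!is.na(d)) out <- c(out, d)
    }
  }
  unique(out)
}

#' Lint a whole collection, adding cross-trial rules
#'
#' Runs [lint_trial()] on every record, then the cross-trial rules: C01
#' (one acronym naming two or more distinct site organisations across
#' trials), C02 (identical EC file-number strings in two or more trials),
#' C03 (the same organisation listing its committee under different names).
#'
#' @param records List of `ctri_record`s.
#' @return A findings tibble; cross-trial findings carry the involved ids in
#'   `evidence` and the first id in `ctri_id`.
#' @export
lint_cohort <- function(records) {
  per_trial <- lapply(records, lint_trial)
  records <- lapply(records, normalize_record)
  cross <- list()

  # C01: acronym -> distinct site organisations, spanning >= 2 trials
  acr_map <- list()
  for (r in records) {
    for (i in seq_len(nrow(r$sites))) {
      s <- r$norm$sites[[i]]
      keys <- c(s$acronyms, if (!is.na(s$acronym_derived)) s$acronym_derived)
      org <- s$canonical
      if (!nzchar(org)) next
      for (k in unique(keys)) {
        acr_map[[k]] <- rbind(acr_map[[k]],
                              data.frame(org = org, id = r$ctri_id,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  for (k in names(acr_map)) {
    m <- unique(acr_map[[k]])
    orgs <- unique(m$org)
    # an all-caps site name equal to the acronym is a use, not another org
    orgs_named <- orgs[orgs != tolower(k)]
    ids <- unique(m$id)
    if (length(orgs_named) >= 2 && length(ids) >= 2) {
      cross[[length(cross) + 1]] <- finding(
        "C01", ids[1], "cross_trial", "warning",
        sprintf("acronym '%s' stands for %d organisations (%s) in trials %s",
                k, length(orgs_named), paste(orgs_named, collapse = " | "),
                paste(ids, collapse = ","))
      )
    }
  }

  # C02: identical file-number strings across trials
  fn_map <- list()
  for (r in records) {
    for (j in seq_len(nrow(r$ecs))) {
      e <- r$norm$ecs[[j]]
      if (e$is_file_number) {
        fn_map[[e$canonical]] <- unique(c(fn_map[[e$canonical]], r$ctri_id))
      }
    }
  }
  for (k in names(fn_map)) {
    ids <- fn_map[[k]]
    if (length(ids) >= 2) {
      cross[[length(cross) + 1]] <- finding(
        "C02", ids[1], "cross_trial", "warning",
        sprintf("EC file number '%s' appears in %d trials: %s",
                k, length(ids), paste(ids, collapse = ","))
      )
    }
  }

  # C03: same organisation (sorted institution tokens), different EC names
  org_map <- list()
  for (r in records) {
    for (j in seq_len(nrow(r$ecs))) {
      core <- r$norm$ec_core[[j]]
      full <- r$norm$ecs[[j]]
      if (length(core$tokens) == 0) next
      key <- paste(sort(unique(core$tokens)), collapse = " ")
      org_map[[key]] <- rbind(org_map[[key]],
                              data.frame(variant = full$canonical, id = r$ctri_id,
                                         stringsAsFactors = FALSE))
    }
  }
  for (k in names(org_map)) {
    m <- unique(org_map[[k]])
    variants <- unique(m$variant)
    ids <- unique(m$id)
    if (length(variants) >= 2 && length(ids) >= 2) {
      cross[[length(cross) + 1]] <- finding(
        "C03", ids[1], "cross_trial", "info",
        sprintf("organisation '%s' appears with %d EC name variants in trials %s",
                k, length(variants), paste(ids, collapse = ","))
      )
    }
  }

  parts <- c(per_trial, cross)
  parts <- parts[vapply(parts, nrow, integer(1)) > 0]
  if (length(parts) == 0) empty_findings() else do.call(rbind, parts)
}

#' Registration-time validation
#'
#' A pure function of the record: rejects when any error-severity rule (R01
#' blank EC table, R04 repeated site with the same PI, R07 message text in
#' the EC field, R08 site name echoed as the EC) fires.
#'
#' @param trial A `ctri_record`.
#' @return A list with `accept` (logical), `blocking` (the error findings)
#'   and `findings` (all findings).
#' @export
validate_for_registration <- function(trial) {
  f <- lint_trial(trial)
  blocking <- f[f$severity == "error", , drop = FALSE]
  list(accept = nrow(blocking) == 0, blocking = blocking, findings = f)
}
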