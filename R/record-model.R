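# The trial-record data model.
#
# A `ctri_record` is a list: identity, dates, type/phase/status, a site table,
# an EC table and a bag of verbatim raw fields. Site and EC tables preserve
# source row order; verbatim text is never rewritten -- normalized companions
# are attached separately by normalize_record().

ctri_id_regex <- "^CTRI/[0-9]{4}/[0-9]{2}/[0-9]{6}$"

trial_types <- c("Interventional", "Observational", "PMS", "BA/BE")

recruitment_statuses <- c(
  "Open", "Closed to Recruitment", "Completed", "Not Yet Recruiting", "Other"
)

#' Build a site table
#'
#' @param name_raw,address_raw,pi_name_raw Character vectors (recycled to a
#'   common length); verbatim source text. Any may be empty strings.
#' @return A tibble with columns `name_raw`, `address_raw`, `pi_name_raw`.
#' @export
site_table <- function(name_raw = character(0), address_raw = "", pi_name_raw = "") {
  if (length(name_raw) == 0) {
    return(tibble::tibble(
      name_raw = character(0), address_raw = character(0), pi_name_raw = character(0)
    ))
  }
  tibble::tibble(
    name_raw = as.character(name_raw),
    address_raw = rep_len(as.character(address_raw), length(name_raw)),
    pi_name_raw = rep_len(as.character(pi_name_raw), length(name_raw))
  )
}

#' Build an ethics-committee table
#'
#' @param name_raw,approval_status_raw Character vectors (recycled); verbatim
#'   source text of *Name of the Committee* and its approval status.
#' @return A tibble with columns `name_raw`, `approval_status_raw`.
#' @export
ec_table <- function(name_raw = character(0), approval_status_raw = "Approved") {
  if (length(name_raw) == 0) {
    return(tibble::tibble(name_raw = character(0), approval_status_raw = character(0)))
  }
  tibble::tibble(
    name_raw = as.character(name_raw),
    approval_status_raw = rep_len(as.character(approval_status_raw), length(name_raw))
  )
}

#' Construct a trial record
#'
#' @param ctri_id Registry identifier matching `CTRI/YYYY/MM/NNNNNN`.
#' @param registration_date,enrollment_start_date `Date` scalars or `NA`.
#' @param trial_type One of "Interventional", "Observational", "PMS", "BA/BE".
#' @param phase_label Verbatim phase text, e.g. `"Phase 2/ Phase 3"`.
#' @param recruitment_status_india Recruitment status for India; free text is
#'   mapped onto the registry's options, anything unrecognised becomes
#'   "Other".
#' @param sites A tibble from [site_table()] (may have zero rows).
#' @param ecs A tibble from [ec_table()] (may have zero rows).
#' @param raw_fields Named character vector of all other captured fields,
#'   verbatim.
#' @return An object of class `ctri_record`. The parsed phase set is stored
#'   in `$phases` (subset of "P1".."P4"); `$phase_parse_warning` is `TRUE`
#'   when the label contained tokens that could not be mapped.
#' @export
trial_record <- function(ctri_id,
                         registration_date = as.Date(NA),
                         enrollment_start_date = as.Date(NA),
                         trial_type = "Interventional",
                         phase_label = "",
                         recruitment_status_india = "Other",
                         sites = site_table(),
                         ecs = ec_table(),
                         raw_fields = character(0)) {
  if (!is.character(ctri_id) || length(ctri_id) != 1 || !grepl(ctri_id_regex, ctri_id)) {
    stop("ctri_id must match CTRI/YYYY/MM/NNNNNN, got: ", ctri_id)
  }
  if (!trial_type %in% trial_types) {
    stop("unknown trial_type: ", trial_type)
  }
  phases <- parse_phases(phase_label)
  rec <- list(
    ctri_id = ctri_id,
    registration_date = as.Date(registration_date),
    enrollment_start_date = as.Date(enrollment_start_date),
    trial_type = trial_type,
    phase_label = phase_label,
    phases = phases$phases,
    phase_parse_warning = phases$warning,
    recruitment_status_india = map_recruitment_status(recruitment_status_india),
    sites = sites,
    ecs = ecs,
    raw_fields = raw_fields
  )
  structure(rec, class = "ctri_record")
}

#' @export
print.ctri_record <- function(x, ...) {
  cat("<ctri_record>", x$ctri_id, "\n")
  cat("  ", x$trial_type, "| phase:", x$phase_label,
      "| status:", x$recruitment_status_india, "\n")
  cat("  registered:", format(x$registration_date),
      "| sites:", nrow(x$sites), "| ECs:", nrow(x$ecs), "\n")
  invisible(x)
}

# "Phase 2/ Phase 3" -> {P2, P3}; tokens without a leading phase digit give an
# empty contribution and set the parse-warning flag
parse_phases <- function(phase_label) {
  if (is.na(phase_label) || !nzchar(trimws(phase_label))) {
    return(list(phases = character(0), warning = FALSE))
  }
  tokens <- trimws(strsplit(phase_label, "/", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  digits <- regmatches(tokens, regexpr("[1-4]", tokens))
  ok <- lengths(regmatches(tokens, gregexpr("[1-4]", tokens))) > 0
  phases <- unique(paste0("P", unlist(regmatches(tokens, regexpr("[1-4]", tokens)))))
  list(phases = sort(phases[nzchar(phases) & phases != "P"]),
       warning = any(!ok))
}

map_recruitment_status <- function(status) {
  if (is.na(status) || !nzchar(trimws(status))) return("Other")
  s <- tolower(trimws(status))
  if (grepl("^open", s)) return("Open")
  if (grepl("^closed", s)) return("Closed to Recruitment")
  if (grepl("^completed", s)) return("Completed")
  if (grepl("^not yet", s)) return("Not Yet Recruiting")
  "Other"
}

# CTRI prints dates as DD/MM/YYYY; unparseable input gives NA (the verbatim
# text stays in raw_fields)
parse_ctri_date <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(as.Date(NA))
  d <- as.Date(trimws(x), format = "%d/%m/%Y")
  if (is.na(d)) d <- suppressWarnings(as.Date(trimws(x), format = "%Y-%m-%d"))
  d
}

#' Attach normalized companions to a record
#'
#' Computes the [normalize_text()] form of every site name, PI name and EC
#' name, the institution-part of every EC name, and each site's city (from
#' the site name, falling back to the address). Idempotent; results are
#' cached on the record under `$norm`.
#'
#' @param trial A `ctri_record`.
#' @return The record with a `$norm` element: lists `sites`, `site_core`
#'   (unused alias), `pis`, `ecs`, `ec_core` and vectors `site_city`,
#'   `ec_city`.
#' @export
normalize_record <- function(trial) {
  stopifnot(inherits(trial, "ctri_record"))
  if (!is.null(trial$norm)) return(trial)
  sites <- lapply(trial$sites$name_raw, normalize_text)
  addrs <- lapply(trial$sites$address_raw, normalize_text)
  pis <- lapply(trial$sites$pi_name_raw, function(p) {
    normalize_text(gsub(honorific_pattern, "", p, perl = TRUE))
  })
  ecs <- lapply(trial$ecs$name_raw, normalize_text)
  ec_core <- lapply(trial$ecs$name_raw, strip_ec_terms)
  site_city <- vapply(seq_along(sites), function(i) {
    c1 <- sites[[i]]$city
    if (!is.na(c1)) c1 else addrs[[i]]$city
  }, character(1))
  ec_city <- vapply(ecs, function(e) e$city, character(1))
  trial$norm <- list(
    sites = sites, addresses = addrs, pis = pis,
    ecs = ecs, ec_core = ec_core,
    site_city = site_city, ec_city = ec_city
  )
  trial
}

# plain-list view of a record for JSON interchange
record_to_list <- function(rec) {
  list(
    ctri_id = rec$ctri_id,
    registration_date = if (is.na(rec$registration_date)) NULL else format(rec$registration_date),
    enrollment_start_date = if (is.na(rec$enrollment_start_date)) NULL else format(rec$enrollment_start_date),
    trial_type = rec$trial_type,
    phase_label = rec$phase_label,
    recruitment_status_india = rec$recruitment_status_india,
    sites = lapply(seq_len(nrow(rec$sites)), function(i) as.list(rec$sites[i, ])),
    ecs = lapply(seq_len(nrow(rec$ecs)), function(i) as.list(rec$ecs[i, ])),
    raw_fields = as.list(rec$raw_fields)
  )
}

list_to_record <- function(x) {
  sites <- if (length(x$sites)) {
    site_table(
      name_raw = vapply(x$sites, function(s) s$name_raw %||% "", character(1)),
      address_raw = vapply(x$sites, function(s) s$address_raw %||% "", character(1)),
      pi_name_raw = vapply(x$sites, function(s) s$pi_name_raw %||% "", character(1))
    )
  } else site_table()
  ecs <- if (length(x$ecs)) {
    ec_table(
      name_raw = vapply(x$ecs, function(e) e$name_raw %||% "", character(1)),
      approval_status_raw = vapply(x$ecs, function(e) e$approval_status_raw %||% "", character(1))
    )
  } else ec_table()
  raw_fields <- unlist(x$raw_fields %||% list())
  if (is.null(raw_fields)) raw_fields <- character(0)
  trial_record(
    ctri_id = x$ctri_id,
    registration_date = if (is.null(x$registration_date)) as.Date(NA) else as.Date(x$registration_date),
    enrollment_start_date = if (is.null(x$enrollment_start_date)) as.Date(NA) else as.Date(x$enrollment_start_date),
    trial_type = x$trial_type,
    phase_label = x$phase_label %||% "",
    recruitment_status_india = x$recruitment_status_india %||% "Other",
    sites = sites,
    ecs = ecs,
    raw_fields = raw_fields
  )
}

# comparable view: drops normalization cache so generator output and a
# reloaded snapshot compare field-equal
record_essence <- function(rec) {
  rec$norm <- NULL
  rec[order(names(rec))]
}

#' Check that a collection of records has unique registry identifiers
#' @param records List of `ctri_record`s.
#' @return Invisibly `TRUE`; errors naming the first duplicated id otherwise.
#' @export
assert_unique_ids <- function(records) {
  ids <- vapply(records, function(r) r$ctri_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate ctri_id in collection: ", dup[1])
  }
  invisible(TRUE)
}
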