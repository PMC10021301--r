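# Snapshot storage and JSON Lines interchange.
#
# A snapshot is a directory of four relational CSV tables -- trial, site, ec,
# raw_field -- keyed by ctri_id plus row index, and a schema.json carrying the
# format version. Output is byte-stable for a fixed input: fixed column
# order, rows sorted by (ctri_id, index), no timestamps.

snapshot_schema_version <- 1L

#' Save a record collection as a relational snapshot
#'
#' @param records List of `ctri_record`s with unique ids.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_snapshot <- function(records, path) {
  assert_unique_ids(records)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create snapshot directory: ", path)
  }
  ids <- vapply(records, function(r) r$ctri_id, character(1))
  records <- records[order(ids)]

  trial <- tibble::tibble(
    ctri_id = vapply(records, function(r) r$ctri_id, character(1)),
    registration_date = vapply(records, function(r) {
      if (is.na(r$registration_date)) "" else format(r$registration_date)
    }, character(1)),
    enrollment_start_date = vapply(records, function(r) {
      if (is.na(r$enrollment_start_date)) "" else format(r$enrollment_start_date)
    }, character(1)),
    trial_type = vapply(records, function(r) r$trial_type, character(1)),
    phase_label = vapply(records, function(r) r$phase_label, character(1)),
    recruitment_status_india = vapply(records, function(r) r$recruitment_status_india, character(1))
  )

  bind_indexed <- function(extract, empty) {
    parts <- lapply(records, extract)
    if (length(parts) == 0) return(empty)
    do.call(rbind, parts)
  }
  empty_site <- tibble::tibble(ctri_id = character(0), site_index = integer(0),
                               name_raw = character(0), address_raw = character(0),
                               pi_name_raw = character(0))
  empty_ec <- tibble::tibble(ctri_id = character(0), ec_index = integer(0),
                             name_raw = character(0), approval_status_raw = character(0))
  empty_rf <- tibble::tibble(ctri_id = character(0), field = character(0),
                             value = character(0))
  site <- bind_indexed(function(r) {
    n <- nrow(r$sites)
    tibble::tibble(
      ctri_id = rep(r$ctri_id, n), site_index = seq_len(n),
      name_raw = r$sites$name_raw, address_raw = r$sites$address_raw,
      pi_name_raw = r$sites$pi_name_raw
    )
  }, empty_site)
  ec <- bind_indexed(function(r) {
    n <- nrow(r$ecs)
    tibble::tibble(
      ctri_id = rep(r$ctri_id, n), ec_index = seq_len(n),
      name_raw = r$ecs$name_raw, approval_status_raw = r$ecs$approval_status_raw
    )
  }, empty_ec)
  raw_field <- bind_indexed(function(r) {
    tibble::tibble(
      ctri_id = rep(r$ctri_id, length(r$raw_fields)),
      field = names(r$raw_fields) %||% character(0),
      value = unname(r$raw_fields)
    )
  }, empty_rf)

  readr::write_csv(trial, file.path(path, "trial.csv"), eol = "\n", progress = FALSE)
  readr::write_csv(site, file.path(path, "site.csv"), eol = "\n", progress = FALSE)
  readr::write_csv(ec, file.path(path, "ec.csv"), eol = "\n", progress = FALSE)
  readr::write_csv(raw_field, file.path(path, "raw_field.csv"), eol = "\n", progress = FALSE)
  writeLines(
    jsonlite::toJSON(
      list(format = "ctriaudit-snapshot", version = snapshot_schema_version),
      auto_unbox = TRUE
    ),
    file.path(path, "schema.json"), useBytes = TRUE
  )
  invisible(path)
}

#' Load a relational snapshot
#'
#' @param path Snapshot directory written by [save_snapshot()].
#' @return List of `ctri_record`s, one per trial table row; errors on a
#'   schema-version mismatch or a duplicated ctri_id.
#' @export
load_snapshot <- function(path) {
  schema_path <- file.path(path, "schema.json")
  if (!file.exists(schema_path)) {
    stop("not a snapshot directory (missing schema.json): ", path)
  }
  schema <- jsonlite::fromJSON(schema_path)
  if (!identical(schema$format, "ctriaudit-snapshot") ||
      !identical(as.integer(schema$version), snapshot_schema_version)) {
    stop("snapshot schema version mismatch: found ",
         schema$format %||% "?", " v", schema$version %||% "?",
         ", this package reads ctriaudit-snapshot v", snapshot_schema_version)
  }
  ctypes <- readr::cols(.default = readr::col_character())
  itypes <- function(idx) {
    args <- list(.default = readr::col_character())
    args[[idx]] <- readr::col_integer()
    do.call(readr::cols, args)
  }
  trial <- readr::read_csv(file.path(path, "trial.csv"), col_types = ctypes, progress = FALSE)
  site <- readr::read_csv(file.path(path, "site.csv"), col_types = itypes("site_index"), progress = FALSE)
  ec <- readr::read_csv(file.path(path, "ec.csv"), col_types = itypes("ec_index"), progress = FALSE)
  raw_field <- readr::read_csv(file.path(path, "raw_field.csv"), col_types = ctypes, progress = FALSE)

  dup <- trial$ctri_id[duplicated(trial$ctri_id)]
  if (length(dup) > 0) stop("duplicate ctri_id in snapshot: ", dup[1])

  blank <- function(x) ifelse(is.na(x), "", x)
  site_split <- split(seq_len(nrow(site)), site$ctri_id)
  ec_split <- split(seq_len(nrow(ec)), ec$ctri_id)
  rf_split <- split(seq_len(nrow(raw_field)), raw_field$ctri_id)

  lapply(seq_len(nrow(trial)), function(i) {
    id <- trial$ctri_id[i]
    si <- site_split[[id]]
    si <- si[order(site$site_index[si])]
    ei <- ec_split[[id]]
    ei <- ei[order(ec$ec_index[ei])]
    ri <- rf_split[[id]]
    sites <- if (length(si)) {
      site_table(blank(site$name_raw[si]), blank(site$address_raw[si]), blank(site$pi_name_raw[si]))
    } else site_table()
    ecs <- if (length(ei)) {
      ec_table(blank(ec$name_raw[ei]), blank(ec$approval_status_raw[ei]))
    } else ec_table()
    rf <- if (length(ri)) {
      setNames(blank(raw_field$value[ri]), raw_field$field[ri])
    } else character(0)
    trial_record(
      ctri_id = id,
      registration_date = if (nzchar(blank(trial$registration_date[i]))) as.Date(trial$registration_date[i]) else as.Date(NA),
      enrollment_start_date = if (nzchar(blank(trial$enrollment_start_date[i]))) as.Date(trial$enrollment_start_date[i]) else as.Date(NA),
      trial_type = trial$trial_type[i],
      phase_label = blank(trial$phase_label[i]),
      recruitment_status_india = blank(trial$recruitment_status_india[i]),
      sites = sites,
      ecs = ecs,
      raw_fields = rf
    )
  })
}

#' Write records as JSON Lines
#'
#' One compact JSON object per line; the standard interchange format of this
#' package. Deterministic for a fixed input.
#'
#' @param records List of `ctri_record`s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(record_to_list(r), auto_unbox = TRUE, null = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read records from JSON Lines
#'
#' @param path File written by [write_jsonl()].
#' @return List of `ctri_record`s.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) list_to_record(jsonlite::fromJSON(ln, simplifyVector = FALSE)))
}

#' Export site and EC tables as CSV
#'
#' @param records List of `ctri_record`s.
#' @param site_path,ec_path Output CSV paths.
#' @return Invisibly, a list with the two tibbles.
#' @export
export_tables_csv <- function(records, site_path, ec_path) {
  site <- do.call(rbind, lapply(records, function(r) {
    n <- nrow(r$sites)
    if (n == 0) return(NULL)
    tibble::tibble(ctri_id = rep(r$ctri_id, n), site_index = seq_len(n),
                   name_raw = r$sites$name_raw, address_raw = r$sites$address_raw,
                   pi_name_raw = r$sites$pi_name_raw)
  }))
  ec <- do.call(rbind, lapply(records, function(r) {
    n <- nrow(r$ecs)
    if (n == 0) return(NULL)
    tibble::tibble(ctri_id = rep(r$ctri_id, n), ec_index = seq_len(n),
                   name_raw = r$ecs$name_raw, approval_status_raw = r$ecs$approval_status_raw)
  }))
  if (is.null(site)) site <- tibble::tibble(ctri_id = character(0), site_index = integer(0),
                                            name_raw = character(0), address_raw = character(0),
                                            pi_name_raw = character(0))
  if (is.null(ec)) ec <- tibble::tibble(ctri_id = character(0), ec_index = integer(0),
                                        name_raw = character(0), approval_status_raw = character(0))
  readr::write_csv(site, site_path, eol = "\n", progress = FALSE)
  readr::write_csv(ec, ec_path, eol = "\n", progress = FALSE)
  invisible(list(site = site, ec = ec))
}
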