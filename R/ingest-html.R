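# HTML ingest: CTRI record pages are label/value tables plus a sites table
# and an ethics-committee table. Parsing is keyed on the field labels, never
# on table position, so modest layout drift is tolerated.

field_labels <- list(
  ctri_id = "CTRI Number",
  registration_date = "Date of Registration",
  enrollment_start_date = "Date of First Enrollment (India)",
  trial_type = "Type of Trial",
  phase_label = "Phase",
  recruitment_status_india = "Recruitment Status of Trial (India)"
)

site_column_labels <- c("Name of Principal Investigator", "Name of Site", "Site Address")
ec_column_labels <- c("Name of Committee", "Approval Status")

#' Parse one CTRI-style record page
#'
#' Reads a single trial-record HTML document: two-cell rows of labelled field
#' tables become raw fields, a table headed by *Name of Site* becomes the
#' site table, and a table headed by *Name of Committee* becomes the EC
#' table. Row order is preserved; missing fields yield empty values, never
#' failure. The only hard requirement is a recognisable CTRI number.
#'
#' @param document HTML text, a file path, or an `xml2` document.
#' @return A `ctri_record`.
#' @export
parse_record_html <- function(document) {
  doc <- if (inherits(document, "xml_document")) {
    document
  } else if (is.character(document) && length(document) == 1 && file.exists(document)) {
    xml2::read_html(document)
  } else {
    xml2::read_html(paste(as.character(document), collapse = "\n"))
  }

  tables <- xml2::xml_find_all(doc, ".//table")
  raw_fields <- character(0)
  sites <- site_table()
  ecs <- ec_table()

  for (tab in tables) {
    rows <- xml2::xml_find_all(tab, ".//tr")
    if (length(rows) == 0) next
    header <- xml2::xml_text(xml2::xml_find_all(rows[[1]], ".//th|.//td"))
    header <- trimws(header)
    if (any(grepl("Name of Site", header, fixed = TRUE))) {
      sites <- parse_columnar_table(rows, header, site_column_labels,
                                    c("pi_name_raw", "name_raw", "address_raw"))
      sites <- site_table(sites$name_raw, sites$address_raw, sites$pi_name_raw)
    } else if (any(grepl("Name of Committee", header, fixed = TRUE))) {
      parsed <- parse_columnar_table(rows, header, ec_column_labels,
                                     c("name_raw", "approval_status_raw"))
      ecs <- ec_table(parsed$name_raw, parsed$approval_status_raw)
    } else {
      for (row in rows) {
        cells <- xml2::xml_text(xml2::xml_find_all(row, ".//td"))
        if (length(cells) == 2) {
          label <- trimws(cells[1])
          if (nzchar(label)) raw_fields[label] <- trimws(cells[2])
        }
      }
    }
  }

  id <- find_ctri_id(raw_fields)
  if (is.na(id)) {
    stop("not a CTRI record page: no 'CTRI Number' field (or CTRI/YYYY/MM/NNNNNN value) found")
  }

  get_field <- function(label) {
    hit <- which(names(raw_fields) == label)
    if (length(hit) == 0) "" else raw_fields[[hit[1]]]
  }

  trial_type <- trimws(get_field(field_labels$trial_type))
  if (!trial_type %in% trial_types) {
    trial_type <- if (grepl("^interventional", tolower(trial_type))) "Interventional"
      else if (grepl("^observational", tolower(trial_type))) "Observational"
      else if (grepl("pms|post.?marketing", tolower(trial_type))) "PMS"
      else if (grepl("ba\\s*/?\\s*be|bioavail", tolower(trial_type))) "BA/BE"
      else "Observational"
  }

  trial_record(
    ctri_id = id,
    registration_date = parse_ctri_date(get_field(field_labels$registration_date)),
    enrollment_start_date = parse_ctri_date(get_field(field_labels$enrollment_start_date)),
    trial_type = trial_type,
    phase_label = get_field(field_labels$phase_label),
    recruitment_status_india = get_field(field_labels$recruitment_status_india),
    sites = sites,
    ecs = ecs,
    raw_fields = raw_fields
  )
}

parse_columnar_table <- function(rows, header, labels, out_names) {
  idx <- vapply(labels, function(lbl) {
    hit <- which(grepl(lbl, header, fixed = TRUE))
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  out <- setNames(rep(list(character(0)), length(out_names)), out_names)
  if (length(rows) < 2) return(out)
  for (row in rows[-1]) {
    cells <- trimws(xml2::xml_text(xml2::xml_find_all(row, ".//td")))
    if (length(cells) == 0) next
    for (k in seq_along(labels)) {
      val <- if (!is.na(idx[k]) && idx[k] <= length(cells)) cells[idx[k]] else ""
      out[[out_names[k]]] <- c(out[[out_names[k]]], val)
    }
  }
  out
}

find_ctri_id <- function(raw_fields) {
  hit <- which(names(raw_fields) == field_labels$ctri_id)
  if (length(hit) > 0) {
    val <- regmatches(raw_fields[[hit[1]]],
                      regexpr("CTRI/[0-9]{4}/[0-9]{2}/[0-9]{6}", raw_fields[[hit[1]]]))
    if (length(val) == 1) return(val)
  }
  for (val in raw_fields) {
    m <- regmatches(val, regexpr("CTRI/[0-9]{4}/[0-9]{2}/[0-9]{6}", val))
    if (length(m) == 1) return(m)
  }
  NA_character_
}

#' Render a record as a CTRI-style HTML page
#'
#' The inverse of [parse_record_html()] for fixture building and round-trip
#' testing: labelled field rows, a *Sites of Study* table and an EC table.
#'
#' @param rec A `ctri_record`.
#' @param path Optional file path; when given the page is written there.
#' @return The HTML text, invisibly when `path` is given.
#' @export
write_record_html <- function(rec, path = NULL) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  fmt_date <- function(d) if (is.na(d)) "" else format(d, "%d/%m/%Y")

  fields <- c(
    setNames(rec$ctri_id, field_labels$ctri_id),
    setNames(fmt_date(rec$registration_date), field_labels$registration_date),
    setNames(fmt_date(rec$enrollment_start_date), field_labels$enrollment_start_date),
    setNames(rec$trial_type, field_labels$trial_type),
    setNames(rec$phase_label, field_labels$phase_label),
    setNames(rec$recruitment_status_india, field_labels$recruitment_status_india)
  )
  extra <- rec$raw_fields[!(names(rec$raw_fields) %in% names(fields))]
  fields <- c(fields, extra)

  field_rows <- paste0(
    "<tr><td>", esc(names(fields)), "</td><td>", esc(unname(fields)), "</td></tr>",
    collapse = "\n"
  )
  site_rows <- if (nrow(rec$sites) > 0) {
    paste0(
      "<tr><td>", esc(rec$sites$pi_name_raw), "</td><td>", esc(rec$sites$name_raw),
      "</td><td>", esc(rec$sites$address_raw), "</td></tr>",
      collapse = "\n"
    )
  } else ""
  ec_rows <- if (nrow(rec$ecs) > 0) {
    paste0(
      "<tr><td>", esc(rec$ecs$name_raw), "</td><td>", esc(rec$ecs$approval_status_raw),
      "</td></tr>",
      collapse = "\n"
    )
  } else ""

  html <- paste0(
    "<html><head><title>", esc(rec$ctri_id), "</title></head><body>\n",
    "<table class=\"trial-details\">\n", field_rows, "\n</table>\n",
    "<h3>Sites of Study</h3>\n",
    "<table class=\"sites\">\n",
    "<tr><th>Name of Principal Investigator</th><th>Name of Site</th><th>Site Address</th></tr>\n",
    site_rows, "\n</table>\n",
    "<h3>Details of Ethics Committee</h3>\n",
    "<table class=\"ecs\">\n",
    "<tr><th>Name of Committee</th><th>Approval Status</th></tr>\n",
    ec_rows, "\n</table>\n",
    "</body></html>\n"
  )
  if (!is.null(path)) {
    writeLines(html, path, useBytes = TRUE)
    return(invisible(html))
  }
  html
}
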