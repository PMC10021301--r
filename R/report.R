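# Pipeline orchestration: filter -> classify -> match -> lint, with
# paper-shaped summary tables and a deterministic report bundle.

#' Run the full audit pipeline
#'
#' @param records List of `ctri_record`s (e.g. from [load_snapshot()],
#'   [read_jsonl()] or [generate_trials()]).
#' @param spec A [cohort_spec()]; `NULL` skips cohort selection and audits
#'   every record.
#' @param cfg A [match_config()].
#' @return An `audit_report` list:
#'   * `cascade`: selection-cascade tibble (empty when `spec` is `NULL`);
#'   * `partition`: count-category table over the audited cohort;
#'   * `grades`: match-grade table plus unmatched-site fraction (matchable
#'     trials only, i.e. at least one site and one EC);
#'   * `findings`: the full [lint_cohort()] output;
#'   * `match_results`: per-trial [match_trial()] results;
#'   * `manifest`: configuration echo for reproducibility.
#' @export
run_audit <- function(records, spec = cohort_spec(), cfg = match_config()) {
  if (!is.null(spec)) {
    sel <- select_cohort(records, spec)
    cohort <- sel$cohort
    cascade <- sel$cascade
  } else {
    cohort <- records
    cascade <- tibble::tibble(step = character(0), description = character(0),
                              n = integer(0))
  }
  partition <- summarize_partition(cohort)
  matchable <- cohort[vapply(cohort, function(r) {
    nrow(r$sites) > 0 && nrow(r$ecs) > 0
  }, logical(1))]
  match_results <- lapply(matchable, match_trial, cfg = cfg)
  grades <- grade_cohort(match_results)
  findings <- lint_cohort(cohort)
  structure(
    list(
      cascade = cascade,
      partition = partition,
      grades = grades,
      findings = findings,
      match_results = match_results,
      manifest = list(
        package_version = as.character(utils::packageVersion("ctriaudit")),
        n_input_records = length(records),
        n_cohort = length(cohort),
        n_matchable = length(matchable),
        spec = if (is.null(spec)) NULL else unclass(spec),
        match_config = unclass(cfg)
      )
    ),
    class = "audit_report"
  )
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report>", x$manifest$n_cohort, "trials audited\n")
  cat("partition:\n")
  print(x$partition)
  cat("match grades (", x$manifest$n_matchable, "matchable trials ):\n")
  print(x$grades$grades)
  cat("findings:", nrow(x$findings), "\n")
  invisible(x)
}

#' Write an audit report bundle to disk
#'
#' Emits `cascade.csv`, `partition.csv`, `grades.csv`, `findings.csv`,
#' `findings.jsonl` and `manifest.json` into a directory. Output is
#' byte-identical for identical inputs (no timestamps).
#'
#' @param report An `audit_report` from [run_audit()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_audit_bundle <- function(report, dir) {
  stopifnot(inherits(report, "audit_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$cascade, file.path(dir, "cascade.csv"),
                   eol = "\n", progress = FALSE)
  readr::write_csv(report$partition, file.path(dir, "partition.csv"),
                   eol = "\n", progress = FALSE)
  grades <- report$grades$grades
  grades$unmatched_fraction <- report$grades$unmatched_fraction
  readr::write_csv(grades, file.path(dir, "grades.csv"),
                   eol = "\n", progress = FALSE)
  readr::write_csv(report$findings, file.path(dir, "findings.csv"),
                   eol = "\n", progress = FALSE)
  writeLines(
    vapply(seq_len(nrow(report$findings)), function(i) {
      as.character(jsonlite::toJSON(as.list(report$findings[i, ]),
                                    auto_unbox = TRUE))
    }, character(1)),
    file.path(dir, "findings.jsonl"), useBytes = TRUE
  )
  writeLines(
    as.character(jsonlite::toJSON(report$manifest, auto_unbox = TRUE,
                                  null = "null", pretty = TRUE)),
    file.path(dir, "manifest.json"), useBytes = TRUE
  )
  invisible(dir)
}
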