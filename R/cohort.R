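# Cohort selection: a parameterised cascade over registration window, trial
# type, phase sets and recruitment status, reporting the survivor count at
# every step. The phase-2 set includes Phase 2/Phase 3 labels; the phase-3
# set includes Phase 2/Phase 3 and Phase 3/Phase 4; the merged cohort is
# their union with the overlap counted once.

#' Cohort selection parameters
#'
#' @param window_start,window_end Registration-date window, inclusive on both
#'   ends. Defaults: 2016-06-01 to 2021-02-19.
#' @param trial_type Trial type retained (default "Interventional").
#' @param phase_rule "merged" (union of the phase-2 and phase-3 sets, overlap
#'   counted once), "phase2" or "phase3".
#' @param status_allowed Recruitment statuses (India) retained.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(window_start = as.Date("2016-06-01"),
                        window_end = as.Date("2021-02-19"),
                        trial_type = "Interventional",
                        phase_rule = c("merged", "phase2", "phase3"),
                        status_allowed = c("Completed", "Closed to Recruitment")) {
  phase_rule <- match.arg(phase_rule)
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (window_start > window_end) stop("window_start must not be after window_end")
  structure(
    list(window_start = window_start, window_end = window_end,
         trial_type = trial_type, phase_rule = phase_rule,
         status_allowed = status_allowed),
    class = "cohort_spec"
  )
}

in_window <- function(records, spec) {
  vapply(records, function(r) {
    !is.na(r$registration_date) &&
      r$registration_date >= spec$window_start &&
      r$registration_date <= spec$window_end
  }, logical(1))
}

#' Select the audit cohort and report the selection cascade
#'
#' Applies, in order: registration window; trial type; phase-2 and phase-3
#' membership (`phases` containing P2 resp. P3, so combined-phase labels are
#' in both sets); recruitment status; single/multi-site split per phase set;
#' and the merge of the two phase sets with duplicates removed once.
#'
#' @param records List of `ctri_record`s.
#' @param spec A [cohort_spec()].
#' @return A list with `cohort` (the selected records) and `cascade`, a
#'   tibble with columns `step`, `description`, `n` recording the count
#'   surviving each step.
#' @export
select_cohort <- function(records, spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  step1 <- records[in_window(records, spec)]
  step2 <- step1[vapply(step1, function(r) r$trial_type == spec$trial_type, logical(1))]
  has_phase <- function(recs, p) {
    recs[vapply(recs, function(r) p %in% r$phases, logical(1))]
  }
  p2 <- has_phase(step2, "P2")
  p3 <- has_phase(step2, "P3")
  status_ok <- function(recs) {
    recs[vapply(recs, function(r) r$recruitment_status_india %in% spec$status_allowed, logical(1))]
  }
  p2s <- status_ok(p2)
  p3s <- status_ok(p3)

  n_single <- function(recs) sum(vapply(recs, function(r) nrow(r$sites) <= 1, logical(1)))
  ids <- function(recs) vapply(recs, function(r) r$ctri_id, character(1))

  cohort <- switch(spec$phase_rule,
    phase2 = p2s,
    phase3 = p3s,
    merged = c(p2s, p3s[!(ids(p3s) %in% ids(p2s))])
  )

  cascade <- tibble::tibble(
    step = c("1", "2", "3", "4", "5", "6",
             "7_single", "7_multi", "8_single", "8_multi",
             "9", "9_single", "9_multi"),
    description = c(
      "registered within window",
      "window AND trial type",
      "window AND type AND phase-2 set",
      "window AND type AND phase-3 set",
      "phase-2 set AND recruitment status",
      "phase-3 set AND recruitment status",
      "phase-2 set, single site", "phase-2 set, multi-site",
      "phase-3 set, single site", "phase-3 set, multi-site",
      "merged cohort (overlap once)",
      "merged cohort, single site", "merged cohort, multi-site"
    ),
    n = c(
      length(step1), length(step2), length(p2), length(p3),
      length(p2s), length(p3s),
      n_single(p2s), length(p2s) - n_single(p2s),
      n_single(p3s), length(p3s) - n_single(p3s),
      length(cohort), n_single(cohort), length(cohort) - n_single(cohort)
    )
  )
  list(cohort = cohort, cascade = cascade)
}

#' Partition a cohort into single-site and multi-site trials
#'
#' Trials with zero site rows are counted with the single-site set so the
#' partition stays exhaustive; the blank site table itself is a matter for
#' the linter.
#'
#' @param cohort List of `ctri_record`s.
#' @return A list with `single` and `multi` record lists.
#' @export
split_by_multiplicity <- function(cohort) {
  single <- vapply(cohort, function(r) nrow(r$sites) <= 1, logical(1))
  list(single = cohort[single], multi = cohort[!single])
}
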