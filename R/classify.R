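# Site/EC count classification: every trial falls in exactly one of five
# categories determined by its raw row counts. Duplicated rows inflate the
# counts on purpose -- duplication is a finding for the linter, not something
# to merge away here.

count_labels <- c("NO_EC", "MORE_SITES", "MORE_ECS", "EQUAL_SINGLE", "EQUAL_MULTI")

#' Classify a trial by its site and EC counts
#'
#' `NO_EC` when no EC row is present; `MORE_SITES` when sites outnumber a
#' non-empty EC table; `MORE_ECS` when ECs outnumber sites (including the
#' degenerate zero-site case, which the linter flags separately);
#' `EQUAL_SINGLE` for exactly one of each; `EQUAL_MULTI` for equal counts
#' greater than one. Exhaustive and mutually exclusive over all count pairs.
#'
#' @param trial A `ctri_record`.
#' @return A `count_category` list with `label`, `n_sites`, `n_ecs`.
#' @export
classify_counts <- function(trial) {
  n_sites <- nrow(trial$sites)
  n_ecs <- nrow(trial$ecs)
  label <- if (n_ecs == 0) {
    "NO_EC"
  } else if (n_ecs > n_sites) {
    "MORE_ECS"
  } else if (n_sites > n_ecs) {
    "MORE_SITES"
  } else if (n_sites == 1) {
    "EQUAL_SINGLE"
  } else {
    "EQUAL_MULTI"
  }
  structure(list(label = label, n_sites = n_sites, n_ecs = n_ecs),
            class = "count_category")
}

#' Summarise the count partition of a cohort
#'
#' @param cohort List of `ctri_record`s.
#' @return A tibble with one row per category (`label`, `n`), all five labels
#'   always present, plus an `EQUAL` aggregate row (`EQUAL_SINGLE` +
#'   `EQUAL_MULTI`). Category counts sum to the cohort size.
#' @export
summarize_partition <- function(cohort) {
  labels <- vapply(cohort, function(r) classify_counts(r)$label, character(1))
  counts <- vapply(count_labels, function(l) sum(labels == l), integer(1))
  tibble::tibble(
    label = c(count_labels, "EQUAL"),
    n = c(unname(counts), unname(counts["EQUAL_SINGLE"] + counts["EQUAL_MULTI"]))
  )
}
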