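# Independent oracles and small record builders shared across tests.

# exhaustive maximum-weight injective assignment over eligible pairs;
# plain recursion with no pruning, independent of the package's solver
brute_force_assignment_total <- function(score, eligible) {
  n_s <- nrow(score)
  n_e <- ncol(score)
  best <- 0
  rec <- function(i, used, tot) {
    if (i > n_s) {
      best <<- max(best, tot)
      return(invisible(NULL))
    }
    rec(i + 1, used, tot)
    for (j in seq_len(n_e)) {
      if (eligible[i, j] && !used[j]) {
        u <- used
        u[j] <- TRUE
        rec(i + 1, u, tot + score[i, j])
      }
    }
  }
  rec(1, rep(FALSE, n_e), 0)
  best
}

# a minimal record with the given counts; names are distinct but arbitrary
mini_record <- function(serial, n_sites = 1, n_ecs = 1,
                        registration = as.Date("2018-01-15"),
                        trial_type = "Interventional",
                        phase_label = "Phase 3",
                        status = "Completed",
                        enrollment = as.Date(NA)) {
  sites <- if (n_sites > 0) {
    site_table(sprintf("Test Hospital %d Site %d", serial, seq_len(n_sites)),
               "1 Lake Road, Pune", "Dr Asha Verma")
  } else site_table()
  ecs <- if (n_ecs > 0) {
    ec_table(sprintf(
      "Test Hospital %d Site %d Institutional Ethics Committee (ECR/%d/Inst/MH/2015)",
      serial, seq_len(n_ecs), 500 + serial))
  } else ec_table()
  trial_record(
    ctri_id = sprintf("CTRI/2018/01/%06d", serial),
    registration_date = registration,
    enrollment_start_date = enrollment,
    trial_type = trial_type,
    phase_label = phase_label,
    recruitment_status_india = status,
    sites = sites,
    ecs = ecs
  )
}

essence <- function(records) lapply(records, ctriaudit:::record_essence)

file_bytes <- function(path) readBin(path, "raw", file.info(path)$size)

dir_bytes <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE))
  lapply(stats::setNames(file.path(dir, files), files), file_bytes)
}
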