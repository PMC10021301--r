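# Site-EC matching.
#
# Evidence per pair: name similarity between the site name and the
# institution part of the EC name (capped for generic committee names, with
# an address fallback), the acronym crosswalk, city agreement, and a PI
# linkage bonus when a doctor's name in the EC field matches the site's PI.
# Phase A resolves a one-to-one assignment over above-threshold pairs by an
# exact branch-and-bound maximum-weight search; a per-site margin test then
# separates clear ("direct") calls from contested ones. Phase B assigns the
# last remaining EC to the last remaining site by elimination. Ambiguity is
# reported, never broken by index order.

#' Matcher configuration
#'
#' @param accept_threshold Minimum pair score for a candidate (default 0.75).
#' @param margin Minimum gap between a site's best and second-best candidate
#'   for a "direct" call (default 0.10).
#' @param generic_cap Ceiling on the name component against a generic or
#'   casual EC name (default 0.30): "Institutional Ethics Committee" alone
#'   never identifies an institution.
#' @param city_bonus,city_penalty Added/subtracted when both sides carry a
#'   city and it agrees/differs (defaults 0.15 / 0.25).
#' @param pi_bonus Added when a doctor's name in the EC field matches the
#'   site's PI (default 0.35); with a generic committee name this is often
#'   the only usable link.
#' @param address_weight Discount on the address-fallback similarity
#'   (default 0.9).
#' @param acronym_bonus Crosswalk bonus inside [similarity()] (default 0.2).
#' @param enable_elimination Run Phase B (default TRUE).
#' @return A `match_config` list.
#' @export
match_config <- function(accept_threshold = 0.75, margin = 0.10,
                         generic_cap = 0.30, city_bonus = 0.15,
                         city_penalty = 0.25, pi_bonus = 0.35,
                         address_weight = 0.9, acronym_bonus = 0.2,
                         enable_elimination = TRUE) {
  stopifnot(accept_threshold >= 0, accept_threshold <= 1, margin >= 0)
  structure(
    list(accept_threshold = accept_threshold, margin = margin,
         generic_cap = generic_cap, city_bonus = city_bonus,
         city_penalty = city_penalty, pi_bonus = pi_bonus,
         address_weight = address_weight, acronym_bonus = acronym_bonus,
         enable_elimination = enable_elimination),
    class = "match_config"
  )
}

#' Score one site-EC pair
#'
#' @param site_index,ec_index Row indices into the trial's tables.
#' @param trial A `ctri_record` (normalized on the fly if needed).
#' @param cfg A [match_config()].
#' @return A list with `score` (in `[0, 1]`) and `evidence`, a named numeric
#'   breakdown (`name`, `address`, `city`, `pi`, `acronym_crosswalk`).
#' @export
score_pair <- function(site_index, ec_index, trial, cfg = match_config()) {
  trial <- normalize_record(trial)
  nrm <- trial$norm
  site <- nrm$sites[[site_index]]
  addr <- nrm$addresses[[site_index]]
  ec_full <- nrm$ecs[[ec_index]]
  ec_core <- nrm$ec_core[[ec_index]]

  name_sim <- similarity(site, ec_core, acronym_bonus = cfg$acronym_bonus)
  addr_sim <- cfg$address_weight * similarity(addr, ec_core, acronym_bonus = cfg$acronym_bonus)
  if (ec_full$is_generic_ec || length(ec_core$tokens) == 0) {
    name_sim <- min(name_sim, cfg$generic_cap)
    addr_sim <- min(addr_sim, cfg$generic_cap)
  }
  name_eff <- max(name_sim, addr_sim)

  site_city <- nrm$site_city[[site_index]]
  ec_city <- nrm$ec_city[[ec_index]]
  city_term <- if (!is.na(site_city) && !is.na(ec_city)) {
    if (identical(site_city, ec_city)) cfg$city_bonus else -cfg$city_penalty
  } else 0

  pi_term <- 0
  persons <- ec_full$person_names
  if (length(persons) > 0) {
    pi_canon <- nrm$pis[[site_index]]$canonical
    person_canon <- vapply(persons, canonicalize, character(1))
    if (nzchar(pi_canon) && any(person_canon == pi_canon)) pi_term <- cfg$pi_bonus
  }

  crosswalk <- acronym_crosswalk(site, ec_core) || acronym_crosswalk(site, ec_full)

  score <- max(0, min(1, name_eff + city_term + pi_term))
  list(
    score = score,
    evidence = c(
      name = name_sim, address = addr_sim, city = city_term,
      pi = pi_term, acronym_crosswalk = as.numeric(crosswalk)
    )
  )
}

# exact maximum-weight injective assignment over eligible pairs, by depth
# first search with an optimistic bound; instances here are tiny (<= 12
# sites) and candidate lists sparse. First-found optimum (sites in order,
# ECs ascending, then "skip") makes ties resolve to the lowest indices.
solve_assignment <- function(score, eligible) {
  n_s <- nrow(score)
  n_e <- ncol(score)
  if (n_s == 0 || n_e == 0) {
    return(list(assignment = integer(0), total = 0))
  }
  cand <- lapply(seq_len(n_s), function(i) {
    j <- which(eligible[i, ])
    j[order(-score[i, j], j)]
  })
  row_max <- vapply(seq_len(n_s), function(i) {
    if (length(cand[[i]])) max(score[i, cand[[i]]]) else 0
  }, numeric(1))
  tail_bound <- rev(cumsum(rev(row_max)))
  best_total <- -1
  best_assign <- rep(NA_integer_, n_s)
  used <- rep(FALSE, n_e)
  assign <- rep(NA_integer_, n_s)
  eps <- 1e-9

  recurse <- function(i, total) {
    if (i > n_s) {
      if (total > best_total + eps) {
        best_total <<- total
        best_assign <<- assign
      }
      return(invisible(NULL))
    }
    if (total + tail_bound[i] <= best_total + eps) return(invisible(NULL))
    for (j in cand[[i]]) {
      if (!used[j]) {
        used[j] <<- TRUE
        assign[i] <<- j
        recurse(i + 1, total + score[i, j])
        used[j] <<- FALSE
        assign[i] <<- NA_integer_
      }
    }
    recurse(i + 1, total)
  }
  recurse(1L, 0)
  list(assignment = best_assign, total = max(best_total, 0))
}

#' Match every site of a trial to an ethics committee
#'
#' @param trial A `ctri_record` with at least one site and one EC; a trial
#'   without ECs belongs to the `NO_EC` count category and is not matchable.
#' @param cfg A [match_config()].
#' @return A `match_result` list:
#'   * `assignments`: tibble (`site_index`, `ec_index`, `status` in
#'     `direct`/`by_elimination`, `score`, evidence columns);
#'   * `unresolved`: tibble (`site_index`, `reason` in
#'     `ambiguous`/`no_candidate`);
#'   * `trial_grade`: `ALL_CLEAR` (every site direct), `ONE_UNCLEAR` (exactly
#'     one site resolved only by elimination or left unresolved),
#'     `MULTI_UNCLEAR` (two or more such sites);
#'   * `phase_a_total`: the exact maximum total score over injective
#'     assignments restricted to above-threshold pairs.
#' @export
match_trial <- function(trial, cfg = match_config()) {
  if (nrow(trial$ecs) == 0) {
    stop("trial ", trial$ctri_id, " lists no EC; see classify_counts() -- ",
         "NO_EC records are not matchable")
  }
  if (nrow(trial$sites) == 0) {
    stop("trial ", trial$ctri_id, " lists no sites; nothing to match")
  }
  trial <- normalize_record(trial)
  n_s <- nrow(trial$sites)
  n_e <- nrow(trial$ecs)

  score <- matrix(0, n_s, n_e)
  evidence <- vector("list", n_s * n_e)
  dim(evidence) <- c(n_s, n_e)
  for (i in seq_len(n_s)) {
    for (j in seq_len(n_e)) {
      sp <- score_pair(i, j, trial, cfg)
      score[i, j] <- sp$score
      evidence[[i, j]] <- sp$evidence
    }
  }

  eligible <- score >= cfg$accept_threshold - 1e-12
  phase_a <- solve_assignment(score, eligible)

  status <- rep(NA_character_, n_s)
  assigned_ec <- rep(NA_integer_, n_s)
  reasons <- rep(NA_character_, n_s)

  for (i in seq_len(n_s)) {
    j <- phase_a$assignment[i]
    cand <- which(eligible[i, ])
    if (!is.na(j)) {
      best <- max(score[i, cand])
      runner <- if (length(cand) > 1) sort(score[i, cand], decreasing = TRUE)[2] else -Inf
      if (abs(score[i, j] - best) < 1e-9 && best - runner >= cfg$margin - 1e-9) {
        status[i] <- "direct"
        assigned_ec[i] <- j
      } else {
        reasons[i] <- "ambiguous"
      }
    } else if (length(cand) == 0) {
      reasons[i] <- "no_candidate"
    } else {
      # had candidates but lost them to other sites in the assignment
      reasons[i] <- "ambiguous"
    }
  }

  if (cfg$enable_elimination) {
    repeat {
      open_sites <- which(is.na(status))
      open_ecs <- setdiff(seq_len(n_e), assigned_ec[!is.na(assigned_ec)])
      if (length(open_sites) == 1 && length(open_ecs) == 1) {
        i <- open_sites
        assigned_ec[i] <- open_ecs
        status[i] <- "by_elimination"
        reasons[i] <- NA_character_
      } else {
        break
      }
    }
  }

  assigned <- which(!is.na(status))
  assignments <- tibble::tibble(
    site_index = assigned,
    ec_index = assigned_ec[assigned],
    status = status[assigned],
    score = score[cbind(assigned, assigned_ec[assigned])],
    name = vapply(assigned, function(i) evidence[[i, assigned_ec[i]]][["name"]], numeric(1)),
    address = vapply(assigned, function(i) evidence[[i, assigned_ec[i]]][["address"]], numeric(1)),
    city = vapply(assigned, function(i) evidence[[i, assigned_ec[i]]][["city"]], numeric(1)),
    pi = vapply(assigned, function(i) evidence[[i, assigned_ec[i]]][["pi"]], numeric(1)),
    acronym_crosswalk = vapply(assigned, function(i) {
      evidence[[i, assigned_ec[i]]][["acronym_crosswalk"]]
    }, numeric(1))
  )
  unresolved <- tibble::tibble(
    site_index = which(is.na(status)),
    reason = reasons[is.na(status)]
  )

  n_unclear <- sum(status == "by_elimination", na.rm = TRUE) + nrow(unresolved)
  grade <- if (n_unclear == 0) "ALL_CLEAR" else if (n_unclear == 1) "ONE_UNCLEAR" else "MULTI_UNCLEAR"

  structure(
    list(
      ctri_id = trial$ctri_id,
      assignments = assignments,
      unresolved = unresolved,
      trial_grade = grade,
      phase_a_total = phase_a$total,
      n_sites = n_s,
      n_ecs = n_e
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result>", x$ctri_id, "grade:", x$trial_grade, "\n")
  cat("  ", nrow(x$assignments), "assigned /", nrow(x$unresolved), "unresolved of",
      x$n_sites, "sites\n")
  invisible(x)
}

#' Summarise match grades over a cohort
#'
#' @param match_results List of `match_result`s from [match_trial()].
#' @return A list with `grades` (tibble `grade`, `n`, counts summing to the
#'   number of matchable trials), `unmatched_fraction` (unresolved sites /
#'   total sites) and the underlying totals.
#' @export
grade_cohort <- function(match_results) {
  grades <- vapply(match_results, function(m) m$trial_grade, character(1))
  lv <- c("ALL_CLEAR", "ONE_UNCLEAR", "MULTI_UNCLEAR")
  tab <- tibble::tibble(
    grade = lv,
    n = vapply(lv, function(g) sum(grades == g), integer(1), USE.NAMES = FALSE)
  )
  total_sites <- sum(vapply(match_results, function(m) m$n_sites, integer(1)))
  unresolved <- sum(vapply(match_results, function(m) nrow(m$unresolved), integer(1)))
  list(
    grades = tab,
    unmatched_fraction = if (total_sites > 0) unresolved / total_sites else 0,
    n_trials = length(match_results),
    n_sites = total_sites,
    n_unresolved_sites = unresolved
  )
}
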