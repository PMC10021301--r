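# Deterministic text canonicalisation and feature extraction.
#
# Everything downstream (the matcher and the deficiency linter) works on the
# normalized form; verbatim source text is never modified.

ec_term_tokens <- c(
  "institutional", "ethics", "ethical", "committee", "committees", "review",
  "board", "iec", "ec", "irb", "independent"
)

connective_tokens <- c("of", "and", "the", "for", "in", "at", "on", "to")

roman_numeral_tokens <- c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii", "ix", "x")

honorific_pattern <- "\\b(?:Dr|Prof|Professor|Mr|Mrs|Ms)\\.?\\s+"

institution_keywords <- c(
  "hospital", "hospitals", "college", "institute", "institution", "university",
  "centre", "center", "clinic", "sciences", "medical", "research", "foundation",
  "trust", "aiims", "sanstha", "laboratory", "academy"
)

acronym_stoplist <- c(
  "EC", "IEC", "ECR", "IRB", "CTRI", "PI", "ICMR", "CDSCO",
  # roman numerals: committee ordinals (IEC-II), not institution acronyms
  "II", "III", "IV", "VI", "VII", "VIII", "IX", "XI", "XII"
)

ecr_regex <- "(?i)\\bECR/([0-9]+)/([A-Za-z]+)/([A-Za-z]+)/((?:19|20)[0-9]{2})((?:/[A-Za-z0-9-]+)+)?"

#' Bundled gazetteer of Indian city names
#'
#' Read from `inst/extdata/india_cities.txt` (one city per line, editable).
#' Returned in canonical (lowercased) form and cached per session.
#'
#' @return Character vector of canonical city names.
#' @export
city_gazetteer <- function() {
  if (is.null(.ctriaudit_env$cities)) {
    path <- system.file("extdata", "india_cities.txt", package = "ctriaudit")
    cities <- readLines(path, warn = FALSE, encoding = "UTF-8")
    cities <- trimws(tolower(cities))
    cities <- cities[nzchar(cities) & !startsWith(cities, "#")]
    # longest first so multi-word cities win over their substrings
    .ctriaudit_env$cities <- cities[order(-nchar(cities), cities)]
  }
  .ctriaudit_env$cities
}

abbreviation_table <- function() {
  if (is.null(.ctriaudit_env$abbrev)) {
    path <- system.file("extdata", "abbreviations.csv", package = "ctriaudit")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    .ctriaudit_env$abbrev <- setNames(tolower(tab$expansion), tolower(tab$abbrev))
  }
  .ctriaudit_env$abbrev
}

# lowercase, fold diacritics, "&" -> and, strip punctuation, collapse space,
# expand bundled abbreviations token-wise. Idempotent.
canonicalize <- function(raw) {
  x <- iconv(raw, from = "", to = "ASCII//TRANSLIT")
  x[is.na(x)] <- raw[is.na(x)]
  x <- gsub("&", " and ", x, fixed = TRUE)
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  x <- trimws(gsub(" +", " ", x))
  abbrev <- abbreviation_table()
  vapply(strsplit(x, " ", fixed = TRUE), function(tok) {
    if (length(tok) == 0) return("")
    hit <- tok %in% names(abbrev)
    tok[hit] <- abbrev[tok[hit]]
    paste(tok, collapse = " ")
  }, character(1))
}

#' Normalize a raw registry string
#'
#' Produces the canonical form used throughout the package: lowercased,
#' diacritics folded, `&` mapped to `and`, punctuation stripped, whitespace
#' collapsed, and common abbreviations (govt, hosp, inst, ...) expanded from
#' the bundled table. Also extracts tokens, literal and derived acronyms, a
#' gazetteer city, person names, and whether the string is a generic/casual
#' ethics-committee name. Deterministic and idempotent on the canonical form.
#'
#' @param raw A character scalar (NA is treated as "").
#' @return An object of class `ctri_norm`: a list with elements `raw`,
#'   `canonical`, `tokens`, `acronyms`, `acronym_derived`, `city`,
#'   `person_names`, `is_generic_ec`, `is_file_number`, `is_message`,
#'   `has_ecr`.
#' @examples
#' normalize_text("Govt. Medical College, Nagpur")$canonical
#' normalize_text("Institutional Ethics Committee")$is_generic_ec
#' @export
normalize_text <- function(raw) {
  if (length(raw) != 1) stop("normalize_text() expects a single string")
  if (is.na(raw)) raw <- ""
  # memoise: registry text repeats heavily (institution pools, benchmarks)
  if (is.null(.ctriaudit_env$norm_cache)) {
    .ctriaudit_env$norm_cache <- new.env(parent = emptyenv())
  }
  key <- paste0("k", raw)
  cached <- get0(key, envir = .ctriaudit_env$norm_cache, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  canonical <- canonicalize(raw)
  tokens <- if (nzchar(canonical)) strsplit(canonical, " ", fixed = TRUE)[[1]] else character(0)
  acronyms <- extract_acronyms(raw)
  derived <- derive_acronym(raw)
  city <- detect_city(canonical)
  persons <- detect_person_names(raw)
  ecr <- detect_ecr(raw)
  is_file_number <- detect_file_number(raw, canonical, tokens, has_ecr = !is.null(ecr))
  is_message <- detect_message(canonical, tokens)
  generic <- is_generic_ec_name(tokens, persons, is_file_number, is_message, city)
  out <- structure(
    list(
      raw = raw,
      canonical = canonical,
      tokens = tokens,
      acronyms = acronyms,
      acronym_derived = derived,
      city = city,
      person_names = persons,
      is_generic_ec = generic,
      is_file_number = is_file_number,
      is_message = is_message,
      has_ecr = !is.null(ecr)
    ),
    class = "ctri_norm"
  )
  assign(key, out, envir = .ctriaudit_env$norm_cache)
  out
}

#' @export
print.ctri_norm <- function(x, ...) {
  cat("<ctri_norm> \"", x$canonical, "\"\n", sep = "")
  if (length(x$acronyms)) cat("  acronyms:", paste(x$acronyms, collapse = ", "), "\n")
  if (!is.na(x$city)) cat("  city:", x$city, "\n")
  if (length(x$person_names)) cat("  persons:", paste(x$person_names, collapse = "; "), "\n")
  invisible(x)
}

#' Extract literal acronyms from raw text
#'
#' Maximal runs of two or more uppercase letters, excluding ethics-committee
#' and registry boilerplate (EC, IEC, IRB, ECR, CTRI, ...) and anything inside
#' a CDSCO EC-registration number, whose slash-separated fields (ECR, state
#' codes) are registration syntax, not institution acronyms.
#'
#' @param raw A character scalar.
#' @return Character vector of distinct acronyms (possibly empty).
#' @examples
#' extract_acronyms("KIMS Hospital")
#' @export
extract_acronyms <- function(raw) {
  if (is.na(raw) || !nzchar(raw)) return(character(0))
  x <- gsub(ecr_regex, " ", raw, perl = TRUE)
  hits <- regmatches(x, gregexpr("[A-Z]{2,}", x))[[1]]
  unique(hits[!(hits %in% acronym_stoplist)])
}

#' Derive an acronym from a multi-word title-case name
#'
#' Initial letters of the capitalised words, skipping connectives
#' (of/and/the/for/...), so "Kempegowda Institute Of Medical Sciences" gives
#' "KIMS". Returns `NA` for names with fewer than two contributing words or
#' when the name is itself an acronym.
#'
#' @param raw A character scalar.
#' @return A single acronym string or `NA_character_`.
#' @export
derive_acronym <- function(raw) {
  if (is.na(raw) || !nzchar(raw)) return(NA_character_)
  words <- strsplit(gsub("[^A-Za-z]+", " ", raw), " ", fixed = TRUE)[[1]]
  words <- words[nzchar(words)]
  words <- words[!(tolower(words) %in% c(connective_tokens, roman_numeral_tokens))]
  caps <- words[grepl("^[A-Z]", words)]
  # an all-caps token is already an acronym, not an expandable name
  caps <- caps[!grepl("^[A-Z]{2,}$", caps)]
  if (length(caps) < 2) return(NA_character_)
  acr <- paste(substr(caps, 1, 1), collapse = "")
  if (nchar(acr) < 2 || nchar(acr) > 10) return(NA_character_)
  toupper(acr)
}

#' Parse a CDSCO ethics-committee registration number
#'
#' Matches `ECR/<serial>/<kind>/<region>/<year>[/<suffix>]` case-insensitively,
#' e.g. `ECR/541/Inst/KA/2014` or `ECR/346/Inst/AP/2013/RR-16`.
#'
#' @param raw A character scalar.
#' @return `NULL` when no registration number is present, otherwise a list
#'   with `raw`, `serial`, `kind` ("Inst", "Indep" or "Other"), `region`,
#'   `year` and `suffix` (`NA` when absent). `raw` reconstructs verbatim from
#'   the components.
#' @export
detect_ecr <- function(raw) {
  if (is.na(raw) || !nzchar(raw)) return(NULL)
  m <- regmatches(raw, regexec(ecr_regex, raw, perl = TRUE))[[1]]
  if (length(m) == 0) return(NULL)
  kind_raw <- m[3]
  kind <- switch(tolower(kind_raw), inst = "Inst", indep = "Indep", "Other")
  suffix <- if (nzchar(m[6])) sub("^/", "", m[6]) else NA_character_
  list(
    raw = m[1],
    serial = as.integer(m[2]),
    kind = kind,
    region = m[4],
    year = as.integer(m[5]),
    suffix = suffix
  )
}

#' Detect person names introduced by honorifics
#'
#' Finds substrings following "Dr", "Prof", "Mr", "Mrs" or "Ms": consecutive
#' capitalised words or initials that are not institution or committee
#' keywords. Deterministic; returns names without the honorific.
#'
#' @param raw A character scalar.
#' @return Character vector of detected names (possibly empty).
#' @examples
#' detect_person_names("IEC Dr A K Sharma")
#' @export
detect_person_names <- function(raw) {
  if (is.na(raw) || !nzchar(raw)) return(character(0))
  stop_words <- c(
    "Institutional", "Ethics", "Ethical", "Committee", "Review", "Board",
    "Hospital", "Hospitals", "College", "Institute", "Institution",
    "University", "Medical", "Sciences", "Centre", "Center", "Research",
    "Clinic", "Trust", "Foundation", "IEC", "EC", "IRB"
  )
  out <- character(0)
  starts <- gregexpr(honorific_pattern, raw, perl = TRUE)[[1]]
  if (starts[1] == -1) return(out)
  lens <- attr(starts, "match.length")
  for (k in seq_along(starts)) {
    rest <- substr(raw, starts[k] + lens[k], nchar(raw))
    words <- strsplit(rest, "[^A-Za-z]+")[[1]]
    words <- words[nzchar(words)]
    name <- character(0)
    for (w in words) {
      if (!grepl("^[A-Z]", w) || w %in% stop_words) break
      name <- c(name, w)
      if (length(name) >= 4) break
    }
    if (length(name) >= 1) out <- c(out, paste(name, collapse = " "))
  }
  unique(out)
}

# last gazetteer city mentioned in a canonical string (cities usually close a
# name or an address); NA when none is present. Longer names are tried first
# and masked out, so "new delhi" is not also reported as "delhi".
detect_city <- function(canonical) {
  if (!nzchar(canonical)) return(NA_character_)
  padded <- paste0(" ", canonical, " ")
  best <- NA_character_
  best_pos <- -1L
  for (city in city_gazetteer()) {
    pat <- paste0(" ", city, " ")
    hits <- gregexpr(pat, padded, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    if (max(hits) > best_pos) {
      best_pos <- max(hits)
      best <- city
    }
    padded <- gsub(pat, strrep(" ", nchar(pat)), padded, fixed = TRUE)
  }
  best
}

detect_file_number <- function(raw, canonical, tokens, has_ecr) {
  if (has_ecr || !nzchar(canonical)) return(FALSE)
  if (!grepl("[0-9]", raw) || !grepl("[/-]", raw)) return(FALSE)
  alpha <- grepl("^[a-z]+$", tokens)
  # two or more consecutive alphabetic tokens look like an institution name
  runs <- rle(alpha)
  if (any(runs$values & runs$lengths >= 2)) return(FALSE)
  TRUE
}

detect_message <- function(canonical, tokens) {
  if (length(tokens) <= 15) return(FALSE)
  any(grepl("\\b(please|consider|was given|kindly|approval was)\\b", canonical))
}

# generic or casual EC reference: nothing identifying an institution remains
# once committee words, connectives, numerals and roman numerals are removed
is_generic_ec_name <- function(tokens, persons, is_file_number, is_message, city) {
  if (length(tokens) == 0) return(FALSE)
  if (is_file_number || is_message || length(persons) > 0) return(FALSE)
  if (!any(tokens %in% ec_term_tokens)) return(FALSE)
  residual <- tokens[!(tokens %in% c(ec_term_tokens, connective_tokens, roman_numeral_tokens))]
  residual <- residual[!grepl("^[0-9]+$", residual)]
  if (length(residual) == 0) return(TRUE)
  if (length(residual) <= 2 &&
      !any(residual %in% institution_keywords) &&
      (is.na(city) || !any(residual %in% strsplit(city, " ")[[1]]))) {
    return(TRUE)
  }
  FALSE
}

# institution part of an EC name: committee words, registration number, bare
# numbers and roman numerals removed. Returns a ctri_norm of the residue.
strip_ec_terms <- function(raw) {
  if (is.na(raw)) raw <- ""
  x <- gsub(ecr_regex, " ", raw, perl = TRUE)
  canonical <- canonicalize(x)
  tokens <- if (nzchar(canonical)) strsplit(canonical, " ", fixed = TRUE)[[1]] else character(0)
  keep <- !(tokens %in% c(ec_term_tokens, roman_numeral_tokens)) & !grepl("^[0-9]+$", tokens)
  normalize_text(paste(tokens[keep], collapse = " "))
}

#' Similarity between two normalized strings
#'
#' A weighted blend of a token-overlap component (Jaccard index of the token
#' sets) and an edit-distance component (1 - Levenshtein distance / longer
#' length), plus an acronym-crosswalk bonus when a literal acronym on one side
#' equals a literal or derived acronym of the other (so "KIMS Ethics
#' Committee" gains on "Kalinga Institute of Medical Sciences"). Symmetric,
#' deterministic, 1 for identical canonical forms, and clamped to [0, 1].
#'
#' @param a,b `ctri_norm` objects (see [normalize_text()]) or raw strings.
#' @param weights Named numeric: `token` and `edit` component weights
#'   (normalised to sum to 1).
#' @param acronym_bonus Added when the acronym crosswalk fires.
#' @return A single numeric score in `[0, 1]`.
#' @export
similarity <- function(a, b, weights = c(token = 0.6, edit = 0.4),
                       acronym_bonus = 0.2) {
  if (!inherits(a, "ctri_norm")) a <- normalize_text(a)
  if (!inherits(b, "ctri_norm")) b <- normalize_text(b)
  if (identical(a$canonical, b$canonical)) {
    return(if (nzchar(a$canonical)) 1 else 0)
  }
  if (!nzchar(a$canonical) || !nzchar(b$canonical)) return(0)
  w <- weights / sum(weights)
  inter <- length(intersect(a$tokens, b$tokens))
  uni <- length(union(a$tokens, b$tokens))
  token_score <- if (uni > 0) inter / uni else 0
  dist <- adist(a$canonical, b$canonical)[1, 1]
  edit_score <- 1 - dist / max(nchar(a$canonical), nchar(b$canonical))
  base <- unname(w["token"] * token_score + w["edit"] * edit_score)
  if (acronym_crosswalk(a, b)) base <- base + acronym_bonus
  max(0, min(1, base))
}

# literal acronym on one side matches a literal or derived acronym of the
# other; derived-vs-derived is deliberately excluded (two different
# "X Institute of Medical Sciences" would otherwise reinforce each other)
acronym_crosswalk <- function(a, b) {
  if (length(intersect(a$acronyms, b$acronyms)) > 0) return(TRUE)
  if (!is.na(a$acronym_derived) && a$acronym_derived %in% b$acronyms) return(TRUE)
  if (!is.na(b$acronym_derived) && b$acronym_derived %in% a$acronyms) return(TRUE)
  FALSE
}
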