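# Text canonicalisation and feature extraction.

test_that("canonical form is idempotent and folds abbreviations", {
  cases <- c(
    "Govt. Medical College, Nagpur",
    "Government Medical College Nagpur",
    "  Inst.  of Health & Research  ",
    "Hospé de São",
    "KIMS Hospital, Hubli",
    "ECR/541/Inst/KA/2014",
    ""
  )
  for (x in cases) {
    n1 <- normalize_text(x)
    n2 <- normalize_text(n1$canonical)
    expect_identical(n1$canonical, n2$canonical, label = paste("idempotence for", x))
  }
  expect_identical(normalize_text("Govt. Medical College, Nagpur")$canonical,
                   normalize_text("Government Medical College Nagpur")$canonical)
  expect_identical(normalize_text("Research & Care")$canonical, "research and care")
})

test_that("generic and casual EC names are recognised, informative ones are not", {
  expect_true(normalize_text("Institutional Ethics Committee")$is_generic_ec)
  expect_true(normalize_text("IEC")$is_generic_ec)
  expect_true(normalize_text("IEC - II")$is_generic_ec)
  expect_true(normalize_text("Ethical Committee of the Council")$is_generic_ec)
  expect_false(normalize_text("Ashwini Medical College Institutional Ethics Committee")$is_generic_ec)
  expect_false(normalize_text("IEC Dr A K Sharma")$is_generic_ec)
  expect_false(normalize_text("IEC/2018/42")$is_generic_ec)
  expect_identical(normalize_text("")$canonical, "")
})

test_that("literal acronyms are extracted; boilerplate and ECR syntax are not", {
  expect_identical(extract_acronyms("KIMS Hospital"), "KIMS")
  expect_identical(extract_acronyms("abc hospital"), character(0))
  expect_identical(extract_acronyms("IEC of the hospital"), character(0))
  # state code and ECR keyword inside a registration number are not acronyms
  expect_identical(extract_acronyms("Committee (ECR/541/Inst/KA/2014)"), character(0))
  expect_setequal(extract_acronyms("AIIMS and PGIMER IEC"), c("AIIMS", "PGIMER"))
})

test_that("derived acronyms skip connectives", {
  expect_identical(derive_acronym("Kempegowda Institute Of Medical Sciences"), "KIMS")
  expect_identical(derive_acronym("Kalinga Institute of Medical Sciences"), "KIMS")
  expect_identical(derive_acronym("Ashwini Medical College"), "AMC")
  expect_identical(derive_acronym("AIMS"), NA_character_)
  expect_identical(derive_acronym("hospital"), NA_character_)
})

test_that("ECR registration numbers parse and reconstruct", {
  e <- detect_ecr("ECR/541/Inst/KA/2014")
  expect_equal(e$serial, 541L)
  expect_identical(e$kind, "Inst")
  expect_identical(e$region, "KA")
  expect_equal(e$year, 2014L)
  expect_true(is.na(e$suffix))
  expect_identical(e$raw, "ECR/541/Inst/KA/2014")

  e2 <- detect_ecr("approved by ECR/346/Inst/AP/2013/RR-16 earlier")
  expect_identical(e2$suffix, "RR-16")
  expect_identical(e2$raw, "ECR/346/Inst/AP/2013/RR-16")

  e3 <- detect_ecr("ECR/400/Inst/Py/2013")
  expect_identical(e3$region, "Py")

  expect_null(detect_ecr("IEC/2018/42"))
  expect_null(detect_ecr("no number here"))

  e4 <- detect_ecr("ECR/131/Indep/MH/2017")
  expect_identical(e4$kind, "Indep")
})

test_that("person names are found after honorifics and stop at keywords", {
  expect_identical(detect_person_names("IEC Dr A K Sharma"), "A K Sharma")
  expect_identical(detect_person_names("Institutional Ethics Committee"), character(0))
  expect_identical(detect_person_names("Dr Meena Rao Institutional Ethics Committee"),
                   "Meena Rao")
  expect_setequal(detect_person_names("Dr Ravi Nair and Prof Asha Verma"),
                  c("Ravi Nair", "Asha Verma"))
})

test_that("city extraction prefers the last, longest gazetteer match", {
  expect_identical(normalize_text("12 Station Road, Pune")$city, "pune")
  expect_identical(normalize_text("Sir Gangaram Hospital, New Delhi")$city, "new delhi")
  expect_identical(normalize_text("Mumbai Clinic, Nagpur")$city, "nagpur")
  expect_true(is.na(normalize_text("no city here")$city))
})

test_that("similarity is symmetric, maximal on identity, and rewards the acronym crosswalk", {
  expect_equal(similarity("Ashwini Medical College", "Ashwini Medical College"), 1)
  a <- normalize_text("Kalinga Institute of Medical Sciences")
  b <- normalize_text("KIMS Ethics Committee")
  expect_equal(similarity(a, b), similarity(b, a))
  with_cw <- similarity(a, b)
  without_cw <- similarity(a, b, acronym_bonus = 0)
  expect_gt(with_cw, without_cw)
  expect_equal(similarity("", "anything"), 0)

  set.seed(42)
  rand_word <- function() paste(sample(letters, 8, replace = TRUE), collapse = "")
  for (k in 1:20) {
    x <- paste(replicate(3, rand_word()), collapse = " ")
    y <- paste(replicate(3, rand_word()), collapse = " ")
    expect_equal(similarity(x, y), similarity(y, x))
    expect_lt(similarity(x, y), 0.75)
  }
})

test_that("removing a shared token never increases the token overlap", {
  set.seed(7)
  vocab <- c("medical", "college", "hospital", "institute", "pune", "care",
             "centre", "city", "general", "trust")
  for (k in 1:50) {
    a_tok <- sample(vocab, sample(3:6, 1))
    b_tok <- sample(vocab, sample(3:6, 1))
    shared <- intersect(a_tok, b_tok)
    if (length(shared) == 0) next
    a <- paste(a_tok, collapse = " ")
    a_less <- paste(setdiff(a_tok, shared[1]), collapse = " ")
    b <- paste(b_tok, collapse = " ")
    jac <- function(x, y) {
      tx <- normalize_text(x)$tokens
      ty <- normalize_text(y)$tokens
      length(intersect(tx, ty)) / length(union(tx, ty))
    }
    expect_lte(jac(a_less, b), jac(a, b))
  }
})
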