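dict2 <- function() {
  tibble::tibble(
    term = c("retinopathy", "diabetes", "obesity", "heart failure",
             "hyperglycemia", "hyperglycemia"),
    code = c("H36", "E14", "E66", "I50", "R73", "R73"),
    vocabulary = c("ICD10", "ICD10", "ICD10", "ICD10", "ICD10", "CUSTOM"))
}

note1 <- function(text, pid = "P1", date = as.Date("2004-02-01")) {
  tibble::tibble(patient_id = pid, date = date, text = text)
}

test_that("normalize_token strips case and punctuation and applies lemmas", {
  expect_equal(normalize_token("Retinopathy."), "retinopathy")
  expect_equal(normalize_token("ulcers"), "ulcers")
  expect_equal(normalize_token("ulcers", c(ulcers = "ulcer")), "ulcer")
  expect_equal(normalize_token("Heart  Failure!"), "heart failure")
})

test_that("fuzzy_match prefers exact hits and honours the edit budget", {
  d <- as_dictionary(dict2())
  exact <- fuzzy_match("diabetes", d)
  expect_equal(exact$code, "E14")
  expect_false(exact$fuzzy)
  fz <- fuzzy_match("diabtes", d)        # single deletion
  expect_equal(fz$code, "E14")
  expect_true(fz$fuzzy)
  # edit distance two: confirmed by an independent DP oracle, no match
  expect_equal(as.integer(utils::adist("diaxxtes", "diabetes")), 2L)
  expect_equal(nrow(fuzzy_match("diaxxtes", d)), 0L)
  # short tokens never fuzzy-match
  short_d <- as_dictionary(tibble::tibble(term = "gout", code = "M10",
                                          vocabulary = "ICD10"))
  expect_equal(nrow(fuzzy_match("gou", short_d)), 0L)
  expect_equal(nrow(fuzzy_match("diabtes", d, max_edits = 0L)), 0L)
})

test_that("detect_negation flags cue words before the mention", {
  toks <- c("no", "sign", "of", "retinopathy")
  expect_true(detect_negation(toks, 4L))
  expect_true(detect_negation(c("the", "patient's", "mother", "had",
                                "retinopathy"), 5L))
  expect_false(detect_negation(c("patient", "has", "retinopathy"), 3L))
  # cue outside the window does not negate
  toks_far <- c("not", rep("filler", 6L), "retinopathy")
  expect_false(detect_negation(toks_far, 8L, window = 5L))
})

test_that("tag_corpus finds mentions with spans, flags and dates", {
  res <- tag_corpus(note1("patient has retinopathy. no sign of obesity."),
                    dict2())
  m <- res$mentions
  expect_equal(nrow(m), 2L)
  ret <- m[m$code == "H36", ]
  expect_false(ret$negated)
  expect_equal(substr("patient has retinopathy. no sign of obesity.",
                      ret$start, ret$end), "retinopathy")
  expect_true(m$negated[m$code == "E66"])
  # only the asserted mention becomes a code event
  expect_equal(res$events$code, "H36")
})

test_that("a negated then later asserted term yields one dated event", {
  notes <- dplyr::bind_rows(
    note1("no sign of retinopathy today.", date = as.Date("2004-01-01")),
    note1("exam shows retinopathy.", date = as.Date("2004-06-01")))
  res <- tag_corpus(notes, dict2())
  expect_equal(nrow(res$mentions), 2L)
  expect_equal(nrow(res$events), 1L)
  expect_equal(res$events$date, as.Date("2004-06-01"))
})

test_that("duplicate codes from two vocabularies collapse at one locus", {
  res <- tag_corpus(note1("patient has hyperglycemia."), dict2())
  expect_equal(nrow(res$mentions), 1L)
  expect_equal(res$mentions$code, "R73")
})

test_that("multi-token terms match longest-first, also with one typo", {
  res <- tag_corpus(note1("patient has heart failure."), dict2())
  expect_equal(res$mentions$code, "I50")
  expect_equal(res$mentions$surface, "heart failure")
  fz <- tag_corpus(note1("patient has heart failXre."), dict2())
  expect_equal(fz$mentions$code, "I50")
  expect_true(fz$mentions$fuzzy)
})

test_that("the blocklist suppresses rejected fuzzy variants only", {
  bl <- tibble::tibble(variant = "diabtes", code = "E14")
  res <- tag_corpus(note1("patient has diabtes."), dict2(), blocklist = bl)
  expect_equal(nrow(res$mentions), 0L)
  keep <- tag_corpus(note1("patient has diabetes."), dict2(),
                     blocklist = bl)
  expect_equal(keep$mentions$code, "E14")
})

test_that("tagging is order-independent across notes", {
  co <- generate_cohort(cohort_config(n_patients = 25, k_clusters = 2,
                                      seed = 11))
  fwd <- tag_corpus(co$notes, co$dictionaries)$mentions
  rev_notes <- co$notes[rev(seq_len(nrow(co$notes))), ]
  bwd <- tag_corpus(rev_notes, co$dictionaries)$mentions
  key <- function(m) {
    sort(paste(m$patient_id, m$note_id, m$code, m$start, m$negated))
  }
  expect_identical(key(fwd), key(bwd))
})

test_that("empty notes and empty corpora produce empty results, not errors", {
  res <- tag_corpus(note1(""), dict2())
  expect_equal(nrow(res$mentions), 0L)
  expect_equal(nrow(res$events), 0L)
  expect_error(tag_corpus(note1("x"), dict2()[0, ]), "non-empty")
})
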