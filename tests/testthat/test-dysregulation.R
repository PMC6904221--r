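hb_series <- function(values, dates, pid = "P1") {
  tibble::tibble(patient_id = pid, date = as.Date("2004-01-01") + dates,
                 value = values)
}

test_that("segment filtering applies the count, span and range rules", {
  # five values over 100 days: one valid segment
  a <- preprocess_hba1c(hb_series(rep(50, 5), c(0, 25, 50, 75, 100)))
  expect_true(all(a$valid))
  expect_equal(unique(a$segment), 1L)
  # four values over 200 days: below the count minimum
  b <- preprocess_hba1c(hb_series(rep(50, 4), c(0, 70, 140, 200)))
  expect_false(any(b$valid))
  # five values over 60 days: below the span minimum
  c_ <- preprocess_hba1c(hb_series(rep(50, 5), c(0, 15, 30, 45, 60)))
  expect_false(any(c_$valid))
  # out-of-range values removed before any other rule
  d <- preprocess_hba1c(hb_series(c(14, 60, 190), c(0, 10, 20)))
  expect_equal(d$value, 60)
})

test_that("long gaps split a series into separate segments", {
  dates <- c(0, 30, 60, 90, 120, 600, 630, 660, 690, 720)
  p <- preprocess_hba1c(hb_series(rep(55, 10), dates))
  expect_equal(unique(p$segment), c(1L, 2L))
  expect_true(all(p$valid))
  # same-day duplicates collapse to their mean
  dup <- preprocess_hba1c(hb_series(c(40, 60), c(0, 0)))
  expect_equal(dup$value, 50)
})

test_that("code criteria follow their definitions", {
  ev <- ev_tbl(c("a", "b", "c"), c("sdcL03", "E89", "I10"))
  res <- code_criteria(ev)
  expect_equal(res$has_dysreg_code, c(TRUE, FALSE, FALSE))
  expect_equal(res$has_hyper_code, c(FALSE, TRUE, FALSE))
  with_ids <- code_criteria(ev, patient_ids = c("a", "d"))
  expect_equal(with_ids$has_dysreg_code, c(TRUE, FALSE))
})

test_that("constant and sub-threshold series never flag a change point", {
  expect_length(phenostrat:::segment_changepoints(rep(50, 12)), 0L)
  set.seed(81)
  # a clear change in location but below the magnitude gate
  x <- c(rnorm(10, 50, 0.5), rnorm(10, 53, 0.5))
  expect_length(phenostrat:::segment_changepoints(x, min_shift = 5), 0L)
})

test_that("a planted level jump is found near its true position", {
  set.seed(83)
  found <- 0L
  for (r in 1:20) {
    x <- c(rnorm(10, 50, 2), rnorm(10, 80, 2))
    cp <- phenostrat:::segment_changepoints(x)
    if (length(cp) == 1L && abs(cp - 11L) <= 2L) found <- found + 1L
  }
  expect_gte(found, 18L)
})

test_that("changepoint_flag aggregates over patients and segments", {
  set.seed(85)
  hb <- dplyr::bind_rows(
    hb_series(c(rnorm(6, 50, 1), rnorm(6, 75, 1)),
              seq(0, 330, by = 30), pid = "jump"),
    hb_series(rnorm(12, 50, 1), seq(0, 330, by = 30), pid = "flat"),
    hb_series(rep(55, 3), c(0, 10, 20), pid = "short"))
  prep <- preprocess_hba1c(hb)
  res <- changepoint_flag(prep)
  flags <- res$flags
  expect_true(flags$changepoint[flags$patient_id == "jump"])
  expect_false(flags$changepoint[flags$patient_id == "flat"])
  expect_false(flags$evaluable[flags$patient_id == "short"])
  expect_equal(res$changepoints$patient_id, "jump")
  expect_lte(abs(res$changepoints$index - 7L), 2L)
})

test_that("onset model recovers a constant level and shrinks singletons", {
  set.seed(87)
  n <- 30
  rows <- lapply(seq_len(n), function(i) {
    hb_series(rep(45, 6) + rnorm(6, 0, 0.5), seq(0, 300, by = 60),
              pid = sprintf("c%02d", i))
  })
  hb <- dplyr::bind_rows(rows)
  prep <- preprocess_hba1c(hb)
  onsets <- tibble::tibble(patient_id = sprintf("c%02d", 1:n),
                           onset_date = as.Date("2004-01-01"))
  res <- onset_level_flag(prep, onsets)
  expect_true(all(abs(res$onset_value - 45) < 2))
  expect_false(any(res$onset_level))
  # a patient with one valid point shrinks toward the population mean
  hb2 <- dplyr::bind_rows(
    hb,
    hb_series(rep(80, 5), c(0, 30, 60, 90, 120), pid = "solo"))
  prep2 <- preprocess_hba1c(hb2)
  prep2$valid[prep2$patient_id == "solo"][-1L] <- FALSE
  res2 <- onset_level_flag(prep2, dplyr::bind_rows(
    onsets, tibble::tibble(patient_id = "solo",
                           onset_date = as.Date("2004-01-01"))))
  solo <- res2$onset_value[res2$patient_id == "solo"]
  expect_lt(solo, 80)     # pulled toward the 45-level population
  expect_gt(solo, 45)
  # missing onset dates make the criterion non-evaluable, flag false
  res3 <- onset_level_flag(prep, onsets[-1L, ])
  expect_false(res3$onset_level[res3$patient_id == "c01"])
  expect_false(res3$evaluable[res3$patient_id == "c01"])
})

test_that("severity flag counts the fraction at or above threshold", {
  mk <- function(vals, pid) hb_series(vals, seq(0, by = 30,
                                                length.out = length(vals)),
                                      pid = pid)
  hb <- dplyr::bind_rows(
    mk(rep(40, 6), "low"), mk(rep(80, 6), "high"),
    mk(c(rep(55, 6), rep(40, 4)), "mixed"))
  res <- severity_flag(preprocess_hba1c(hb))
  f <- res$flags
  expect_false(f$severity[f$patient_id == "low"])
  expect_true(f$severity[f$patient_id == "high"])
  expect_true(f$severity[f$patient_id == "mixed"])   # 6/10 >= 53
  expect_equal(f$frac_above[f$patient_id == "mixed"], 0.6)
  bins <- res$bin_freq
  expect_equal(sum(bins$freq[bins$patient_id == "low"]), 1)
})

test_that("the score counts true criteria and thresholds at three", {
  flags <- tibble::tibble(
    patient_id = c("p1", "p2", "p3"),
    has_dysreg_code = c(FALSE, TRUE, TRUE),
    has_hyper_code = c(FALSE, TRUE, TRUE),
    changepoint = c(FALSE, TRUE, TRUE),
    onset_level = c(FALSE, FALSE, TRUE),
    severity = c(FALSE, FALSE, TRUE))
  prof <- dysregulation_score(flags)
  expect_equal(prof$score, c(0L, 3L, 5L))
  expect_equal(prof$dysregulated, c(FALSE, TRUE, TRUE))
})

test_that("lab normalization filters on coverage and standardizes", {
  set.seed(89)
  ids <- sprintf("p%03d", 1:100)
  labs <- dplyr::bind_rows(
    tibble::tibble(patient_id = rep(ids, each = 2L),
                   test_id = "T_full", date = as.Date("2005-01-01"),
                   value = rnorm(200, 7, 2)),
    tibble::tibble(patient_id = rep(ids[1:60], each = 2L),
                   test_id = "T_sparse", date = as.Date("2005-01-01"),
                   value = rnorm(120)))
  res <- normalize_labs(labs, population = ids)
  expect_equal(attr(res, "tests"), "T_full")      # 60% coverage dropped
  expect_false("T_sparse" %in% res$test_id)
  expect_equal(mean(res$mean), 0, tolerance = 0.2)
})

test_that("lab contrasts separate a shifted group and control the null", {
  set.seed(91)
  ids <- sprintf("p%03d", 1:200)
  grp <- tibble::tibble(patient_id = ids,
                        group = rep(c("dys", "reg"), each = 100L))
  mk <- function(test, shift) {
    tibble::tibble(patient_id = ids, test_id = test,
                   date = as.Date("2005-01-01"),
                   value = rnorm(200) + c(rep(shift, 100), rep(0, 100)))
  }
  labs <- dplyr::bind_rows(mk("T_shift", 1), mk("T_null", 0))
  res <- lab_contrasts(normalize_labs(labs, population = ids), grp)
  expect_lt(res$manova$p_value, 0.01)
  ks <- res$ks
  expect_true(all(ks$significant[ks$test_id == "T_shift"]))
  expect_false(any(ks$significant[ks$test_id == "T_null"]))
  expect_gt(ks$mean_diff[ks$test_id == "T_shift" & ks$group == "dys"], 0)
})
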