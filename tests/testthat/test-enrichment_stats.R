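make_strata <- function(ids, stratum = "F:1950") {
  tibble::tibble(patient_id = ids, stratum = stratum)
}

test_that("a uniform-prevalence cluster hits the closed-form binomial tail", {
  # 20 corpus patients, prevalence 1/2 in the single stratum; a cluster of
  # 10 all carrying the code has p = 0.5^10 before adjustment
  ids <- sprintf("p%02d", 1:20)
  carriers <- ids[1:10]
  ev <- ev_tbl(carriers, rep("I10", 10L))
  part <- tibble::tibble(patient_id = ids,
                         cluster = rep(c(1L, 2L), each = 10L))
  res <- stratified_binomial_enrichment(part, ev, make_strata(ids),
                                        min_support = 1L)
  row <- res[res$cluster == 1L & res$code == "I10", ]
  expect_equal(row$p0, 0.5)
  expect_equal(row$p_value, 0.5^10, tolerance = 1e-12)
  expect_equal(row$observed, 10L)
  expect_equal(row$expected, 5)
})

test_that("observing exactly the expected proportion is never enriched", {
  ids <- sprintf("p%02d", 1:40)
  carriers <- c(ids[1:5], ids[21:25])      # prevalence 1/4 in both halves
  ev <- ev_tbl(carriers, rep("I10", 10L))
  part <- tibble::tibble(patient_id = ids,
                         cluster = rep(c(1L, 2L), each = 20L))
  res <- stratified_binomial_enrichment(part, ev, make_strata(ids),
                                        min_support = 1L)
  expect_true(all(res$p_value >= 0.5))
})

test_that("a single stratum reduces to the unstratified binomial", {
  set.seed(61)
  ids <- sprintf("p%03d", 1:100)
  ev <- ev_tbl(sample(ids, 140, replace = TRUE),
               sample(c("I10", "E66", "H36"), 140, replace = TRUE))
  part <- tibble::tibble(patient_id = ids,
                         cluster = sample(1:3, 100, replace = TRUE))
  res <- stratified_binomial_enrichment(part, ev, make_strata(ids),
                                        min_support = 1L)
  presence <- dplyr::distinct(ev, patient_id, code)
  for (i in seq_len(nrow(res))) {
    prev <- sum(presence$code == res$code[i]) / 100
    expect_equal(res$p0[i], prev, tolerance = 1e-12)
    expect_equal(res$p_value[i],
                 oracle_binom_upper(res$observed[i], res$cluster_size[i],
                                    prev),
                 tolerance = 1e-9)
  }
})

test_that("stratification corrects a sex-confounded code", {
  # code carried only by males; cluster 1 is all male. Unstratified the
  # cluster looks enriched; the sex stratum absorbs the excess.
  set.seed(59)
  ids <- sprintf("p%03d", 1:200)
  sex <- rep(c("M", "F"), each = 100L)
  carriers <- sample(ids[sex == "M"], 60L)
  ev <- ev_tbl(carriers, rep("N40", length(carriers)))
  part <- tibble::tibble(
    patient_id = ids,
    cluster = c(rep(1L, 50), rep(2L, 50), rep(2L, 100)))
  strata <- tibble::tibble(patient_id = ids, stratum = sex)
  res <- stratified_binomial_enrichment(part, ev, strata, min_support = 1L)
  naive <- stratified_binomial_enrichment(part, ev, make_strata(ids),
                                          min_support = 1L)
  p_corr <- res$p_value[res$cluster == 1L & res$code == "N40"]
  p_naive <- naive$p_value[naive$cluster == 1L & naive$code == "N40"]
  expect_gt(p_corr, 0.05)
  expect_lt(p_naive, 0.05)
  expect_equal(res$p0[res$cluster == 1L], 0.6)  # male prevalence
})

test_that("BH adjustment is monotone and the support filter applies", {
  set.seed(63)
  ids <- sprintf("p%03d", 1:150)
  ev <- ev_tbl(sample(ids, 600, replace = TRUE),
               sample(paste0("C", 1:8), 600, replace = TRUE))
  part <- tibble::tibble(patient_id = ids,
                         cluster = sample(1:3, 150, replace = TRUE))
  res <- stratified_binomial_enrichment(part, ev, make_strata(ids),
                                        min_support = 10L)
  expect_true(all(res$observed >= 10L))
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
  expect_true(all(res$p_adjusted <= 1))
  ord <- order(res$p_value)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-12))
  expect_error(
    stratified_binomial_enrichment(part, ev, make_strata(ids[-1])),
    "strata undefined")
})

test_that("metadata contrasts find a planted location shift", {
  set.seed(65)
  ids <- sprintf("p%03d", 1:240)
  part <- tibble::tibble(patient_id = ids,
                         cluster = rep(1:4, each = 60L))
  age <- rnorm(240, 60, 8)
  age[1:60] <- age[1:60] + 10            # cluster 1 is 10 years older
  pts <- tibble::tibble(patient_id = ids, age = age,
                        flat = rnorm(240))
  res <- metadata_contrasts(part, pts)
  shifted <- res[res$cluster == 1L & res$field == "age", ]
  expect_true(shifted$significant)
  expect_gt(shifted$mean, shifted$rest_median)
  null_rows <- res[res$field == "flat", ]
  expect_true(all(null_rows$p_adjusted > 0.05, na.rm = TRUE))
})

test_that("degenerate metadata cases yield NA p-values, not errors", {
  part <- tibble::tibble(patient_id = c("a", "b", "c"),
                         cluster = c(1L, 2L, 2L))
  pts <- tibble::tibble(patient_id = c("a", "b", "c"),
                        age = c(50, 60, 70), const = c(1, 1, 1))
  res <- metadata_contrasts(part, pts)
  expect_true(is.na(res$p_value[res$cluster == 1L & res$field == "age"]))
  expect_true(all(is.na(res$p_value[res$field == "const"])))
})

test_that("ATC truncation handles all levels and malformed codes", {
  expect_equal(atc_truncate("C07AB02", 3), "C07A")
  expect_equal(atc_truncate("C07AB02", 1), "C")
  expect_equal(atc_truncate("C07AB02", 4), "C07AB")
  expect_equal(atc_truncate("C07AB02", 5), "C07AB02")
  expect_true(is.na(atc_truncate("B02", 3)))
  expect_true(is.na(atc_truncate("7C0AB02", 3)))
})

test_that("a drug class carried by everyone cannot be enriched", {
  ids <- sprintf("p%03d", 1:120)
  part <- tibble::tibble(patient_id = ids,
                         cluster = rep(1:2, each = 60L))
  rx <- tibble::tibble(patient_id = ids, atc = "A10AB01",
                       date = as.Date("2005-01-01"))
  res <- prescription_enrichment(part, rx, min_cluster_size = 50L)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$odds_ratio %in% c(0, 1) | is.infinite(res$odds_ratio) |
                    abs(res$odds_ratio - 1) < 1e-9))
})

test_that("a planted cluster-specific drug class is recovered", {
  set.seed(67)
  ids <- sprintf("p%03d", 1:200)
  part <- tibble::tibble(patient_id = ids,
                         cluster = rep(1:2, each = 100L))
  rx <- dplyr::bind_rows(
    tibble::tibble(patient_id = ids[1:80], atc = "C07AB02"),
    tibble::tibble(patient_id = sample(ids, 60), atc = "A02BC01"))
  rx$date <- as.Date("2006-01-01")
  expect_warning(
    res <- prescription_enrichment(
      dplyr::bind_rows(part, tibble::tibble(patient_id = "x", cluster = 9L)),
      dplyr::bind_rows(rx, tibble::tibble(patient_id = "x", atc = "??",
                                          date = as.Date("2006-01-01"))),
      min_cluster_size = 50L),
    "malformed")
  hit <- res[res$cluster == 1L & res$class == "C07A", ]
  expect_true(hit$significant)
  expect_equal(hit$direction, "enriched")
  # clusters under the size floor are not tested
  expect_false(9L %in% res$cluster)
})
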