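test_that("comorbidity score is zero at independence and antisymmetric", {
  # 100 patients; A and B independent with expected co-occurrence 4
  ids <- sprintf("p%03d", 1:100)
  ev <- dplyr::bind_rows(
    ev_tbl(ids[1:20], rep("AA1", 20)),
    ev_tbl(ids[c(1:4, 21:36)], rep("BB1", 20)))
  res <- pair_cooccurrence(ev, population = ids, min_carriers = 5L)
  expect_equal(res$n_both, 4L)
  expect_equal(res$expected, 4)
  expect_equal(res$cs, 0)
  # flipping observed and expected flips the score's sign
  s <- 1
  expect_equal(log2((10 + s) / (4 + s)), -log2((4 + s) / (10 + s)))
})

test_that("Fisher p-values equal the hypergeometric enumeration oracle", {
  # the printed 2x2 fixture [[20,5],[5,70]]
  ids <- sprintf("p%03d", 1:100)
  a_carriers <- ids[1:25]
  b_carriers <- ids[c(1:20, 26:30)]
  ev <- dplyr::bind_rows(ev_tbl(a_carriers, rep("AA1", 25)),
                         ev_tbl(b_carriers, rep("BB1", 25)))
  res <- pair_cooccurrence(ev, population = ids, min_carriers = 5L)
  expect_equal(res$n_both, 20L)
  expect_equal(res$p_cooccur, oracle_fisher_p(20, 5, 5, 70),
               tolerance = 1e-9)
  expect_equal(res$p_cooccur,
               fisher.test(matrix(c(20, 5, 5, 70), 2))$p.value,
               tolerance = 1e-12)
})

test_that("direction counts partition the carriers of both codes", {
  d0 <- as.Date("2000-01-01")
  ev <- dplyr::bind_rows(
    ev_tbl(c("a", "b", "c", "d"), rep("AA1", 4),
           date = d0 + c(0, 0, 50, 10)),
    ev_tbl(c("a", "b", "c", "e"), rep("BB1", 4),
           date = d0 + c(30, 0, 20, 5)))
  res <- pair_directionality(ev, tibble::tibble(code_a = "AA1",
                                                code_b = "BB1"))
  expect_equal(res$n_carriers, 3L)
  expect_equal(res$n_ab, 1L)   # a: 0 -> 30
  expect_equal(res$n_ba, 1L)   # c: 50 -> 20
  expect_equal(res$ties, 1L)   # b, excluded from direction counts
  expect_equal(res$n_ab + res$n_ba + res$ties, res$n_carriers)
  expect_equal(res$mean_lag, mean(c(30, -30)))
  # symmetric counts leave both directional p-values at or above 0.5
  expect_gte(res$p_a_before_b, 0.5)
  expect_gte(res$p_b_before_a, 0.5)
})

test_that("a fully ordered pair hits the closed-form sign-test tail", {
  d0 <- as.Date("2000-01-01")
  n <- 30
  ids <- sprintf("p%02d", 1:n)
  ev <- dplyr::bind_rows(
    ev_tbl(ids, rep("AA1", n), date = d0),
    ev_tbl(ids, rep("BB1", n), date = d0 + 100))
  res <- pair_directionality(ev, tibble::tibble(code_a = "AA1",
                                                code_b = "BB1"))
  expect_equal(res$p_a_before_b, 0.5^30, tolerance = 1e-12)
  expect_equal(res$direction, "A_before_B")
  expect_equal(res$mean_lag, 100)
})

test_that("greedy top-pair extraction equals the brute-force best prefix", {
  set.seed(71)
  pairs <- tibble::tibble(
    code_a = c("A", "A", "B", "C", "E", "F", "G", "A", "H", "I"),
    code_b = c("B", "C", "C", "D", "F", "G", "H", "D", "I", "J"),
    p_adjusted = sort(runif(10)))
  got <- top_pairs_by_unique_codes(pairs, max_unique = 5L)
  # oracle: longest prefix of the ranked list within the code budget
  ranked <- pairs[order(pairs$p_adjusted), ]
  best <- 0L
  for (k in seq_len(nrow(ranked))) {
    if (length(unique(c(ranked$code_a[1:k], ranked$code_b[1:k]))) <= 5L) {
      best <- k
    } else {
      break
    }
  }
  expect_equal(nrow(got), best)
  expect_lte(length(unique(c(got$code_a, got$code_b))), 5L)
  # under budget: everything is taken; shared codes admit extra pairs
  all_in <- top_pairs_by_unique_codes(pairs[1:3, ], max_unique = 4L)
  expect_equal(nrow(all_in), 3L)
  expect_gt(3L, 4L / 2L)
})

test_that("group-unique pairs are significant in exactly one group", {
  mk <- function(sig_pairs) {
    tibble::tibble(code_a = c("A", "C"), code_b = c("B", "D"),
                   significant = sig_pairs)
  }
  res <- group_unique_pairs(list(g1 = mk(c(TRUE, TRUE)),
                                 g2 = mk(c(TRUE, FALSE))))
  expect_equal(nrow(res), 1L)
  expect_equal(res$group, "g1")
  expect_equal(res$code_a, "C")
  none <- group_unique_pairs(list(g1 = mk(c(TRUE, TRUE)),
                                  g2 = mk(c(TRUE, TRUE))))
  expect_equal(nrow(none), 0L)
})

test_that("lag ANOVA flags a shifted group and skips degenerate input", {
  set.seed(73)
  lag_tab <- tibble::tibble(
    code_a = "AA1", code_b = "BB1",
    group = rep(c("g1", "g2", "g3"), each = 20L),
    patient_id = sprintf("p%02d", 1:60),
    lag = c(rnorm(20, 100, 30), rnorm(20, 100, 30), rnorm(20, 400, 30)))
  res <- lag_anova(lag_tab)
  expect_true(res$significant)
  one_group <- lag_anova(dplyr::filter(lag_tab, group == "g1"))
  expect_true(is.na(one_group$p_value))
  # null: identical lag distributions are rarely significant
  null_tab <- lag_tab
  null_tab$lag <- rnorm(60, 100, 30)
  expect_gt(lag_anova(null_tab)$p_value, 0.001)
})

test_that("first occurrence takes the earliest of assigned or mined dates", {
  d0 <- as.Date("2000-01-01")
  ev <- dplyr::bind_rows(
    ev_tbl("a", "AA1", date = d0 + 50, source = "assigned"),
    ev_tbl("a", "AA1", date = d0, source = "mined"),
    ev_tbl("a", "BB1", date = d0 + 10))
  firsts <- phenostrat:::first_occurrence(ev)
  expect_equal(firsts$first_date[firsts$code == "AA1"], d0)
  res <- pair_directionality(ev, tibble::tibble(code_a = "AA1",
                                                code_b = "BB1"))
  expect_equal(res$n_ab, 1L)
  expect_equal(res$mean_lag, 10)
})
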