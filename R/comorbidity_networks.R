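# Pairwise comorbidity statistics: co-occurrence Fisher tests with a log2
# comorbidity score, temporal directionality by exact sign tests on
# first-occurrence order, top-pair extraction under a unique-code budget,
# group-unique pairs, and cross-group time-lag ANOVA.

patient_code_presence <- function(events) {
  assert_cols(events, c("patient_id", "code"), "events")
  distinct(events, patient_id, code)
}

#' Comorbidity co-occurrence statistics for all code pairs
#'
#' For every unordered pair of sufficiently common codes: a two-sided
#' Fisher exact test on joint presence, the expected co-occurrence
#' `n_A n_B / N` under independence, and the comorbidity score
#' `CS = log2((n_both + s) / (expected + s))` with smoothing `s` guarding
#' the logarithm. P-values are Bonferroni-adjusted across all pairs;
#' significance is called at adjusted p <= 0.01.
#'
#' @param events code event stream (`patient_id`, `code`).
#' @param population optional character vector of all patient ids defining
#'   `N` (defaults to the patients present in `events`).
#' @param min_carriers smallest per-code carrier count entering the pair
#'   analysis.
#' @param smoothing additive smoothing `s` in the comorbidity score.
#' @param alpha significance level on adjusted p-values.
#' @return a tibble of pair statistics (`code_a < code_b`), one row per
#'   pair: counts of the 2x2 table, `expected`, `cs`, `p_cooccur`,
#'   `p_adjusted`, `direction`, `significant`.
#' @export
pair_cooccurrence <- function(events, population = NULL, min_carriers = 10L,
                              smoothing = 1, alpha = 0.01) {
  presence <- patient_code_presence(events)
  pats <- population %||% sort(unique(presence$patient_id))
  n_pop <- length(pats)
  presence <- filter(presence, patient_id %in% pats)
  carriers <- count(presence, code, name = "n")
  keep <- carriers$code[carriers$n >= min_carriers]
  if (length(keep) < 2L) {
    return(empty_pairstats())
  }
  presence <- filter(presence, code %in% keep)
  codes <- sort(unique(presence$code))
  x <- sparseMatrix(i = match(presence$patient_id, pats),
                    j = match(presence$code, codes),
                    x = 1, dims = c(n_pop, length(codes)),
                    dimnames = list(pats, codes))
  joint <- as.matrix(Matrix::crossprod(x))
  n_code <- Matrix::diag(joint)
  pair_idx <- which(upper.tri(joint), arr.ind = TRUE)
  n_a <- unname(n_code[pair_idx[, 1L]])
  n_b <- unname(n_code[pair_idx[, 2L]])
  n_both <- unname(joint[pair_idx])
  expected <- n_a * n_b / n_pop
  p <- vapply(seq_along(n_both), function(i) {
    a <- n_both[i]
    tab <- matrix(c(a, n_a[i] - a, n_b[i] - a,
                    n_pop - n_a[i] - n_b[i] + a), nrow = 2L)
    fisher.test(tab)$p.value
  }, numeric(1L))
  res <- tibble(
    code_a = codes[pair_idx[, 1L]],
    code_b = codes[pair_idx[, 2L]],
    n_both = as.integer(n_both),
    n_a_only = as.integer(n_a - n_both),
    n_b_only = as.integer(n_b - n_both),
    n_neither = as.integer(n_pop - n_a - n_b + n_both),
    expected = expected,
    cs = log2((n_both + smoothing) / (expected + smoothing)),
    p_cooccur = p,
    p_adjusted = p.adjust(p, method = "bonferroni")
  )
  res$direction <- if_else(res$n_both >= res$expected, "together", "apart")
  res$significant <- res$p_adjusted <= alpha
  arrange(res, p_adjusted, code_a, code_b)
}

empty_pairstats <- function() {
  tibble(code_a = character(), code_b = character(), n_both = integer(),
         n_a_only = integer(), n_b_only = integer(), n_neither = integer(),
         expected = numeric(), cs = numeric(), p_cooccur = numeric(),
         p_adjusted = numeric(), direction = character(),
         significant = logical())
}

first_occurrence <- function(events) {
  assert_cols(events, c("patient_id", "code", "date"), "events")
  events |>
    group_by(patient_id, code) |>
    summarise(first_date = min(date), .groups = "drop")
}

#' Temporal directionality of diagnosis pairs
#'
#' Among patients carrying both codes of a pair on distinct first dates,
#' counts how often code A precedes code B and vice versa, and tests each
#' direction with an exact binomial sign test against 0.5 (the only exact
#' test determined by first-occurrence order). Same-day ties are excluded
#' from the direction counts and reported. The mean lag is
#' `mean(first(B) - first(A))` in days over carriers of both codes with
#' distinct dates. Each directional p-value family is Bonferroni-adjusted
#' separately; significance at adjusted p <= 0.01.
#'
#' @param events dated code event stream.
#' @param pairs tibble `code_a`, `code_b` of pairs to score (e.g. from
#'   [pair_cooccurrence()]); when `NULL`, all pairs of codes with at least
#'   `min_carriers` carriers.
#' @param min_carriers carrier floor used when `pairs` is `NULL`.
#' @param alpha significance level on adjusted p-values.
#' @return tibble per pair: `n_ab` (A first), `n_ba`, `ties`, `mean_lag`
#'   (days), directional p-values and adjusted versions, and the called
#'   `direction` (`"A_before_B"`, `"B_before_A"` or `"none"`).
#' @export
pair_directionality <- function(events, pairs = NULL, min_carriers = 10L,
                                alpha = 0.01) {
  firsts <- first_occurrence(events)
  if (is.null(pairs)) {
    carriers <- count(firsts, code, name = "n")
    keep <- sort(carriers$code[carriers$n >= min_carriers])
    if (length(keep) < 2L) {
      stop("fewer than two codes pass the carrier floor", call. = FALSE)
    }
    pairs <- as_tibble(t(utils::combn(keep, 2L)), .name_repair = ~
                         c("code_a", "code_b"))
  }
  assert_cols(pairs, c("code_a", "code_b"), "pairs")
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- firsts[firsts$code == pairs$code_a[i], ]
    b <- firsts[firsts$code == pairs$code_b[i], ]
    both <- inner_join(a, b, by = "patient_id", suffix = c("_a", "_b"))
    lag <- as.numeric(both$first_date_b - both$first_date_a)
    n_ab <- sum(lag > 0)
    n_ba <- sum(lag < 0)
    ties <- sum(lag == 0)
    m <- n_ab + n_ba
    rows[[i]] <- tibble(
      code_a = pairs$code_a[i], code_b = pairs$code_b[i],
      n_carriers = nrow(both), n_ab = n_ab, n_ba = n_ba, ties = ties,
      mean_lag = if (m > 0) mean(lag[lag != 0]) else NA_real_,
      p_a_before_b = if (m > 0) {
        pbinom(n_ab - 1L, m, 0.5, lower.tail = FALSE)
      } else NA_real_,
      p_b_before_a = if (m > 0) {
        pbinom(n_ba - 1L, m, 0.5, lower.tail = FALSE)
      } else NA_real_
    )
  }
  res <- bind_rows(rows)
  res$p_ab_adjusted <- p.adjust(res$p_a_before_b, method = "bonferroni")
  res$p_ba_adjusted <- p.adjust(res$p_b_before_a, method = "bonferroni")
  res$direction <- dplyr::case_when(
    !is.na(res$p_ab_adjusted) & res$p_ab_adjusted <= alpha ~ "A_before_B",
    !is.na(res$p_ba_adjusted) & res$p_ba_adjusted <= alpha ~ "B_before_A",
    TRUE ~ "none"
  )
  res
}

#' Most significant pairs under a unique-code budget
#'
#' Takes pairs in order of increasing adjusted p-value and stops before
#' the pair whose inclusion would push the number of distinct codes above
#' `max_unique`.
#'
#' @param pairs ranked pair table with `code_a`, `code_b` and the ranking
#'   column `p_col`.
#' @param max_unique budget of distinct codes.
#' @param p_col name of the column to rank by (ascending).
#' @return the selected prefix of `pairs`.
#' @export
top_pairs_by_unique_codes <- function(pairs, max_unique = 100L,
                                      p_col = "p_adjusted") {
  assert_cols(pairs, c("code_a", "code_b", p_col), "pairs")
  pairs <- pairs[order(pairs[[p_col]]), ]
  seen <- character()
  take <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    cand <- union(seen, c(pairs$code_a[i], pairs$code_b[i]))
    if (length(cand) > max_unique) break
    seen <- cand
    take[i] <- TRUE
  }
  pairs[take, ]
}

#' Comorbidity pairs unique to one symptom group
#'
#' @param pair_results named list of pair tables (one per symptom group)
#'   with a logical `significant` column.
#' @return tibble `group`, `code_a`, `code_b` of pairs significant in
#'   exactly one group, with that group's statistics.
#' @export
group_unique_pairs <- function(pair_results) {
  stopifnot(is.list(pair_results), !is.null(names(pair_results)))
  sig <- bind_rows(lapply(names(pair_results), function(g) {
    df <- pair_results[[g]]
    assert_cols(df, c("code_a", "code_b", "significant"), "pair table")
    mutate(filter(df, significant), group = g)
  }))
  if (!nrow(sig)) return(sig)
  sig |>
    group_by(code_a, code_b) |>
    filter(n() == 1L) |>
    ungroup() |>
    select(group, dplyr::everything())
}

#' Per-patient first-occurrence lags for code pairs, by patient group
#'
#' @param events dated code event stream.
#' @param pairs tibble `code_a`, `code_b`.
#' @param patient_groups tibble `patient_id`, `group` (e.g. symptom group
#'   membership via cluster).
#' @return tibble `code_a`, `code_b`, `group`, `patient_id`, `lag` (days).
#' @export
pair_lag_table <- function(events, pairs, patient_groups) {
  assert_cols(patient_groups, c("patient_id", "group"), "patient_groups")
  firsts <- first_occurrence(events)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- firsts[firsts$code == pairs$code_a[i], ]
    b <- firsts[firsts$code == pairs$code_b[i], ]
    both <- inner_join(a, b, by = "patient_id", suffix = c("_a", "_b"))
    tibble(code_a = pairs$code_a[i], code_b = pairs$code_b[i],
           patient_id = both$patient_id,
           lag = as.numeric(both$first_date_b - both$first_date_a))
  })
  bind_rows(rows) |>
    inner_join(patient_groups, by = "patient_id") |>
    select(code_a, code_b, group, patient_id, lag)
}

#' One-way ANOVA of pair lags across symptom groups
#'
#' Tests, per pair, whether the first-occurrence time lag differs across
#' patient groups. Pairs with fewer than two groups holding at least two
#' lag observations are skipped.
#'
#' @param lag_table a [pair_lag_table()] result.
#' @param adjust multiple-testing method across pairs (`"BH"` or
#'   `"bonferroni"`).
#' @param alpha significance level on adjusted p-values.
#' @return tibble per pair with `n_groups`, `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
lag_anova <- function(lag_table, adjust = c("BH", "bonferroni"),
                      alpha = 0.05) {
  adjust <- match.arg(adjust)
  assert_cols(lag_table, c("code_a", "code_b", "group", "lag"), "lag_table")
  keys <- distinct(lag_table, code_a, code_b)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    d <- filter(lag_table, code_a == keys$code_a[i],
                code_b == keys$code_b[i])
    ok <- d |> count(group) |> filter(n >= 2L)
    d <- filter(d, group %in% ok$group)
    if (nrow(ok) < 2L || length(unique(d$lag)) < 2L) {
      return(tibble(code_a = keys$code_a[i], code_b = keys$code_b[i],
                    n_groups = nrow(ok), p_value = NA_real_))
    }
    fit <- aov(lag ~ factor(group), data = d)
    tibble(code_a = keys$code_a[i], code_b = keys$code_b[i],
           n_groups = nrow(ok),
           p_value = summary(fit)[[1L]][["Pr(>F)"]][1L])
  })
  res <- bind_rows(rows)
  res$p_adjusted <- p.adjust(res$p_value, method = adjust)
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted <= alpha
  res
}
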