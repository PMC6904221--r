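# Per-cluster enrichment statistics: stratum-corrected binomial tests for
# diagnosis/custom codes, rank-sum contrasts for patient metadata, and
# Fisher tests for prescription (ATC) classes, each with multiple-testing
# control.

#' Patient strata from sex and birth decade
#'
#' @param patients patient table with `patient_id`, `sex`, `birth_date`.
#' @return tibble `patient_id`, `stratum` (e.g. `"F:1950"`).
#' @export
sex_decade_strata <- function(patients) {
  assert_cols(patients, c("patient_id", "sex", "birth_date"), "patients")
  decade <- 10L * (as.integer(format(as.Date(patients$birth_date), "%Y")) %/% 10L)
  tibble(patient_id = patients$patient_id,
         stratum = paste(patients$sex, decade, sep = ":"))
}

#' Stratum-corrected binomial enrichment of codes in clusters
#'
#' For each (cluster, code) pair, the expected probability of carrying the
#' code is the stratum-weighted corpus prevalence: the sum over strata of
#' (stratum share within the cluster) times (code prevalence in that
#' stratum corpus-wide). The p-value is the upper binomial tail of the
#' observed carrier count at that probability, so the test asks for codes
#' found more often than expected while correcting for the cluster's sex
#' and birth-decade composition. Benjamini-Hochberg adjustment is applied
#' across all tests.
#'
#' @param partition partition (or a size-filtered view) of the patients.
#' @param events combined code event stream (`patient_id`, `code`).
#' @param strata tibble `patient_id`, `stratum`; see [sex_decade_strata()].
#' @param min_support smallest in-cluster carrier count tested (the
#'   minimum-support filter is applied before adjustment).
#' @param alpha significance level on the adjusted p-value.
#' @return tibble with cluster, code, observed/expected counts, raw and
#'   BH-adjusted p-values and a `significant` flag.
#' @export
stratified_binomial_enrichment <- function(partition, events, strata,
                                           min_support = 10L,
                                           alpha = 0.05) {
  assign <- if (inherits(partition, "mcl_partition")) {
    partition$assignments
  } else {
    assert_cols(partition, c("patient_id", "cluster"), "partition")
  }
  assert_cols(events, c("patient_id", "code"), "events")
  assert_cols(strata, c("patient_id", "stratum"), "strata")
  miss <- setdiff(assign$patient_id, strata$patient_id)
  if (length(miss)) {
    stop(sprintf("strata undefined for %d clustered patients", length(miss)),
         call. = FALSE)
  }
  presence <- distinct(events, patient_id, code)
  # corpus-wide per-stratum code prevalence
  strat_sizes <- count(strata, stratum, name = "stratum_n")
  empty <- strat_sizes$stratum[strat_sizes$stratum_n == 0L]
  if (length(empty)) {
    warning(sprintf("skipping empty strata: %s", paste(empty, collapse = ", ")))
  }
  prev <- presence |>
    inner_join(strata, by = "patient_id") |>
    count(stratum, code, name = "carriers") |>
    inner_join(strat_sizes, by = "stratum") |>
    mutate(prev = carriers / stratum_n)
  # cluster composition over strata
  comp <- assign |>
    inner_join(strata, by = "patient_id") |>
    count(cluster, stratum, name = "n_cs") |>
    group_by(cluster) |>
    mutate(share = n_cs / sum(n_cs)) |>
    ungroup()
  sizes <- count(assign, cluster, name = "cluster_size")
  observed <- presence |>
    inner_join(assign, by = "patient_id") |>
    count(cluster, code, name = "observed") |>
    filter(observed >= min_support)
  if (!nrow(observed)) return(empty_enrichment())
  expected <- observed |>
    distinct(cluster, code) |>
    inner_join(comp, by = "cluster", relationship = "many-to-many") |>
    left_join(prev, by = c("stratum", "code")) |>
    mutate(prev = replace_na(prev, 0)) |>
    group_by(cluster, code) |>
    summarise(p0 = sum(share * prev), .groups = "drop")
  res <- observed |>
    inner_join(expected, by = c("cluster", "code")) |>
    inner_join(sizes, by = "cluster") |>
    mutate(
      expected = cluster_size * p0,
      p_value = pbinom(observed - 1L, cluster_size, p0, lower.tail = FALSE),
      p_adjusted = p.adjust(p_value, method = "BH"),
      direction = if_else(observed >= expected, "enriched", "depleted"),
      significant = p_adjusted <= alpha
    ) |>
    arrange(p_adjusted, cluster, code)
  select(res, cluster, code, observed, expected, cluster_size, p0,
         p_value, p_adjusted, direction, significant)
}

empty_enrichment <- function() {
  tibble(cluster = integer(), code = character(), observed = integer(),
         expected = numeric(), cluster_size = integer(), p0 = numeric(),
         p_value = numeric(), p_adjusted = numeric(),
         direction = character(), significant = logical())
}

#' Metadata contrasts per cluster (rank-sum against the rest)
#'
#' Summarises numeric patient metadata (e.g. age, observation days,
#' diabetes duration) per cluster and tests each cluster against all
#' remaining clustered patients with a two-sided Wilcoxon rank-sum test,
#' BH-adjusted across the whole family.
#'
#' @param partition partition or assignments tibble.
#' @param patients patient table; `fields` selects its numeric columns
#'   (all numeric columns by default).
#' @param fields character vector of metadata columns to contrast.
#' @param alpha significance level on adjusted p-values.
#' @return tibble cluster x field with mean, median, n, p-values. Clusters
#'   of size one and constant fields yield `NA` p-values.
#' @export
metadata_contrasts <- function(partition, patients, fields = NULL,
                               alpha = 0.05) {
  assign <- if (inherits(partition, "mcl_partition")) {
    partition$assignments
  } else {
    assert_cols(partition, c("patient_id", "cluster"), "partition")
  }
  assert_cols(patients, "patient_id", "patients")
  if (is.null(fields)) {
    fields <- names(patients)[vapply(patients, is.numeric, TRUE)]
  }
  if (!length(fields)) stop("no numeric metadata fields", call. = FALSE)
  dat <- inner_join(assign, patients, by = "patient_id")
  rows <- list()
  for (cl in sort(unique(dat$cluster))) {
    in_cl <- dat$cluster == cl
    for (f in fields) {
      x <- dat[[f]][in_cl]
      y <- dat[[f]][!in_cl]
      p <- NA_real_
      if (sum(!is.na(x)) >= 2L && sum(!is.na(y)) >= 2L &&
          length(unique(na.omit(c(x, y)))) > 1L) {
        p <- suppressWarnings(
          wilcox.test(x, y, exact = FALSE)$p.value)
      }
      rows[[length(rows) + 1L]] <- tibble(
        cluster = cl, field = f, n = sum(!is.na(x)),
        mean = mean(x, na.rm = TRUE), median = median(x, na.rm = TRUE),
        rest_median = median(y, na.rm = TRUE), p_value = p)
    }
  }
  out <- bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted <= alpha
  out
}

#' Truncate ATC codes to a classification level
#'
#' @param atc character vector of ATC codes.
#' @param level 1 (anatomical) to 5 (substance); level 3 is the
#'   pharmacological subgroup (e.g. `A10B`).
#' @return truncated codes; malformed codes give `NA`.
#' @export
atc_truncate <- function(atc, level = 3L) {
  widths <- c(1L, 3L, 4L, 5L, 7L)
  stopifnot(level %in% 1:5)
  w <- widths[level]
  ok <- grepl("^[A-Z][0-9]{2}[A-Z]{0,2}([0-9]{2})?$", atc) & nchar(atc) >= w
  out <- rep(NA_character_, length(atc))
  out[ok] <- substr(atc[ok], 1L, w)
  out
}

#' Prescription enrichment per cluster (Fisher exact on ATC classes)
#'
#' Two-sided Fisher's exact test of the 2x2 table (in cluster / not) x
#' (has ATC class / not), at the requested ATC level, restricted to
#' clusters of at least `min_cluster_size` patients, BH-adjusted.
#'
#' @param partition partition or assignments tibble.
#' @param prescriptions tibble `patient_id`, `atc` (full codes), `date`.
#' @param level ATC truncation level (3 by default).
#' @param min_cluster_size smallest cluster tested (50 by default).
#' @param alpha significance level on adjusted p-values.
#' @return tibble cluster x ATC class with counts, odds ratio, direction,
#'   raw and adjusted p-values.
#' @export
prescription_enrichment <- function(partition, prescriptions, level = 3L,
                                    min_cluster_size = 50L, alpha = 0.05) {
  assign <- if (inherits(partition, "mcl_partition")) {
    partition$assignments
  } else {
    assert_cols(partition, c("patient_id", "cluster"), "partition")
  }
  assert_cols(prescriptions, c("patient_id", "atc"), "prescriptions")
  cls <- atc_truncate(prescriptions$atc, level)
  bad <- is.na(cls)
  if (any(bad)) {
    warning(sprintf("dropping %d prescriptions with malformed ATC codes",
                    sum(bad)))
  }
  presence <- distinct(tibble(patient_id = prescriptions$patient_id[!bad],
                              class = cls[!bad]))
  sizes <- count(assign, cluster, name = "cluster_size")
  big <- sizes$cluster[sizes$cluster_size >= min_cluster_size]
  assign <- filter(assign, cluster %in% big)
  if (!nrow(assign)) {
    return(tibble(cluster = integer(), class = character(),
                  in_cluster = integer(), out_cluster = integer(),
                  cluster_size = integer(), odds_ratio = numeric(),
                  p_value = numeric(), p_adjusted = numeric(),
                  direction = character(), significant = logical()))
  }
  presence <- semi_join(presence, assign, by = "patient_id")
  n_total <- nrow(distinct(assign, patient_id))
  class_totals <- count(presence |> inner_join(assign, by = "patient_id"),
                        class, name = "total_carriers")
  counts <- presence |>
    inner_join(assign, by = "patient_id") |>
    count(cluster, class, name = "in_cluster")
  grid <- tidyr::expand_grid(cluster = sort(unique(assign$cluster)),
                             class = sort(unique(presence$class)))
  res <- grid |>
    left_join(counts, by = c("cluster", "class")) |>
    mutate(in_cluster = replace_na(in_cluster, 0L)) |>
    inner_join(sizes, by = "cluster") |>
    inner_join(class_totals, by = "class") |>
    mutate(out_cluster = total_carriers - in_cluster)
  stat <- vapply(seq_len(nrow(res)), function(i) {
    a <- res$in_cluster[i]
    b <- res$cluster_size[i] - a
    c_ <- res$out_cluster[i]
    d <- n_total - res$cluster_size[i] - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), nrow = 2L))
    c(ft$p.value, unname(ft$estimate))
  }, numeric(2L))
  res$p_value <- stat[1L, ]
  res$odds_ratio <- stat[2L, ]
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res$direction <- if_else(res$odds_ratio >= 1, "enriched", "depleted")
  res$significant <- res$p_adjusted <= alpha
  arrange(res, p_adjusted, cluster, class)
}
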