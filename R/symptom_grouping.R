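# Grouping of patient clusters into symptom-related groups: per-cluster
# frequencies over ICD-10 chapter XVIII level-1 symptom blocks, then
# hierarchical clustering with Euclidean distance and Ward linkage.

#' ICD-10 chapter XVIII level-1 symptom blocks
#'
#' The fixed, ordered blocks of the symptoms-and-signs chapter (R-codes),
#' e.g. `R50-R69` "General symptoms and signs".
#' @export
ICD10_R_BLOCKS <- c("R00-R09", "R10-R19", "R20-R23", "R25-R29", "R30-R39",
                    "R40-R46", "R47-R49", "R50-R69", "R70-R79", "R80-R82",
                    "R83-R89", "R90-R94", "R95-R99")

#' Map ICD-10 codes to their chapter XVIII level-1 block
#'
#' @param code character vector of level-3 codes.
#' @return block labels from [ICD10_R_BLOCKS], `NA` for codes outside
#'   chapter XVIII.
#' @export
symptom_block <- function(code) {
  num <- suppressWarnings(as.integer(substr(code, 2L, 3L)))
  is_r <- grepl("^R[0-9]{2}", code) & !is.na(num)
  lo <- as.integer(substr(ICD10_R_BLOCKS, 2L, 3L))
  hi <- as.integer(substr(ICD10_R_BLOCKS, 6L, 7L))
  out <- rep(NA_character_, length(code))
  if (any(is_r)) {
    idx <- vapply(num[is_r], function(x) {
      w <- which(x >= lo & x <= hi)
      if (length(w)) w[1L] else NA_integer_
    }, integer(1L))
    out[is_r] <- ICD10_R_BLOCKS[idx]
  }
  out
}

#' Per-cluster symptom-block frequency profiles
#'
#' For each cluster, the fraction of its patients having at least one
#' (assigned or mined) code in each chapter XVIII level-1 block.
#'
#' @param partition an `mcl_partition` or assignments tibble; pass the
#'   analysis view ([partition_view()] with `min_size = 50`) to reproduce
#'   the published grouping contract.
#' @param events combined code event stream (`patient_id`, `code`).
#' @return a tibble with column `cluster` and one column per block, every
#'   entry in `[0, 1]`.
#' @export
symptom_profiles <- function(partition, events) {
  assign <- if (inherits(partition, "mcl_partition")) {
    partition$assignments
  } else {
    assert_cols(partition, c("patient_id", "cluster"), "partition")
  }
  if (!nrow(assign)) stop("partition view is empty", call. = FALSE)
  assert_cols(events, c("patient_id", "code"), "events")
  sizes <- count(assign, cluster, name = "size")
  hits <- events |>
    mutate(block = symptom_block(code)) |>
    filter(!is.na(block)) |>
    distinct(patient_id, block) |>
    inner_join(assign, by = "patient_id") |>
    count(cluster, block, name = "n_patients")
  grid <- tidyr::expand_grid(cluster = sort(unique(assign$cluster)),
                             block = ICD10_R_BLOCKS)
  prof <- grid |>
    left_join(hits, by = c("cluster", "block")) |>
    left_join(sizes, by = "cluster") |>
    mutate(freq = replace_na(n_patients, 0L) / size) |>
    select(cluster, block, freq) |>
    pivot_wider(names_from = block, values_from = freq)
  prof[, c("cluster", ICD10_R_BLOCKS)]
}

profile_matrix <- function(profiles) {
  m <- as.matrix(profiles[, ICD10_R_BLOCKS])
  rownames(m) <- profiles$cluster
  m
}

#' Group clusters by hierarchical clustering of symptom profiles
#'
#' Agglomerative clustering of the profile vectors with Euclidean distance
#' and Ward linkage (`"ward.D"`, the classical update on unsquared
#' distances; `"ward.D2"` available), cut into `k` groups.
#'
#' @param profiles a [symptom_profiles()] tibble.
#' @param k number of symptom groups; defaults to 7 (six main groups plus
#'   an outlier in the motivating analysis). The tree cut is exposed
#'   rather than automated.
#' @param method `"ward.D"` or `"ward.D2"`.
#' @return an object of class `symptom_grouping`: list with `groups`
#'   (tibble `cluster`, `group`), `tree` (the `hclust` object), `k`.
#' @export
ward_groups <- function(profiles, k = 7L, method = c("ward.D", "ward.D2")) {
  method <- match.arg(method)
  k <- assert_count(k, "k")
  m <- profile_matrix(profiles)
  if (k > nrow(m)) {
    stop(sprintf("k = %d exceeds the number of clusters (%d)", k, nrow(m)),
         call. = FALSE)
  }
  tree <- hclust(dist(m), method = method)
  cut <- cutree(tree, k = k)
  structure(
    list(groups = tibble(cluster = as.integer(names(cut)),
                         group = unname(cut)),
         tree = tree, k = k, method = method),
    class = "symptom_grouping"
  )
}

#' @export
print.symptom_grouping <- function(x, ...) {
  cat(sprintf("<symptom_grouping> %d clusters in %d groups (%s)\n",
              nrow(x$groups), x$k, x$method))
  invisible(x)
}

#' Export a symptom-grouping dendrogram as Newick text
#'
#' @param grouping a [ward_groups()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_dendrogram <- function(grouping, path) {
  stopifnot(inherits(grouping, "symptom_grouping"))
  tr <- grouping$tree
  build <- function(i) {
    if (i < 0) return(tr$labels[-i])
    sprintf("(%s,%s):%.6g", build(tr$merge[i, 1L]), build(tr$merge[i, 2L]),
            tr$height[i])
  }
  writeLines(paste0(build(nrow(tr$merge)), ";"), path)
  invisible(path)
}
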