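test_that("symptom codes map to their chapter XVIII level-1 blocks", {
  expect_equal(symptom_block(c("R00", "R06", "R55", "R69", "R73", "R99")),
               c("R00-R09", "R00-R09", "R50-R69", "R50-R69", "R70-R79",
                 "R95-R99"))
  expect_true(is.na(symptom_block("I10")))
  expect_true(is.na(symptom_block("sdcL03")))
})

test_that("profiles equal hand-computed fractions on a 3-cluster fixture", {
  part <- tibble::tibble(
    patient_id = c("a", "b", "c", "d", "e", "f"),
    cluster = c(1L, 1L, 2L, 2L, 3L, 3L))
  ev <- ev_tbl(
    patient_id = c("a", "b", "a", "c", "e", "e", "f"),
    code = c("R55", "R51", "I10", "R06", "R73", "R73", "R80"))
  prof <- symptom_profiles(part, ev)
  expect_equal(prof$`R50-R69`[prof$cluster == 1L], 1.0)  # a (R55) + b (R51)
  expect_equal(prof$`R00-R09`[prof$cluster == 2L], 0.5)  # only c
  expect_equal(prof$`R70-R79`[prof$cluster == 3L], 0.5)  # e (dedup) only
  expect_equal(prof$`R80-R82`[prof$cluster == 3L], 0.5)
  expect_true(all(as.matrix(prof[, -1L]) >= 0 & as.matrix(prof[, -1L]) <= 1))
})

test_that("a corpus without symptom codes yields all-zero profiles", {
  part <- tibble::tibble(patient_id = c("a", "b"), cluster = c(1L, 2L))
  ev <- ev_tbl(c("a", "b"), c("I10", "E66"))
  prof <- symptom_profiles(part, ev)
  expect_true(all(as.matrix(prof[, -1L]) == 0))
})

test_that("ward grouping recovers two well-separated triplets", {
  base_a <- c(rep(0.9, 4), rep(0.05, 9))
  base_b <- c(rep(0.05, 9), rep(0.9, 4))
  set.seed(51)
  mk <- function(base) pmin(pmax(base + runif(13, -0.02, 0.02), 0), 1)
  prof <- tibble::as_tibble(
    rbind(mk(base_a), mk(base_a), mk(base_a),
          mk(base_b), mk(base_b), mk(base_b)),
    .name_repair = "minimal")
  names(prof) <- ICD10_R_BLOCKS
  prof <- dplyr::bind_cols(tibble::tibble(cluster = 1:6), prof)
  grp <- ward_groups(prof, k = 2)
  g <- grp$groups$group
  expect_equal(length(unique(g[1:3])), 1L)
  expect_equal(length(unique(g[4:6])), 1L)
  expect_false(g[1] == g[4])
  # exhaustive oracle: the returned split minimises within-group variance
  # over all 2-partitions with non-empty parts
  m <- as.matrix(prof[, -1L])
  wgv <- function(assign) {
    sum(vapply(unique(assign), function(k) {
      rows <- m[assign == k, , drop = FALSE]
      sum(scale(rows, scale = FALSE)^2)
    }, numeric(1L)))
  }
  best <- Inf
  for (mask in 1:(2^6 - 2)) {
    assign <- as.integer(intToBits(mask))[1:6]
    best <- min(best, wgv(assign))
  }
  expect_equal(wgv(as.integer(g == g[1])), best, tolerance = 1e-9)
})

test_that("identical profiles merge first at height zero", {
  prof <- tibble::as_tibble(rbind(rep(0.2, 13), rep(0.2, 13),
                                  rep(0.8, 13)), .name_repair = "minimal")
  names(prof) <- ICD10_R_BLOCKS
  prof <- dplyr::bind_cols(tibble::tibble(cluster = 1:3), prof)
  grp <- ward_groups(prof, k = 2)
  expect_equal(grp$tree$height[1L], 0, tolerance = 1e-12)
  expect_equal(grp$groups$group[1L], grp$groups$group[2L])
})

test_that("merge heights are non-decreasing and k bounds are enforced", {
  prof <- symptom_profiles(
    tibble::tibble(patient_id = letters[1:8],
                   cluster = rep(1:4, each = 2L)),
    ev_tbl(letters[1:8],
           c("R00", "R11", "R21", "R31", "R42", "R51", "R73", "R80")))
  grp <- ward_groups(prof, k = 2)
  expect_true(all(diff(grp$tree$height) >= -1e-12))
  full <- ward_groups(prof, k = 4)
  expect_equal(sort(unique(full$groups$group)), 1:4)
  expect_error(ward_groups(prof, k = 5), "exceeds")
  expect_error(ward_groups(prof, k = 0), "integer")
})

test_that("grouping is invariant to cluster label permutation", {
  set.seed(53)
  prof <- tibble::as_tibble(matrix(runif(5 * 13), nrow = 5),
                            .name_repair = "minimal")
  names(prof) <- ICD10_R_BLOCKS
  prof <- dplyr::bind_cols(tibble::tibble(cluster = 1:5), prof)
  g1 <- ward_groups(prof, k = 2)$groups
  perm <- c(3L, 5L, 1L, 2L, 4L)
  prof2 <- prof[perm, ]
  prof2$cluster <- prof$cluster[perm]
  g2 <- ward_groups(prof2, k = 2)$groups
  j <- dplyr::inner_join(g1, g2, by = "cluster")
  tab <- table(j$group.x, j$group.y)
  expect_true(all(rowSums(tab > 0) == 1L))
})

test_that("the dendrogram exports as parseable Newick text", {
  prof <- tibble::as_tibble(rbind(rep(0.1, 13), rep(0.5, 13),
                                  rep(0.9, 13)), .name_repair = "minimal")
  names(prof) <- ICD10_R_BLOCKS
  prof <- dplyr::bind_cols(tibble::tibble(cluster = 1:3), prof)
  grp <- ward_groups(prof, k = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram(grp, path)
  txt <- readLines(path)
  expect_match(txt, "^\\(.*\\).*;$")
  tr <- ape::read.tree(path)
  expect_equal(sort(tr$tip.label), c("1", "2", "3"))
})
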