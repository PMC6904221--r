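# Patient similarity network and Markov clustering.
#
# Pairwise cosine similarities of BM25 vectors are thresholded (>= 0.5 by
# default) and rescaled linearly from [cutoff, 1] to [10, 100] before MCL.
# MCL alternates expansion (matrix squaring of the column-stochastic
# transition matrix) with inflation (entrywise power and renormalization)
# until the matrix stops changing, then reads clusters off the attractors.

#' Thresholded, rescaled cosine similarity network
#'
#' All patient pairs with cosine similarity at or above `cutoff` become
#' undirected edges; similarities are mapped affinely from
#' `[cutoff, 1]` to `[10, 100]` (`w = 10 + 180 (s - 0.5)` at the default
#' cutoff), which increases the variance seen by the clustering.
#'
#' @param vectors a [bm25_vectors()] triplet table or a patient-by-code
#'   matrix.
#' @param cutoff minimum cosine similarity retained.
#' @return an object of class `similarity_network`: list with `nodes`
#'   (patients with a non-empty vector) and `edges`
#'   (`from`, `to`, `cosine`, `weight`).
#' @export
cosine_network <- function(vectors, cutoff = 0.5) {
  m <- if (is.data.frame(vectors)) bm25_matrix(vectors) else vectors
  norms <- sqrt(Matrix::rowSums(m^2))
  nonzero <- norms > 0
  if (sum(nonzero) < 2L) {
    stop("need at least two patients with non-empty vectors", call. = FALSE)
  }
  m <- m[nonzero, , drop = FALSE]
  mn <- m / norms[nonzero]
  s <- as.matrix(Matrix::tcrossprod(mn))
  keep <- which(upper.tri(s) & s >= cutoff, arr.ind = TRUE)
  nodes <- rownames(m)
  cosine <- s[keep]
  edges <- tibble(
    from = nodes[keep[, 1L]],
    to = nodes[keep[, 2L]],
    cosine = pmin(cosine, 1),
    weight = 10 + 90 / (1 - cutoff) * (pmin(cosine, 1) - cutoff)
  )
  structure(list(nodes = nodes, edges = edges, cutoff = cutoff),
            class = "similarity_network")
}

#' Construct a similarity network from an edge list
#'
#' Useful for re-loading saved edge lists or building test networks. Edge
#' weights are recomputed from the cosine column when absent.
#'
#' @param nodes character vector of node (patient) ids.
#' @param edges tibble with `from`, `to`, `cosine` (and optionally
#'   `weight`); may be empty.
#' @param cutoff the cosine cutoff the edges are assumed to satisfy.
#' @return a `similarity_network`.
#' @export
similarity_network <- function(nodes, edges = NULL, cutoff = 0.5) {
  if (is.null(edges) || !nrow(edges)) {
    edges <- tibble(from = character(), to = character(),
                    cosine = numeric(), weight = numeric())
  }
  assert_cols(edges, c("from", "to", "cosine"), "edges")
  if (!all(c(edges$from, edges$to) %in% nodes)) {
    stop("edge endpoints must be listed in `nodes`", call. = FALSE)
  }
  if (any(edges$from == edges$to)) {
    stop("self-edges are not allowed", call. = FALSE)
  }
  if (!"weight" %in% names(edges)) {
    edges$weight <- 10 + 90 / (1 - cutoff) * (edges$cosine - cutoff)
  }
  structure(list(nodes = nodes, edges = as_tibble(edges), cutoff = cutoff),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d nodes, %d edges (cosine >= %.2f)\n",
              length(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

# sparse column-stochastic matrix from a similarity network; self-loops are
# added per node (max incident weight, or 1 for isolated nodes) so the
# random walk has a lazy component and the iteration converges.
network_matrix <- function(network, loop = c("max", "one", "none")) {
  loop <- match.arg(loop)
  nodes <- network$nodes
  n <- length(nodes)
  e <- network$edges
  i <- match(e$from, nodes)
  j <- match(e$to, nodes)
  a <- sparseMatrix(i = c(i, j), j = c(j, i), x = rep(e$weight, 2L),
                    dims = c(n, n), dimnames = list(nodes, nodes))
  if (loop != "none") {
    mx <- apply_max_col(a)
    d <- if (loop == "max") ifelse(mx > 0, mx, 1) else rep(1, n)
    a <- a + Diagonal(n, d)
  }
  a
}

apply_max_col <- function(a) {
  res <- numeric(ncol(a))
  cs <- Matrix::colSums(a)
  nz <- cs > 0
  if (any(nz)) {
    aa <- as(a, "CsparseMatrix")
    p <- aa@p
    for (c in which(nz)) {
      res[c] <- max(aa@x[(p[c] + 1L):p[c + 1L]])
    }
  }
  res
}

col_normalize <- function(m) {
  cs <- Matrix::colSums(m)
  cs[cs == 0] <- 1
  m %*% Diagonal(ncol(m), 1 / cs)
}

#' Markov clustering of a patient similarity network
#'
#' Alternates expansion (squaring of the column-stochastic matrix) and
#' inflation (entrywise power `inflation` followed by column
#' renormalization) until the matrix change drops below `tol`. Clusters are
#' read from the attractors (nodes with positive diagonal mass); attractors
#' that share attracted nodes are merged, and each node joins the cluster
#' of its highest-mass attractor (ties: lowest label), so the extraction is
#' deterministic.
#'
#' @param network a [cosine_network()] result.
#' @param inflation inflation parameter; lower values give coarser
#'   clusters. Default 1.2.
#' @param max_iter iteration cap; exceeding it raises a convergence error
#'   with diagnostics.
#' @param tol convergence tolerance on the max absolute matrix change.
#' @param prune entries below this are dropped after each inflation to keep
#'   the matrix sparse.
#' @param loop self-loop scheme before normalization.
#' @return an object of class `mcl_partition`: list with `assignments`
#'   (tibble `patient_id`, `cluster`; labels ordered by decreasing cluster
#'   size), `n_iter`, `inflation`.
#' @export
mcl_partition <- function(network, inflation = 1.2, max_iter = 200L,
                          tol = 1e-8, prune = 1e-10,
                          loop = c("max", "one", "none")) {
  stopifnot(inherits(network, "similarity_network"))
  if (!length(network$nodes)) stop("network is empty", call. = FALSE)
  a <- network_matrix(network, loop)
  m <- col_normalize(a)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    m_new <- m %*% m                      # expansion
    m_new@x <- m_new@x^inflation          # inflation
    m_new <- drop0(m_new, tol = prune)
    m_new <- col_normalize(m_new)
    delta <- max(abs(m_new - m))
    m <- m_new
    if (delta < tol) break
    if (iter >= max_iter) {
      stop(sprintf(
        "MCL did not converge in %d iterations (last change %.3e, tol %.1e)",
        max_iter, delta, tol), call. = FALSE)
    }
  }
  labels <- extract_clusters(m, network$nodes)
  new_partition(labels, meta = list(n_iter = iter, inflation = inflation))
}

# attractor-based cluster extraction from a converged MCL matrix
extract_clusters <- function(m, nodes, attr_tol = 1e-6) {
  m <- as(m, "CsparseMatrix")
  n <- length(nodes)
  attractors <- which(Matrix::diag(m) >= attr_tol)
  labels <- rep(NA_integer_, n)
  if (length(attractors)) {
    sub <- m[attractors, , drop = FALSE]
    sub@x[sub@x < attr_tol] <- 0
    sub <- drop0(sub)
    # merge attractors that attract a common node (or each other)
    sub_b <- sub
    sub_b@x[] <- 1
    ov <- as(as(Matrix::tcrossprod(sub_b), "generalMatrix"),
             "TsparseMatrix")
    g <- igraph::make_empty_graph(n = nrow(sub), directed = FALSE)
    g <- igraph::add_edges(g, rbind(ov@i + 1L, ov@j + 1L))
    comp <- igraph::components(g)$membership
    # each node joins the merged cluster of its highest-mass attractor
    tri <- as(sub, "TsparseMatrix")
    sm <- data.frame(i = tri@i + 1L, j = tri@j + 1L, x = tri@x)
    if (nrow(sm)) {
      ord <- order(sm$j, -sm$x, comp[sm$i])
      sm <- sm[ord, ]
      best <- sm[!duplicated(sm$j), ]
      labels[best$j] <- comp[best$i]
    }
  }
  # unattracted nodes become singletons
  free <- which(is.na(labels))
  if (length(free)) {
    labels[free] <- max(labels, 0L, na.rm = TRUE) + seq_along(free)
  }
  setNames(labels, nodes)
}

# canonical partition object: labels relabelled 1..K by decreasing size
# (ties broken by first node appearance)
new_partition <- function(labels, meta = list()) {
  stopifnot(!is.null(names(labels)))
  sizes <- table(labels)
  first_seen <- tapply(seq_along(labels), labels, min)
  ord <- order(-as.integer(sizes), first_seen[names(sizes)])
  relab <- setNames(seq_along(ord), names(sizes)[ord])
  assignments <- tibble(
    patient_id = names(labels),
    cluster = unname(relab[as.character(labels)])
  )
  structure(c(list(assignments = assignments), meta),
            class = "mcl_partition")
}

#' Construct a partition from a label vector
#'
#' @param labels named vector (names are patient ids) of cluster labels.
#' @return an `mcl_partition`.
#' @export
as_partition <- function(labels) {
  if (inherits(labels, "mcl_partition")) return(labels)
  new_partition(labels)
}

#' @export
print.mcl_partition <- function(x, ...) {
  sz <- partition_sizes(x)
  cat(sprintf(
    "<mcl_partition> %d nodes in %d clusters (max %d, median %.0f)\n",
    nrow(x$assignments), length(sz), max(sz), median(sz)))
  invisible(x)
}

#' Cluster sizes of a partition
#' @param partition an `mcl_partition`.
#' @return named integer vector of cluster sizes.
#' @export
partition_sizes <- function(partition) {
  stopifnot(inherits(partition, "mcl_partition"))
  tab <- table(partition$assignments$cluster)
  setNames(as.integer(tab), names(tab))
}

#' Size-filtered views of a partition
#'
#' The retained view drops clusters of ten or fewer patients
#' (`min_size = 11`); the analysis view keeps clusters with at least 50
#' patients (`min_size = 50`).
#'
#' @param partition an `mcl_partition`.
#' @param min_size smallest cluster size kept.
#' @return assignments tibble restricted to qualifying clusters.
#' @export
partition_view <- function(partition, min_size = 11L) {
  sz <- partition_sizes(partition)
  keep <- as.integer(names(sz)[sz >= min_size])
  filter(partition$assignments, cluster %in% keep)
}

#' Named label vector of a partition
#' @param partition an `mcl_partition` or assignments tibble.
#' @return named integer vector.
#' @export
partition_labels <- function(partition) {
  if (inherits(partition, "mcl_partition")) {
    a <- partition$assignments
  } else if (is.data.frame(partition)) {
    a <- assert_cols(partition, c("patient_id", "cluster"), "partition")
  } else {
    if (is.null(names(partition))) {
      stop("label vectors must be named by patient id", call. = FALSE)
    }
    return(partition)
  }
  setNames(a$cluster, a$patient_id)
}
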