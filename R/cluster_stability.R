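# Robustness of the clustering under network perturbation, scored by the
# Variation of Information (VI) against a reference partition.
#
# Two perturbation modes: "dilute" deletes each edge independently with
# probability alpha; "shuffle" rewires a fraction alpha of edges by
# degree-preserving double-edge swaps, so the number of edges and every
# node's degree are unchanged.

#' Perturb a similarity network
#'
#' @param network a [cosine_network()] result.
#' @param mode `"dilute"` (independent edge deletion with probability
#'   `alpha`) or `"shuffle"` (degree-preserving double-edge swaps touching
#'   a fraction `alpha` of edges; edge weights travel with the rewired
#'   edges).
#' @param alpha perturbation strength in `[0, 1]`; `alpha = 0` returns the
#'   network unchanged.
#' @param seed optional integer; when given, the perturbation is drawn
#'   under this seed without disturbing the session RNG.
#' @return a perturbed `similarity_network` over the same node set.
#' @export
perturb_network <- function(network, mode = c("dilute", "shuffle"),
                            alpha, seed = NULL) {
  stopifnot(inherits(network, "similarity_network"))
  mode <- match.arg(mode)
  assert_prob(alpha, "alpha")
  run <- function() {
    e <- network$edges
    if (alpha == 0 || !nrow(e)) return(network)
    if (mode == "dilute") {
      keep <- runif(nrow(e)) >= alpha
      out <- network
      out$edges <- e[keep, ]
      return(out)
    }
    out <- network
    out$edges <- double_edge_swap(e, n_swaps = round(alpha * nrow(e)))
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Degree-preserving rewiring: pick two edges (a-b, c-d) on four distinct
# nodes and swap to (a-d, c-b) unless either new edge already exists.
# Each successful swap rewires two edges.
double_edge_swap <- function(edges, n_swaps, max_attempts = 50L * n_swaps) {
  m <- nrow(edges)
  if (m < 2L || n_swaps < 1L) return(edges)
  from <- edges$from
  to <- edges$to
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  existing <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key(from, to)) assign(k, TRUE, envir = existing)
  done <- 0L
  attempts <- 0L
  while (done < n_swaps && attempts < max_attempts) {
    attempts <- attempts + 1L
    idx <- sample.int(m, 2L)
    a <- from[idx[1L]]; b <- to[idx[1L]]
    c_ <- from[idx[2L]]; d <- to[idx[2L]]
    if (length(unique(c(a, b, c_, d))) != 4L) next
    new1 <- key(a, d); new2 <- key(c_, b)
    if (exists(new1, envir = existing) || exists(new2, envir = existing)) next
    rm(list = c(key(a, b), key(c_, d)), envir = existing)
    assign(new1, TRUE, envir = existing)
    assign(new2, TRUE, envir = existing)
    to[idx[1L]] <- d
    to[idx[2L]] <- b
    done <- done + 1L
  }
  out <- edges
  out$from <- from
  out$to <- to
  out
}

#' Variation of Information between two partitions
#'
#' `VI(P, Q) = H(P) + H(Q) - 2 I(P; Q)` with entropies of the cluster-size
#' proportions in natural log (nats). VI is a metric on partitions: zero
#' iff the partitions are identical, symmetric, and satisfies the triangle
#' inequality. Nodes present in only one partition are dropped; the score
#' is computed on the common node set.
#'
#' @param p,q partitions: `mcl_partition` objects, assignment tibbles or
#'   named label vectors.
#' @return VI in nats.
#' @export
variation_of_information <- function(p, q) {
  lp <- partition_labels(p)
  lq <- partition_labels(q)
  common <- intersect(names(lp), names(lq))
  if (!length(common)) {
    stop("partitions share no nodes", call. = FALSE)
  }
  tab <- table(lp[common], lq[common])
  joint <- tab / sum(tab)
  px <- rowSums(joint)
  py <- colSums(joint)
  ent <- function(v) -sum(v[v > 0] * log(v[v > 0]))
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  max(0, ent(px) + ent(py) - 2 * mi)
}

#' Stability curve of an MCL clustering under network perturbation
#'
#' For each perturbation strength `alpha` and replicate, the network is
#' perturbed, re-clustered with MCL, and scored by VI against the
#' reference partition. Reference lines give the VI obtained by randomly
#' reassigning fixed fractions of vertices (10% and 20% by default) to
#' different random clusters, averaged over `replicates` Monte-Carlo
#' draws.
#'
#' @param network the unperturbed `similarity_network`.
#' @param reference reference partition; computed by [mcl_partition()] on
#'   `network` when `NULL`.
#' @param alphas grid of perturbation strengths.
#' @param mode perturbation mode, see [perturb_network()].
#' @param replicates perturbed replicates per alpha.
#' @param inflation MCL inflation used for every re-clustering.
#' @param reassign_fractions vertex fractions for the reference lines.
#' @param seed integer seed controlling all perturbation randomness.
#' @return an object of class `stability_curve`: tibble
#'   (`mode`, `alpha`, `replicate`, `vi`) with the reference lines in
#'   `attr(, "reference_lines")` and the reference partition in
#'   `attr(, "reference")`.
#' @export
stability_curve <- function(network, reference = NULL,
                            alphas = seq(0, 0.5, by = 0.1),
                            mode = c("dilute", "shuffle"),
                            replicates = 5L, inflation = 1.2,
                            reassign_fractions = c(0.1, 0.2),
                            seed = 1L) {
  mode <- match.arg(mode)
  replicates <- assert_count(replicates, "replicates")
  if (is.null(reference)) {
    reference <- mcl_partition(network, inflation = inflation)
  }
  grid <- expand.grid(alpha = alphas, replicate = seq_len(replicates))
  vi <- numeric(nrow(grid))
  errors <- character(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pert <- perturb_network(network, mode, grid$alpha[g],
                            seed = seed + 7919L * g)
    part <- tryCatch(mcl_partition(pert, inflation = inflation),
                     error = function(e) e)
    if (inherits(part, "error")) {
      vi[g] <- NA_real_
      errors[g] <- conditionMessage(part)
    } else {
      vi[g] <- variation_of_information(reference, part)
    }
  }
  ref_lines <- random_reassignment_vi(reference, reassign_fractions,
                                      replicates, seed = seed + 104729L)
  out <- tibble(mode = mode, alpha = grid$alpha,
                replicate = grid$replicate, vi = vi)
  structure(out, class = c("stability_curve", class(out)),
            reference_lines = ref_lines, reference = reference,
            errors = errors[nzchar(errors)])
}

# Mean VI from randomly reassigning a fraction of vertices to different
# random clusters; serves as the orientation lines on stability curves.
random_reassignment_vi <- function(reference, fractions, replicates,
                                   seed = 1L) {
  labels <- partition_labels(reference)
  ks <- sort(unique(labels))
  withr::with_seed(seed, {
    rows <- lapply(fractions, function(f) {
      vis <- vapply(seq_len(replicates), function(r) {
        new_labels <- labels
        n_move <- round(f * length(labels))
        move <- sample(seq_along(labels), n_move)
        for (i in move) {
          others <- if (length(ks) > 1L) setdiff(ks, labels[i]) else ks
          new_labels[i] <- if (length(others) == 1L) others else
            sample(others, 1L)
        }
        variation_of_information(labels, new_labels)
      }, numeric(1L))
      tibble(fraction = f, vi_mean = mean(vis), vi_sd = sd(vis))
    })
    bind_rows(rows)
  })
}
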