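# Shared fixtures and independent oracles. Expensive fixtures are cached
# per test run so several files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# the study-condition cohort: 600 patients, 6 planted profiles, seed 1
cohort600 <- function() {
  cached_fixture("cohort600", generate_cohort(cohort_config(seed = 1)))
}

# combined assigned + mined events for the study-condition cohort
events600 <- function() {
  cached_fixture("events600", {
    co <- cohort600()
    tg <- tag_corpus(co$notes, co$dictionaries)
    dplyr::bind_rows(co$events, tg$events)
  })
}

# a smaller, well-separated cohort for stability analyses
cohort300 <- function() {
  cached_fixture("cohort300",
                 generate_cohort(cohort_config(n_patients = 300,
                                               k_clusters = 6, seed = 3)))
}

network300 <- function() {
  cached_fixture("network300", {
    co <- cohort300()
    tg <- tag_corpus(co$notes, co$dictionaries)
    ev <- dplyr::bind_rows(co$events, tg$events)
    cosine_network(bm25_vectors(build_code_lists(ev)))
  })
}

partition300 <- function() {
  cached_fixture("partition300", mcl_partition(network300()))
}

# --- independent oracles -------------------------------------------------

# naive two-loop BM25: plain R loops, no shared code with the package path
naive_bm25 <- function(events, b = 0.75, k1 = 1.2,
                       exclude = c("E10", "E109", "E11", "E119")) {
  pats <- sort(unique(events$patient_id))
  ev <- events[!(events$code %in% exclude), , drop = FALSE]
  n_total <- length(pats)
  p_len <- numeric(n_total)
  names(p_len) <- pats
  for (p in pats) p_len[p] <- sum(ev$patient_id == p)
  p_ave <- mean(p_len)
  codes <- sort(unique(ev$code))
  n_c <- numeric(length(codes))
  names(n_c) <- codes
  for (cd in codes) n_c[cd] <- length(unique(ev$patient_id[ev$code == cd]))
  rows <- list()
  for (p in pats) {
    my <- ev[ev$patient_id == p, , drop = FALSE]
    if (!nrow(my)) next
    for (cd in unique(my$code)) {
      f <- sum(my$code == cd)
      idf_val <- log((n_total - n_c[cd] + 0.5) / (n_c[cd] + 0.5))
      w <- idf_val * f * (k1 + 1) /
        (f + k1 * (1 - b + b * p_len[p] / p_ave))
      rows[[length(rows) + 1L]] <-
        data.frame(patient_id = p, code = cd, weight = w)
    }
  }
  do.call(rbind, rows)
}

# brute-force VI from first principles (label-pair enumeration)
oracle_vi <- function(p, q) {
  stopifnot(length(p) == length(q))
  n <- length(p)
  h <- function(labels) {
    tot <- 0
    for (a in unique(labels)) {
      pr <- sum(labels == a) / n
      tot <- tot - pr * log(pr)
    }
    tot
  }
  mi <- 0
  for (a in unique(p)) {
    for (b in unique(q)) {
      pab <- sum(p == a & q == b) / n
      if (pab > 0) {
        mi <- mi + pab * log(pab / ((sum(p == a) / n) * (sum(q == b) / n)))
      }
    }
  }
  h(p) + h(q) - 2 * mi
}

# exhaustive two-sided Fisher p for a 2x2 table via hypergeometric
# enumeration over all tables with the observed margins
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) dhyper(x, m, n, k), numeric(1L))
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive upper-tail binomial p by direct summation
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(x) choose(n, x) * p^x * (1 - p)^(n - x),
             numeric(1L)))
}

# random small partitions over a shared node set
random_partition <- function(n, k) {
  labs <- sample(seq_len(k), n, replace = TRUE)
  stats::setNames(labs, paste0("n", seq_len(n)))
}

# build a similarity network of disconnected cliques
clique_network <- function(sizes, cosine = 0.9) {
  nodes <- character()
  edges <- list()
  offset <- 0L
  for (sz in sizes) {
    ids <- paste0("p", offset + seq_len(sz))
    nodes <- c(nodes, ids)
    if (sz > 1L) {
      cmb <- utils::combn(ids, 2L)
      edges[[length(edges) + 1L]] <-
        tibble::tibble(from = cmb[1L, ], to = cmb[2L, ], cosine = cosine)
    }
    offset <- offset + sz
  }
  similarity_network(nodes, dplyr::bind_rows(edges))
}

digest_file <- function(path) unname(tools::md5sum(path))

# hand-built events table helper
ev_tbl <- function(patient_id, code,
                   date = as.Date("2005-06-15"), source = "assigned") {
  tibble::tibble(patient_id = patient_id, code = code,
                 date = date, source = source)
}
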