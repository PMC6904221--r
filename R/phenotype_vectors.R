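# Per-patient diagnosis-code vectors: combined assigned + text-mined code
# events, exclusion of uncomplicated primary diabetes codes, and the BM25
# weighting transform.

#' Diabetes codes excluded from phenotype vectors
#'
#' Uncomplicated primary diabetes codes are removed before weighting so the
#' stratification is driven by comorbidities, complications and symptoms
#' rather than by the broad primary type assignment.
#' @export
DIABETES_EXCLUDE_CODES <- c("E10", "E109", "E11", "E119")

#' Build per-patient code frequency lists and corpus statistics
#'
#' Frequencies `f(c, p)` are counted over the combined assigned and mined
#' event stream after removing `exclude_codes`. Patients whose every event
#' is excluded are retained with an empty vector and flagged. Corpus
#' statistics are computed on the filtered lists: `N` (total patients),
#' `n(c)` (patients carrying each code), `|p|` per patient (total event
#' count with multiplicity) and the corpus mean `|p_ave|`.
#'
#' @param events tibble with `patient_id`, `code` (a `date`/`source` column
#'   is allowed and ignored here). Mined and assigned duplicates of a code
#'   both count toward `f`.
#' @param exclude_codes codes removed before counting.
#' @return an object of class `code_lists`: list with `counts`
#'   (`patient_id`, `code`, `f`), `stats` (`N`, `n_c`, `p_len`, `p_ave`)
#'   and `empty_patients`.
#' @export
build_code_lists <- function(events,
                             exclude_codes = DIABETES_EXCLUDE_CODES) {
  assert_cols(events, c("patient_id", "code"), "events")
  if (!nrow(events)) stop("`events` must be non-empty", call. = FALSE)
  all_patients <- sort(unique(events$patient_id))
  kept <- filter(events, !code %in% exclude_codes)
  counts <- count(kept, patient_id, code, name = "f")
  p_len <- setNames(numeric(length(all_patients)), all_patients)
  f_sum <- counts |> group_by(patient_id) |> summarise(len = sum(f))
  p_len[f_sum$patient_id] <- f_sum$len
  n_c <- counts |> distinct(patient_id, code) |> count(code, name = "n")
  stats <- list(
    N = length(all_patients),
    n_c = setNames(n_c$n, n_c$code),
    p_len = p_len,
    p_ave = mean(p_len)
  )
  if (stats$p_ave <= 0) {
    stop("all events were excluded; corpus has no surviving codes",
         call. = FALSE)
  }
  structure(
    list(counts = counts, stats = stats,
         empty_patients = setdiff(all_patients, unique(counts$patient_id))),
    class = "code_lists"
  )
}

#' Inverse document frequency of diagnosis codes
#'
#' `IDF(c) = log((N - n(c) + 0.5) / (n(c) + 0.5))`, natural log. Codes held
#' by more than half the corpus get a negative weight (documented,
#' intentional: they carry anti-discriminative signal).
#'
#' @param code character vector of codes.
#' @param stats the `stats` element of a [build_code_lists()] result (or
#'   the `code_lists` object itself).
#' @return numeric IDF weights.
#' @export
idf <- function(code, stats) {
  if (inherits(stats, "code_lists")) stats <- stats$stats
  n <- stats$n_c[code]
  if (any(is.na(n))) {
    stop(sprintf("code(s) absent from corpus: %s",
                 paste(code[is.na(n)], collapse = ", ")), call. = FALSE)
  }
  unname(log((stats$N - n + 0.5) / (n + 0.5)))
}

#' BM25-weighted phenotype vectors
#'
#' Scores each code `c` in patient `p` as
#' `IDF(c) * f (k1 + 1) / (f + k1 (1 - b + b |p| / |p_ave|))`
#' with term-frequency saturation `k1` and document-length normalization
#' `b`. Defaults `b = 0.75`, `k1 = 1.2`.
#'
#' @param code_lists a [build_code_lists()] result.
#' @param b length-normalization weight in `[0, 1]`.
#' @param k1 saturation parameter, positive.
#' @return a tibble (`patient_id`, `code`, `weight`) of class
#'   `phenotype_vectors`, with the corpus stats and parameters attached as
#'   attributes. Patients flagged empty have no rows but are listed in
#'   `attr(, "empty_patients")`.
#' @export
bm25_vectors <- function(code_lists, b = 0.75, k1 = 1.2) {
  stopifnot(inherits(code_lists, "code_lists"))
  if (!is.numeric(b) || b < 0 || b > 1) {
    stop("`b` must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(k1) || k1 <= 0) stop("`k1` must be positive", call. = FALSE)
  counts <- code_lists$counts
  st <- code_lists$stats
  w_idf <- idf(counts$code, st)
  plen <- st$p_len[counts$patient_id]
  denom <- counts$f + k1 * (1 - b + b * plen / st$p_ave)
  out <- tibble(
    patient_id = counts$patient_id,
    code = counts$code,
    weight = unname(w_idf * counts$f * (k1 + 1) / denom)
  )
  structure(out, class = c("phenotype_vectors", class(out)),
            stats = st, b = b, k1 = k1,
            empty_patients = code_lists$empty_patients)
}

#' Sparse patient-by-code matrix of BM25 weights
#'
#' @param vectors a [bm25_vectors()] result (or any `patient_id`, `code`,
#'   `weight` triplet table).
#' @return a `dgCMatrix` with patients as rows and codes as columns.
#' @export
bm25_matrix <- function(vectors) {
  assert_cols(vectors, c("patient_id", "code", "weight"), "vectors")
  pats <- sort(unique(vectors$patient_id))
  codes <- sort(unique(vectors$code))
  sparseMatrix(
    i = match(vectors$patient_id, pats),
    j = match(vectors$code, codes),
    x = vectors$weight,
    dims = c(length(pats), length(codes)),
    dimnames = list(pats, codes)
  )
}
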