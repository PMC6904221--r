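# Internal validation and text helpers.

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_cols <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("`%s` is missing required column(s): %s", name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Tokenize note text into sentences and tokens with character spans
#'
#' Sentences are split on `.`, `;`, `!` and `?`; tokens are maximal runs of
#' letters, digits and apostrophes. Spans index into the original string.
#'
#' @param text a single character string.
#' @return a tibble with columns `sentence`, `token`, `start`, `end`.
#' @keywords internal
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(tibble(sentence = integer(), token = character(),
                  start = integer(), end = integer()))
  }
  sent_m <- gregexpr("[^.;!?]+", text)[[1]]
  if (sent_m[1] == -1L) {
    return(tibble(sentence = integer(), token = character(),
                  start = integer(), end = integer()))
  }
  out <- vector("list", length(sent_m))
  for (s in seq_along(sent_m)) {
    s_start <- sent_m[s]
    s_text <- substr(text, s_start, s_start + attr(sent_m, "match.length")[s] - 1L)
    tok_m <- gregexpr("[A-Za-z0-9']+", s_text)[[1]]
    if (tok_m[1] == -1L) next
    starts <- as.integer(tok_m) + s_start - 1L
    lens <- attr(tok_m, "match.length")
    out[[s]] <- tibble(
      sentence = s,
      token = substring(text, starts, starts + lens - 1L),
      start = starts,
      end = starts + lens - 1L
    )
  }
  bind_rows(out)
}

# Levenshtein distance between one token and a vector of candidates.
edit_distance <- function(token, candidates) {
  as.integer(adist(token, candidates)[1L, ])
}

# deterministic date helper: days since epoch -> Date
as_study_date <- function(days) as.Date(days, origin = "1970-01-01")
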