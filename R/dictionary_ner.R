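# Dictionary-based tagging of clinical notes: longest-match-first window
# matching over normalized tokens, fuzzy matching within one character edit,
# and suppression of negated or non-patient-subject mentions.

#' Default negation and non-patient-subject cue lists
#'
#' A mention is suppressed when one of these cues occurs within a fixed
#' token window before it in the same sentence: `negation` cues capture
#' language negation ("no sign of retinopathy"), `subject` cues capture
#' statements about someone other than the patient ("the patient's mother
#' had retinopathy").
#'
#' @return a list with character vectors `negation` and `subject`.
#' @export
default_cue_lists <- function() {
  list(
    negation = c("no", "not", "without", "denies", "never", "negative"),
    subject = c("mother", "father", "family", "brother", "sister",
                "parent", "grandmother", "grandfather")
  )
}

#' Validate a term dictionary
#'
#' @param df a data frame with columns `term`, `code`, `vocabulary`.
#' @return the validated tibble with normalized terms.
#' @export
as_dictionary <- function(df) {
  assert_cols(df, c("term", "code", "vocabulary"), "dictionary")
  df <- as_tibble(df)
  df$term <- normalize_token(df$term)
  if (any(!nzchar(df$term))) {
    stop("dictionary contains terms that are empty after normalization",
         call. = FALSE)
  }
  distinct(df, term, code, vocabulary)
}

#' Read a dictionary TSV (`term<TAB>code<TAB>vocabulary`)
#' @param path file path.
#' @return a validated dictionary tibble.
#' @export
read_dictionary <- function(path) {
  as_dictionary(readr::read_tsv(path, col_types = "ccc", progress = FALSE))
}

#' Normalize raw tokens
#'
#' Lowercases, strips punctuation (keeping internal alphanumerics), and maps
#' through an optional lemma table (e.g. `c(ulcers = "ulcer")`). Tokens
#' absent from the table are returned unchanged; multi-token strings are
#' normalized token-wise.
#'
#' @param raw character vector of raw tokens (or space-separated terms).
#' @param lemma_table named character vector mapping token to lemma.
#' @return normalized character vector.
#' @export
normalize_token <- function(raw, lemma_table = NULL) {
  out <- vapply(strsplit(tolower(raw), " ", fixed = TRUE), function(toks) {
    toks <- gsub("[^a-z0-9]", "", toks)
    if (!is.null(lemma_table)) {
      hit <- toks %in% names(lemma_table)
      toks[hit] <- unname(lemma_table[toks[hit]])
    }
    paste(toks[nzchar(toks)], collapse = " ")
  }, "")
  out
}

#' Fuzzy-match one normalized token against single-token dictionary entries
#'
#' Exact matches are returned preferentially with `fuzzy = FALSE`.
#' Otherwise entries within Levenshtein distance `max_edits` (substitution,
#' insertion or deletion) are returned flagged `fuzzy = TRUE`. Tokens of
#' length three or less never fuzzy-match, guarding against noise in short
#' codes and abbreviations.
#'
#' @param token a single normalized token.
#' @param dictionary a dictionary tibble (only its single-token entries are
#'   considered).
#' @param max_edits 0 or 1.
#' @return matching dictionary rows with an added `fuzzy` column.
#' @export
fuzzy_match <- function(token, dictionary, max_edits = 1L) {
  stopifnot(max_edits %in% c(0L, 1L))
  dic <- dictionary[!grepl(" ", dictionary$term, fixed = TRUE), ]
  exact <- dic[dic$term == token, ]
  if (nrow(exact)) return(mutate(exact, fuzzy = FALSE))
  if (max_edits == 0L || nchar(token) <= 3L) {
    return(mutate(dic[0, ], fuzzy = logical()))
  }
  d <- edit_distance(token, dic$term)
  mutate(dic[d <= max_edits & nchar(dic$term) > 3L, ], fuzzy = TRUE)
}

#' Detect negation for a mention inside one sentence
#'
#' @param sentence_tokens normalized tokens of the sentence.
#' @param position index of the mention's first token in the sentence.
#' @param cue_lists see [default_cue_lists()].
#' @param window number of tokens before the mention that are scanned.
#' @return `TRUE` when a negation or subject cue precedes the mention.
#' @export
detect_negation <- function(sentence_tokens, position,
                            cue_lists = default_cue_lists(), window = 5L) {
  if (position <= 1L) return(FALSE)
  lo <- max(1L, position - window)
  pre <- sentence_tokens[lo:(position - 1L)]
  any(pre %in% c(cue_lists$negation, cue_lists$subject))
}

# Precompiled matching structures for a combined dictionary.
compile_dictionary <- function(dictionaries, lemma_table = NULL) {
  dic <- as_dictionary(dictionaries)
  dic$term <- normalize_token(dic$term, lemma_table)
  dic <- distinct(dic, term, code, vocabulary)
  toks <- strsplit(dic$term, " ", fixed = TRUE)
  dic$n_tokens <- lengths(toks)
  single <- which(dic$n_tokens == 1L)
  list(
    entries = dic,
    token_sets = toks,
    lengths = sort(unique(dic$n_tokens), decreasing = TRUE),
    multi_idx = which(dic$n_tokens > 1L),
    single_idx = single,
    single_terms = dic$term[single],
    single_nchar = nchar(dic$term[single])
  )
}

# Match attempt at token position i of one sentence. Returns NULL or a list
# with one entry row index, token span length and fuzzy flag. Exact matches
# win over fuzzy; longer terms win over shorter; at most one token of a
# term may be fuzzy, and only when both the observed and dictionary token
# have more than three characters.
match_at <- function(toks, i, comp, max_edits, blocked) {
  n <- length(toks)
  for (L in comp$lengths) {
    if (i + L - 1L > n) next
    window <- paste(toks[i:(i + L - 1L)], collapse = " ")
    ci <- which(comp$entries$n_tokens == L & comp$entries$term == window)
    if (length(ci)) return(list(rows = ci[1L], span = L, fuzzy = FALSE))
  }
  if (max_edits == 0L) return(NULL)
  for (ci in comp$multi_idx) {  # multi-token fuzzy, longest terms are few
    tt <- comp$token_sets[[ci]]
    L <- length(tt)
    if (i + L - 1L > n) next
    window <- toks[i:(i + L - 1L)]
    bad <- which(tt != window)
    if (length(bad) != 1L) next
    b <- bad[1L]
    if (nchar(window[b]) <= 3L || nchar(tt[b]) <= 3L) next
    if (edit_distance(window[b], tt[b]) > max_edits) next
    key <- paste(paste(window, collapse = " "),
                 comp$entries$code[ci], sep = "\r")
    if (key %in% blocked) next
    return(list(rows = ci, span = L, fuzzy = TRUE))
  }
  tok <- toks[i]
  if (nchar(tok) <= 3L) return(NULL)
  ok <- comp$single_nchar > 3L
  if (!any(ok)) return(NULL)
  d <- edit_distance(tok, comp$single_terms)
  hit <- which(ok & d <= max_edits)
  for (h in hit) {
    ci <- comp$single_idx[h]
    key <- paste(tok, comp$entries$code[ci], sep = "\r")
    if (key %in% blocked) next
    return(list(rows = ci, span = 1L, fuzzy = TRUE))
  }
  NULL
}

#' Tag a corpus of clinical notes with dictionary terms
#'
#' Runs dictionary NER over every note: tokens are normalized, multi-token
#' terms are matched longest-first over token windows, unmatched tokens may
#' fuzzy-match within one edit, and mentions preceded by a negation or
#' subject cue in the same sentence are flagged negated. Duplicate matches
#' of the same code by different vocabularies at one locus are collapsed to
#' a single mention. Non-negated mentions are emitted as dated, text-mined
#' code events.
#'
#' @param notes tibble with `patient_id`, `date`, `text` (and optionally
#'   `note_id`).
#' @param dictionaries one dictionary tibble or a list of them; combined
#'   before matching.
#' @param lemma_table optional named character vector (token -> lemma).
#' @param cue_lists see [default_cue_lists()].
#' @param max_edits fuzzy matching budget, 0 or 1.
#' @param negation_window tokens scanned before a mention for cues.
#' @param blocklist optional tibble with columns `variant`, `code`: rejected
#'   fuzzy (variant, code) pairs that must never match.
#' @return a list with `mentions` (one row per surviving mention, with
#'   `negated` and `fuzzy` flags and character spans) and `events`
#'   (non-negated mentions as rows `patient_id`, `code`, `date`,
#'   `source = "mined"`).
#' @export
tag_corpus <- function(notes, dictionaries, lemma_table = NULL,
                       cue_lists = default_cue_lists(), max_edits = 1L,
                       negation_window = 5L, blocklist = NULL) {
  assert_cols(notes, c("patient_id", "date", "text"), "notes")
  if (is.data.frame(dictionaries)) dictionaries <- list(dictionaries)
  dic_all <- bind_rows(lapply(dictionaries, as_dictionary))
  if (!nrow(dic_all)) stop("dictionaries must be non-empty", call. = FALSE)
  comp <- compile_dictionary(dic_all, lemma_table)
  blocked <- character()
  if (!is.null(blocklist) && nrow(blocklist)) {
    assert_cols(blocklist, c("variant", "code"), "blocklist")
    blocked <- paste(normalize_token(blocklist$variant, lemma_table),
                     blocklist$code, sep = "\r")
  }
  if (!"note_id" %in% names(notes)) {
    notes$note_id <- sprintf("N%06d", seq_len(nrow(notes)))
  }

  out <- vector("list", nrow(notes))
  for (r in seq_len(nrow(notes))) {
    tk <- tokenize_text(notes$text[r])
    if (!nrow(tk)) next
    tk$norm <- normalize_token(tk$token, lemma_table)
    res <- list()
    for (s in unique(tk$sentence)) {
      st <- tk[tk$sentence == s, ]
      toks <- st$norm
      i <- 1L
      while (i <= length(toks)) {
        m <- match_at(toks, i, comp, max_edits, blocked)
        if (is.null(m)) {
          i <- i + 1L
          next
        }
        span_end <- i + m$span - 1L
        entry <- comp$entries[m$rows, ]
        # same surface may carry the same code in several vocabularies
        dup <- comp$entries$term == entry$term[1L] &
          comp$entries$n_tokens == m$span
        hits <- distinct(comp$entries[dup, ], code, .keep_all = TRUE)
        if (m$fuzzy) hits <- entry  # fuzzy resolution is entry-specific
        neg <- detect_negation(toks, i, cue_lists, negation_window)
        res[[length(res) + 1L]] <- tibble(
          patient_id = notes$patient_id[r],
          note_id = notes$note_id[r],
          date = notes$date[r],
          code = hits$code, vocabulary = hits$vocabulary,
          term = hits$term,
          start = st$start[i], end = st$end[span_end],
          surface = paste(st$token[i:span_end], collapse = " "),
          negated = neg, fuzzy = m$fuzzy
        )
        i <- span_end + 1L
      }
    }
    if (length(res)) out[[r]] <- bind_rows(res)
  }
  mentions <- bind_rows(out)
  if (!nrow(mentions)) {
    mentions <- tibble(patient_id = character(), note_id = character(),
                       date = as.Date(character()), code = character(),
                       vocabulary = character(), term = character(),
                       start = integer(), end = integer(),
                       surface = character(), negated = logical(),
                       fuzzy = logical())
  }
  events <- mentions |>
    filter(!negated) |>
    transmute(patient_id, code, date, source = "mined")
  list(mentions = mentions, events = events)
}
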