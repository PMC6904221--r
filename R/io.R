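# Readers and writers for the pipeline's canonical file formats: TSV for
# tabular layers, JSON lines for notes, JSON for manifests.

#' Write clinical notes as JSON lines
#'
#' One JSON object per line with fields `note_id`, `patient_id`, `date`,
#' `text`.
#'
#' @param notes notes tibble.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_notes <- function(notes, path) {
  assert_cols(notes, c("patient_id", "date", "text"), "notes")
  notes <- mutate(notes, date = as.character(date))
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(as.data.frame(notes), con, verbose = FALSE)
  invisible(path)
}

#' Read clinical notes from JSON lines
#' @param path notes file (`{patient_id, date, text}` per line).
#' @return notes tibble with `date` parsed as `Date`.
#' @export
read_notes <- function(path) {
  notes <- as_tibble(jsonlite::stream_in(file(path), verbose = FALSE))
  assert_cols(notes, c("patient_id", "date", "text"), "notes")
  mutate(notes, date = as.Date(date))
}

#' Read a diagnosis event TSV (`patient_id`, `code`, `date`, `source`)
#' @param path file path.
#' @return events tibble.
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(ev, c("patient_id", "code", "date"), "events")
  mutate(ev, date = as.Date(date))
}

#' Read a patient table TSV
#' @param path file path.
#' @return patients tibble with dates parsed.
#' @export
read_patients <- function(path) {
  p <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(p, "patient_id", "patients")
  for (col in intersect(c("birth_date", "onset_date"), names(p))) {
    p[[col]] <- as.Date(p[[col]])
  }
  p
}

#' Read a long-format lab TSV (`patient_id`, `test_id`, `date`, `value`)
#' @param path file path.
#' @return labs tibble.
#' @export
read_labs <- function(path) {
  l <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(l, c("patient_id", "test_id", "date", "value"), "labs")
  mutate(l, date = as.Date(date))
}

#' Read a prescription TSV (`patient_id`, `atc`, `date`)
#' @param path file path.
#' @return prescriptions tibble.
#' @export
read_prescriptions <- function(path) {
  rx <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(rx, c("patient_id", "atc"), "prescriptions")
  if ("date" %in% names(rx)) rx$date <- as.Date(rx$date)
  rx
}
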