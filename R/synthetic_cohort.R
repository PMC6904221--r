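# Synthetic EHR cohort generator with planted ground truth.
#
# The generator emulates the statistical structure the downstream pipeline
# assumes: k phenotype clusters with disjoint comorbidity-code profiles,
# templated clinical notes embedding dictionary terms (with controllable
# negation and single-edit typo rates), HbA1c trajectories with optional
# level jumps, lab panels with group-level mean shifts, and prescription
# profiles with a cluster-specific drug class. Every planted feature is
# recorded in the returned ground truth so recovery can be scored exactly.

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients number of patients.
#' @param k_clusters number of planted phenotype clusters.
#' @param profile_codes_per_cluster codes in each cluster's comorbidity
#'   profile (two of which are symptom-chapter R codes when the profile has
#'   room for them).
#' @param background_code_rate probability that any non-profile code is
#'   assigned to a patient.
#' @param note_terms_per_patient mean number of dictionary-term mentions per
#'   patient (Poisson, minimum one).
#' @param negation_rate probability that a planted mention is wrapped in a
#'   negation template.
#' @param typo_rate probability that a planted mention carries exactly one
#'   character edit (substitution, insertion or deletion) on one token.
#' @param hba1c_points_per_patient HbA1c measurements per patient.
#' @param hba1c_changepoint_fraction fraction of patients whose HbA1c series
#'   has a planted level jump; these patients are also the planted
#'   glycemically dysregulated group (elevated baseline, dysregulation and
#'   hyperglycemia codes, shifted labs).
#' @param lab_effect_size standardized mean shift applied to the first four
#'   panel tests of planted-dysregulated patients.
#' @param seed integer seed; a fixed seed makes the whole cohort
#'   byte-identical across runs.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 600L,
                          k_clusters = 6L,
                          profile_codes_per_cluster = 8L,
                          background_code_rate = 0.05,
                          note_terms_per_patient = 6,
                          negation_rate = 0.1,
                          typo_rate = 0.05,
                          hba1c_points_per_patient = 12L,
                          hba1c_changepoint_fraction = 0.3,
                          lab_effect_size = 1.0,
                          seed = 1L) {
  n_patients <- assert_count(n_patients, "n_patients")
  k_clusters <- assert_count(k_clusters, "k_clusters")
  if (k_clusters > n_patients) {
    stop("`k_clusters` must not exceed `n_patients`", call. = FALSE)
  }
  profile_codes_per_cluster <-
    assert_count(profile_codes_per_cluster, "profile_codes_per_cluster")
  assert_prob(background_code_rate, "background_code_rate")
  if (!is.numeric(note_terms_per_patient) || note_terms_per_patient <= 0) {
    stop("`note_terms_per_patient` must be a positive mean", call. = FALSE)
  }
  assert_prob(negation_rate, "negation_rate")
  assert_prob(typo_rate, "typo_rate")
  hba1c_points_per_patient <-
    assert_count(hba1c_points_per_patient, "hba1c_points_per_patient", min = 0L)
  assert_prob(hba1c_changepoint_fraction, "hba1c_changepoint_fraction")
  if (!is.numeric(lab_effect_size) || length(lab_effect_size) != 1L) {
    stop("`lab_effect_size` must be a single number", call. = FALSE)
  }
  seed <- assert_count(seed, "seed", min = 0L)
  structure(
    list(n_patients = n_patients, k_clusters = k_clusters,
         profile_codes_per_cluster = profile_codes_per_cluster,
         background_code_rate = background_code_rate,
         note_terms_per_patient = note_terms_per_patient,
         negation_rate = negation_rate, typo_rate = typo_rate,
         hba1c_points_per_patient = hba1c_points_per_patient,
         hba1c_changepoint_fraction = hba1c_changepoint_fraction,
         lab_effect_size = lab_effect_size, seed = seed),
    class = "cohort_config"
  )
}

#' Built-in term dictionaries for the synthetic cohort
#'
#' Two dictionaries in the pipeline's canonical layout (`term`, `code`,
#' `vocabulary`): an ICD10-like level-3 diagnosis dictionary (comorbidity
#' and chapter-XVIII symptom terms, including two multi-token terms) and a
#' small custom clinic vocabulary (dysregulation, compliance, treatments).
#' The custom dictionary deliberately repeats `hyperglycemia -> R73` so the
#' duplicate-code collapse in [tag_corpus()] is exercised.
#'
#' @return a tibble with columns `term`, `code`, `vocabulary`.
#' @export
default_dictionaries <- function() {
  icd <- c(
    hypertension = "I10", angina = "I20", infarction = "I21",
    cardiomyopathy = "I42", fibrillation = "I48", atherosclerosis = "I70",
    embolism = "I74", thrombosis = "I82", stroke = "I64",
    obesity = "E66", dyslipidemia = "E78", hypothyroidism = "E03",
    thyrotoxicosis = "E05", gout = "M10", pancreatitis = "K86",
    gastritis = "K29", cirrhosis = "K74", hepatitis = "K75",
    colitis = "K51", cholelithiasis = "K80", diverticulosis = "K57",
    nephropathy = "N08", pyelonephritis = "N10", urolithiasis = "N20",
    cystitis = "N30", hyperplasia = "N40", glaucoma = "H40",
    cataract = "H25", retinopathy = "H36", neuropathy = "G63",
    epilepsy = "G40", migraine = "G43", insomnia = "G47",
    schizophrenia = "F20", depression = "F32", dementia = "F03",
    delirium = "F05", anemia = "D64", asthma = "J45", pneumonia = "J18",
    bronchitis = "J40", sinusitis = "J32", emphysema = "J43",
    psoriasis = "L40", dermatitis = "L30", cellulitis = "L03",
    arthritis = "M13", osteoporosis = "M81", dorsalgia = "M54",
    spondylosis = "M47", amputation = "Z89", transplantation = "Z94",
    "heart failure" = "I50", "foot ulcer" = "L97",
    # chapter XVIII symptom terms, one per code, spread over level-1 blocks
    tachycardia = "R00", dyspnea = "R06", nausea = "R11",
    exanthema = "R21", tremor = "R25", hematuria = "R31",
    polyuria = "R35", vertigo = "R42", fever = "R50", fatigue = "R53",
    syncope = "R55", edema = "R60", hyperglycemia = "R73",
    proteinuria = "R80"
  )
  custom <- c(
    dysregulation = "sdcL03", compliance = "sdcL01",
    hypoglycemia = "sdcL07", "insulin shock" = "sdcL05",
    "gastric bypass" = "sdcL10", hyperglycemia = "R73"
  )
  bind_rows(
    tibble(term = names(icd), code = unname(icd), vocabulary = "ICD10"),
    tibble(term = names(custom), code = unname(custom), vocabulary = "CUSTOM")
  )
}

# Sentence templates. Filler words are kept disjoint (beyond edit distance 1)
# from every dictionary token so tagging a template can only hit the
# embedded term.
.affirm_templates <- c(
  "patient has %s", "exam shows %s", "%s is present",
  "follow up for %s", "patient reports %s today"
)
.negation_templates <- c(
  "no sign of %s", "patient denies %s", "without %s",
  "the patient's mother had %s", "family history of %s"
)

# One random character edit on one token (length >= 4) of a term. The edit is
# re-drawn until the typo token is (a) not itself a dictionary token and
# (b) at edit distance >= 2 from every dictionary token other than the
# original, so fuzzy resolution is unambiguous. Returns NULL when no
# qualifying edit is found.
make_typo <- function(term, dict_tokens, max_tries = 20L) {
  toks <- strsplit(term, " ", fixed = TRUE)[[1]]
  eligible <- which(nchar(toks) >= 4L)
  if (!length(eligible)) return(NULL)
  letters_pool <- letters
  for (i in seq_len(max_tries)) {
    ti <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    tok <- toks[ti]
    type <- sample(c("substitution", "insertion", "deletion"), 1L)
    pos <- sample(nchar(tok), 1L)
    new_tok <- switch(type,
      substitution = {
        repl <- sample(setdiff(letters_pool, substr(tok, pos, pos)), 1L)
        paste0(substr(tok, 1L, pos - 1L), repl,
               substr(tok, pos + 1L, nchar(tok)))
      },
      insertion = paste0(substr(tok, 1L, pos), sample(letters_pool, 1L),
                         substr(tok, pos + 1L, nchar(tok))),
      deletion = paste0(substr(tok, 1L, pos - 1L),
                        substr(tok, pos + 1L, nchar(tok)))
    )
    if (nchar(new_tok) <= 3L) next
    d <- edit_distance(new_tok, dict_tokens)
    others <- dict_tokens != tok
    if (any(d == 0L)) next
    if (any(d[others] <= 1L)) next
    out <- toks
    out[ti] <- new_tok
    return(list(term = paste(out, collapse = " "), type = type))
  }
  NULL
}

#' Generate a fully labelled synthetic EHR cohort
#'
#' Produces the five canonical pipeline inputs (patient table, notes,
#' assigned diagnosis events, long-format labs, prescriptions) together with
#' the planted ground truth (cluster labels, note-mention inventory with
#' negation/typo flags, HbA1c change-point positions, dysregulated flags).
#'
#' Cluster profiles are disjoint code sets; each patient draws every profile
#' code of their cluster with probability 0.8 and every other code with
#' `background_code_rate`. Notes are templated sentences (three mentions per
#' note). HbA1c series are piecewise-constant-plus-noise; the planted
#' dysregulated fraction carries a +15 mmol/mol level jump, an elevated
#' baseline, dysregulation/hyperglycemia codes, and a `lab_effect_size`
#' shift on the first four panel tests.
#'
#' @param config a [cohort_config()].
#' @return an object of class `ehr_cohort`: a list with elements `patients`,
#'   `notes`, `events`, `labs`, `prescriptions`, `truth`, `dictionaries`,
#'   `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 60, k_clusters = 3,
#'                                         seed = 42))
#' table(cohort$truth$clusters$cluster)
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be created with cohort_config()", call. = FALSE)
  }
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  dict <- default_dictionaries()
  icd <- filter(dict, vocabulary == "ICD10")
  r_pool <- filter(icd, grepl("^R", code))
  como_pool <- filter(icd, !grepl("^R", code))
  dict_tokens <- unique(unlist(strsplit(dict$term, " ", fixed = TRUE)))

  n <- cfg$n_patients
  k <- cfg$k_clusters
  ids <- sprintf("P%04d", seq_len(n))

  # planted clusters: balanced, every label used at least once
  cluster <- sample(rep_len(seq_len(k), n))

  # disjoint profiles: up to 2 symptom (R) codes + comorbidity codes each
  n_r <- min(2L, max(0L, cfg$profile_codes_per_cluster - 2L),
             nrow(r_pool) %/% k)
  n_c <- cfg$profile_codes_per_cluster - n_r
  if (n_c * k > nrow(como_pool)) {
    stop("profile_codes_per_cluster too large for the built-in dictionary",
         call. = FALSE)
  }
  r_codes <- sample(r_pool$code, n_r * k)
  c_codes <- sample(como_pool$code, n_c * k)
  profiles <- tibble(
    cluster = rep(seq_len(k), each = cfg$profile_codes_per_cluster),
    code = as.vector(rbind(
      matrix(c_codes, nrow = n_c),
      if (n_r > 0) matrix(r_codes, nrow = n_r) else NULL
    ))
  )
  profile_by_cluster <- split(profiles$code, profiles$cluster)
  all_codes <- unique(icd$code)

  # patient table
  sex <- sample(c("F", "M"), n, replace = TRUE)
  birth_year <- sample(1930:1985, n, replace = TRUE)
  birth_date <- as.Date(sprintf("%d-%02d-%02d", birth_year,
                                sample(1:12, n, TRUE), sample(1:28, n, TRUE)))
  diabetes_type <- sample(c("T1D", "T2D"), n, replace = TRUE,
                          prob = c(0.35, 0.65))
  onset_date <- as.Date(sprintf("%d-%02d-%02d",
                                sample(1995:2008, n, TRUE),
                                sample(1:12, n, TRUE), sample(1:28, n, TRUE)))
  patients <- tibble(patient_id = ids, sex = sex, birth_date = birth_date,
                     diabetes_type = diabetes_type, onset_date = onset_date)

  dysregulated <- as.logical(
    rbinom(n, 1L, cfg$hba1c_changepoint_fraction))

  study_end <- as.Date("2012-12-31")
  rand_date <- function(from, m) {
    from <- as.integer(from)
    as_study_date(from + floor(runif(m) * (as.integer(study_end) - from)))
  }

  # assigned diagnosis events + per-patient present code set
  ev_list <- vector("list", n)
  present_codes <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- profile_by_cluster[[cluster[i]]]
    keep_prof <- prof[runif(length(prof)) < 0.8]
    bg_pool <- setdiff(all_codes, prof)
    keep_bg <- bg_pool[runif(length(bg_pool)) < cfg$background_code_rate]
    dm_code <- if (diabetes_type[i] == "T1D") "E10" else "E11"
    dm4 <- if (diabetes_type[i] == "T1D") "E109" else "E119"
    codes <- c(keep_prof, keep_bg, dm_code,
               if (runif(1) < 0.3) dm4,
               if (dysregulated[i] && runif(1) < 0.7) "R73")
    reps <- 1L + rpois(length(codes), 0.4)
    codes <- rep(codes, reps)
    ev_list[[i]] <- tibble(
      patient_id = ids[i], code = codes,
      date = rand_date(onset_date[i], length(codes)), source = "assigned")
    present_codes[[i]] <- unique(c(keep_prof, keep_bg))
  }
  events <- bind_rows(ev_list)

  # notes + mention inventory
  term_for_code <- split(dict$term[dict$vocabulary == "ICD10"],
                         dict$code[dict$vocabulary == "ICD10"])
  custom_terms <- filter(dict, vocabulary == "CUSTOM", code != "R73")
  note_list <- list()
  inv_list <- list()
  note_counter <- 0L
  for (i in seq_len(n)) {
    n_m <- max(1L, rpois(1L, cfg$note_terms_per_patient))
    cand <- present_codes[[i]]
    if (!length(cand)) cand <- sample(all_codes, 1L)
    codes_m <- sample(cand, n_m, replace = TRUE)
    terms_m <- vapply(codes_m, function(cd) sample(term_for_code[[cd]], 1L), "")
    extra <- NULL
    if (dysregulated[i] && runif(1) < 0.8) {
      extra <- tibble(code = "sdcL03", term = "dysregulation")
    } else if (runif(1) < 0.1) {
      j <- sample(nrow(custom_terms), 1L)
      extra <- tibble(code = custom_terms$code[j], term = custom_terms$term[j])
    }
    mt <- tibble(code = unname(codes_m), term = unname(terms_m))
    if (!is.null(extra)) mt <- bind_rows(mt, extra)
    m <- nrow(mt)
    mt$negated <- runif(m) < cfg$negation_rate
    mt$typo <- FALSE
    mt$typo_type <- NA_character_
    mt$surface <- mt$term
    do_typo <- runif(m) < cfg$typo_rate
    for (j in which(do_typo)) {
      tp <- make_typo(mt$term[j], dict_tokens)
      if (!is.null(tp)) {
        mt$typo[j] <- TRUE
        mt$typo_type[j] <- tp$type
        mt$surface[j] <- tp$term
      }
    }
    # pack mentions into notes of three sentences
    note_of <- ceiling(seq_len(m) / 3L)
    for (nn in unique(note_of)) {
      note_counter <- note_counter + 1L
      rows <- which(note_of == nn)
      sentences <- vapply(rows, function(j) {
        tmpl <- if (mt$negated[j]) {
          sample(.negation_templates, 1L)
        } else {
          sample(.affirm_templates, 1L)
        }
        sprintf(tmpl, mt$surface[j])
      }, "")
      nd <- rand_date(onset_date[i], 1L)
      note_id <- sprintf("N%06d", note_counter)
      note_list[[note_counter]] <- tibble(
        note_id = note_id, patient_id = ids[i], date = nd,
        text = paste0(paste(sentences, collapse = ". "), "."))
      inv_list[[note_counter]] <- mutate(mt[rows, ], note_id = note_id,
                                         patient_id = ids[i], date = nd)
    }
  }
  notes <- bind_rows(note_list)
  inventory <- select(bind_rows(inv_list),
                      patient_id, note_id, date, term, surface, code,
                      negated, typo, typo_type)

  # HbA1c series (test NPU27300) + panel labs
  hb_list <- vector("list", n)
  cp_list <- vector("list", n)
  if (cfg$hba1c_points_per_patient >= 1L) {
    for (i in seq_len(n)) {
      np <- cfg$hba1c_points_per_patient
      start <- as.integer(onset_date[i])
      days <- sort(start + sample.int(365L * 3L, np))
      base <- rnorm(1L, if (dysregulated[i]) 58 else 45, 3)
      vals <- base + rnorm(np, 0, 3)
      cp_idx <- NA_integer_
      if (dysregulated[i] && np >= 6L) {
        cp_idx <- sample(seq(floor(np / 3), ceiling(2 * np / 3)), 1L)
        vals[cp_idx:np] <- vals[cp_idx:np] + 15
      }
      hb_list[[i]] <- tibble(patient_id = ids[i], test_id = "NPU27300",
                             date = as_study_date(days),
                             value = round(vals, 1))
      cp_list[[i]] <- tibble(patient_id = ids[i], index = cp_idx,
                             date = if (is.na(cp_idx)) as.Date(NA) else
                               as_study_date(days[cp_idx]),
                             base_level = base)
    }
  }
  changepoints <- bind_rows(cp_list)

  panel_tests <- sprintf("LAB%02d", 1:8)
  lab_list <- vector("list", n)
  has_lab8 <- runif(n) < 0.5
  for (i in seq_len(n)) {
    tests <- panel_tests[c(rep(TRUE, 7L), has_lab8[i])]
    reps <- 3L
    shift <- ifelse(tests %in% panel_tests[1:4] & dysregulated[i],
                    cfg$lab_effect_size, 0)
    lab_list[[i]] <- tibble(
      patient_id = ids[i],
      test_id = rep(tests, each = reps),
      date = rand_date(onset_date[i], length(tests) * reps),
      value = round(rnorm(length(tests) * reps,
                          rep(shift, each = reps), 1), 3))
  }
  labs <- bind_rows(c(lab_list, hb_list))

  # prescriptions: insulins for most, one signature ATC class per cluster
  sig_classes <- rep_len(c("C07A", "C09A", "C10A", "N05A", "A02B", "M01A",
                           "C03A", "B01A"), k)
  rx_list <- vector("list", n)
  for (i in seq_len(n)) {
    atc <- character()
    if (runif(1) < 0.85) atc <- c(atc, "A10AB01")
    if (runif(1) < 0.7) atc <- c(atc, paste0(sig_classes[cluster[i]], "B02"))
    others <- setdiff(sig_classes[seq_len(k)], sig_classes[cluster[i]])
    bg <- others[runif(length(others)) < 0.08]
    if (length(bg)) atc <- c(atc, paste0(bg, "B02"))
    if (!length(atc)) next
    reps <- 1L + rpois(length(atc), 1)
    atc <- rep(atc, reps)
    rx_list[[i]] <- tibble(patient_id = ids[i], atc = atc,
                           date = rand_date(onset_date[i], length(atc)))
  }
  prescriptions <- bind_rows(rx_list)

  truth <- list(
    clusters = tibble(patient_id = ids, cluster = cluster),
    mentions = inventory,
    changepoints = changepoints,
    dysregulated = tibble(patient_id = ids, dysregulated = dysregulated),
    profiles = profiles,
    signature_atc = tibble(cluster = seq_len(k),
                           atc_class = sig_classes[seq_len(k)])
  )

  structure(
    list(patients = patients, notes = notes, events = events, labs = labs,
         prescriptions = prescriptions, truth = truth, dictionaries = dict,
         config = cfg),
    class = "ehr_cohort"
  )
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("<ehr_cohort>\n")
  cat(sprintf("  patients: %d in %d planted clusters\n",
              nrow(x$patients), x$config$k_clusters))
  cat(sprintf("  notes: %d | assigned events: %d | lab rows: %d | rx: %d\n",
              nrow(x$notes), nrow(x$events), nrow(x$labs),
              nrow(x$prescriptions)))
  cat(sprintf("  planted mentions: %d (%.0f%% negated, %.0f%% typo)\n",
              nrow(x$truth$mentions),
              100 * mean(x$truth$mentions$negated),
              100 * mean(x$truth$mentions$typo)))
  invisible(x)
}

#' Extract the HbA1c series from a long-format lab table
#'
#' @param labs lab table with `patient_id`, `test_id`, `date`, `value`.
#' @param test_id identifier of the HbA1c assay (NPU27300 by default).
#' @return tibble with `patient_id`, `date`, `value`.
#' @export
extract_hba1c <- function(labs, test_id = "NPU27300") {
  assert_cols(labs, c("patient_id", "test_id", "date", "value"), "labs")
  labs |>
    filter(.data$test_id == .env$test_id) |>
    select("patient_id", "date", "value")
}

#' Write the synthetic cohort to its canonical on-disk formats
#'
#' Patient table, diagnosis events, labs and prescriptions as TSV; notes as
#' JSON lines (`{patient_id, date, text}` per line); ground truth as JSON;
#' dictionaries as a single TSV.
#'
#' @param cohort an `ehr_cohort`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(cohort$patients, file.path(dir, "patients.tsv"))
  readr::write_tsv(cohort$events, file.path(dir, "events.tsv"))
  readr::write_tsv(cohort$labs, file.path(dir, "labs.tsv"))
  readr::write_tsv(cohort$prescriptions, file.path(dir, "prescriptions.tsv"))
  readr::write_tsv(cohort$dictionaries, file.path(dir, "dictionaries.tsv"))
  write_notes(cohort$notes, file.path(dir, "notes.jsonl"))
  truth <- cohort$truth
  truth$changepoints$date <- as.character(truth$changepoints$date)
  truth$mentions$date <- as.character(truth$mentions$date)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null", digits = NA)
  invisible(dir)
}
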