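# End-to-end orchestration: tag -> vectorize -> cluster -> stability /
# symptom groups / enrichment / comorbidity / dysregulation, driven by a
# single validated configuration with a reproducible run manifest.

default_run_params <- function() {
  list(
    ner = list(max_edits = 1L, negation_window = 5L),
    vectors = list(b = 0.75, k1 = 1.2,
                   exclude_codes = DIABETES_EXCLUDE_CODES),
    network = list(cutoff = 0.5),
    mcl = list(inflation = 1.2, min_cluster = 11L, analysis_min = 50L),
    stability = list(alphas = seq(0, 0.5, by = 0.1), mode = "dilute",
                     replicates = 5L),
    symptoms = list(k = 7L, method = "ward.D"),
    enrichment = list(min_support = 10L, alpha = 0.05, atc_level = 3L),
    comorbidity = list(alpha = 0.01, min_carriers = 10L,
                       max_unique_codes = 100L, smoothing = 1),
    dysregulation = list(min_criteria = 3L, hba1c_test_id = "NPU27300",
                         coverage = 0.75, alpha = 0.05)
  )
}

PIPELINE_STAGES <- c("tag", "vectorize", "cluster", "stability",
                     "symptom_groups", "enrichment", "comorbidity",
                     "dysregulation")

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML file holding one) with
#' elements `inputs` (paths: `notes`, `events`, `patients`, `labs`,
#' `prescriptions`, `dictionaries`, optionally `lemma_table`,
#' `blocklist`), `output_dir`, optional `stages`, `seed` and `params`
#' overriding [default_run_params()] per stage. Unknown keys are
#' rejected before any computation.
#'
#' @param config named list or path to a YAML file.
#' @return the resolved configuration with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop(sprintf("config file does not exist: %s", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  known <- c("inputs", "output_dir", "stages", "seed", "params", "cohort")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(config$output_dir)) {
    stop("config$output_dir is required", call. = FALSE)
  }
  config$seed <- config$seed %||% 1L
  config$stages <- config$stages %||% PIPELINE_STAGES
  bad_stage <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad_stage)) {
    stop(sprintf("unknown stage(s): %s", paste(bad_stage, collapse = ", ")),
         call. = FALSE)
  }
  defaults <- default_run_params()
  params <- config$params %||% list()
  unknown_p <- setdiff(names(params), names(defaults))
  if (length(unknown_p)) {
    stop(sprintf("unknown params key(s): %s",
                 paste(unknown_p, collapse = ", ")), call. = FALSE)
  }
  for (stage in names(defaults)) {
    given <- params[[stage]] %||% list()
    unknown_k <- setdiff(names(given), names(defaults[[stage]]))
    if (length(unknown_k)) {
      stop(sprintf("unknown params$%s key(s): %s", stage,
                   paste(unknown_k, collapse = ", ")), call. = FALSE)
    }
    defaults[[stage]][names(given)] <- given
  }
  config$params <- defaults
  if (is.null(config$cohort)) {
    ins <- config$inputs
    if (is.null(ins)) stop("config$inputs is required", call. = FALSE)
    required <- c("notes", "events", "patients", "labs", "prescriptions",
                  "dictionaries")
    missing <- setdiff(required, names(ins))
    if (length(missing)) {
      stop(sprintf("config$inputs missing: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    for (nm in setdiff(names(ins), "dictionaries")) {
      if (!file.exists(ins[[nm]])) {
        stop(sprintf("input file does not exist: %s (%s)", ins[[nm]], nm),
             call. = FALSE)
      }
    }
    for (p in ins$dictionaries) {
      if (!file.exists(p)) {
        stop(sprintf("dictionary file does not exist: %s", p), call. = FALSE)
      }
    }
  }
  config
}

#' Run the stratification pipeline end to end
#'
#' Executes the configured stages in dependency order on the configured
#' inputs (file paths, or an in-memory `ehr_cohort` passed as
#' `config$cohort`), writes every stage output in its canonical format
#' under `output_dir`, and records a machine-readable manifest
#' (`manifest.json`) with the resolved configuration, package version and
#' per-stage row counts. All randomness (stability perturbations) derives
#' from `config$seed`, so a fixed configuration reproduces identical
#' outputs.
#'
#' @param config run configuration; see [validate_run_config()].
#' @return invisibly, a list with every computed stage result and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  p <- config$params
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  counts <- list()
  emit <- function(df, name) {
    readr::write_tsv(df, file.path(config$output_dir, paste0(name, ".tsv")))
    counts[[name]] <<- nrow(df)
  }

  if (!is.null(config$cohort)) {
    stopifnot(inherits(config$cohort, "ehr_cohort"))
    cohort <- config$cohort
    notes <- cohort$notes
    events_assigned <- cohort$events
    patients <- cohort$patients
    labs <- cohort$labs
    prescriptions <- cohort$prescriptions
    dictionaries <- list(cohort$dictionaries)
  } else {
    ins <- config$inputs
    notes <- read_notes(ins$notes)
    events_assigned <- read_events(ins$events)
    patients <- read_patients(ins$patients)
    labs <- read_labs(ins$labs)
    prescriptions <- read_prescriptions(ins$prescriptions)
    dictionaries <- lapply(ins$dictionaries, read_dictionary)
  }
  stages <- config$stages

  events_all <- events_assigned
  if ("tag" %in% stages) {
    lemma <- NULL
    if (!is.null(config$inputs$lemma_table)) {
      lt <- readr::read_tsv(config$inputs$lemma_table,
                            show_col_types = FALSE, progress = FALSE)
      lemma <- setNames(lt[[2L]], lt[[1L]])
    }
    blocklist <- NULL
    if (!is.null(config$inputs$blocklist)) {
      blocklist <- readr::read_tsv(config$inputs$blocklist,
                                   show_col_types = FALSE, progress = FALSE)
    }
    tagged <- tag_corpus(notes, dictionaries, lemma_table = lemma,
                         max_edits = p$ner$max_edits,
                         negation_window = p$ner$negation_window,
                         blocklist = blocklist)
    out$mentions <- tagged$mentions
    emit(tagged$mentions, "mentions")
    events_all <- bind_rows(
      mutate(events_assigned, source = "assigned"),
      tagged$events)
    emit(events_all, "events_combined")
  }
  out$events <- events_all

  vectors <- NULL
  if ("vectorize" %in% stages) {
    lists <- build_code_lists(events_all,
                              exclude_codes = p$vectors$exclude_codes)
    vectors <- bm25_vectors(lists, b = p$vectors$b, k1 = p$vectors$k1)
    out$vectors <- vectors
    emit(vectors, "vectors")
  }

  partition <- NULL
  network <- NULL
  if ("cluster" %in% stages) {
    if (is.null(vectors)) {
      # allow clustering precomputed vectors from an earlier run
      vec_path <- file.path(config$output_dir, "vectors.tsv")
      if (!file.exists(vec_path)) {
        stop("clustering requires the vectorize stage or a vectors.tsv in ",
             "output_dir", call. = FALSE)
      }
      vectors <- readr::read_tsv(vec_path, show_col_types = FALSE,
                                 progress = FALSE)
    }
    network <- cosine_network(vectors, cutoff = p$network$cutoff)
    partition <- mcl_partition(network, inflation = p$mcl$inflation)
    out$network <- network
    out$partition <- partition
    emit(network$edges, "network_edges")
    emit(partition$assignments, "partition")
    emit(partition_view(partition, p$mcl$min_cluster), "partition_retained")
  }

  if ("stability" %in% stages && !is.null(partition)) {
    curve <- stability_curve(network, reference = partition,
                             alphas = p$stability$alphas,
                             mode = p$stability$mode,
                             replicates = p$stability$replicates,
                             inflation = p$mcl$inflation,
                             seed = config$seed)
    out$stability <- curve
    emit(as_tibble(curve), "stability_curve")
    emit(attr(curve, "reference_lines"), "stability_reference_lines")
  }

  grouping <- NULL
  if ("symptom_groups" %in% stages && !is.null(partition)) {
    analysis <- partition_view(partition, p$mcl$analysis_min)
    if (nrow(analysis) && n_distinct(analysis$cluster) >= 2L) {
      profiles <- symptom_profiles(analysis, events_all)
      k_eff <- min(p$symptoms$k, nrow(profiles))
      grouping <- ward_groups(profiles, k = k_eff,
                              method = p$symptoms$method)
      out$symptom_profiles <- profiles
      out$symptom_grouping <- grouping
      emit(profiles, "symptom_profiles")
      emit(grouping$groups, "symptom_groups")
    }
  }

  if ("enrichment" %in% stages && !is.null(partition)) {
    retained <- partition_view(partition, p$mcl$min_cluster)
    strata <- sex_decade_strata(patients)
    enr <- stratified_binomial_enrichment(
      retained, events_all, strata,
      min_support = p$enrichment$min_support, alpha = p$enrichment$alpha)
    out$enrichment <- enr
    emit(enr, "enrichment")
    meta <- patients |>
      mutate(age = as.numeric(as.Date("2012-12-31") - birth_date) / 365.25,
             diabetes_duration =
               as.numeric(as.Date("2012-12-31") - onset_date) / 365.25) |>
      select(patient_id, age, diabetes_duration)
    contrasts <- metadata_contrasts(retained, meta,
                                    alpha = p$enrichment$alpha)
    out$metadata_contrasts <- contrasts
    emit(contrasts, "metadata_contrasts")
    rx <- prescription_enrichment(partition, prescriptions,
                                  level = p$enrichment$atc_level,
                                  min_cluster_size = p$mcl$analysis_min,
                                  alpha = p$enrichment$alpha)
    out$prescription_enrichment <- rx
    emit(rx, "prescription_enrichment")
  }

  if ("comorbidity" %in% stages) {
    pairs <- pair_cooccurrence(events_all,
                               min_carriers = p$comorbidity$min_carriers,
                               smoothing = p$comorbidity$smoothing,
                               alpha = p$comorbidity$alpha)
    out$pair_stats <- pairs
    emit(pairs, "comorbidity_pairs")
    dir_stats <- pair_directionality(
      events_all, pairs = select(pairs, code_a, code_b),
      alpha = p$comorbidity$alpha)
    out$pair_directionality <- dir_stats
    emit(dir_stats, "comorbidity_directionality")
    top <- top_pairs_by_unique_codes(pairs,
                                     max_unique = p$comorbidity$max_unique_codes)
    emit(top, "comorbidity_top_pairs")
    out$top_pairs <- top
    if (!is.null(grouping) && !is.null(partition)) {
      membership <- partition$assignments |>
        inner_join(grouping$groups, by = "cluster") |>
        select(patient_id, group)
      per_group <- lapply(split(membership$patient_id, membership$group),
                          function(ids) {
        pair_cooccurrence(filter(events_all, patient_id %in% ids),
                          min_carriers = p$comorbidity$min_carriers,
                          smoothing = p$comorbidity$smoothing,
                          alpha = p$comorbidity$alpha)
      })
      uniq <- group_unique_pairs(per_group)
      out$group_unique_pairs <- uniq
      emit(uniq, "group_unique_pairs")
      sig_dir <- filter(dir_stats, direction != "none")
      if (nrow(sig_dir)) {
        lag_tab <- pair_lag_table(events_all,
                                  select(sig_dir, code_a, code_b),
                                  membership)
        lagres <- lag_anova(lag_tab)
        out$lag_anova <- lagres
        emit(lagres, "lag_anova")
      }
    }
  }

  if ("dysregulation" %in% stages) {
    hba1c <- extract_hba1c(labs, p$dysregulation$hba1c_test_id)
    onsets <- select(patients, patient_id, onset_date)
    prof <- dysregulation_profiles(events_all, hba1c, onsets,
                                   patient_ids = patients$patient_id,
                                   min_criteria = p$dysregulation$min_criteria)
    out$dysregulation <- prof
    emit(as_tibble(prof), "dysregulation_profiles")
    panel <- filter(labs, test_id != p$dysregulation$hba1c_test_id)
    summaries <- normalize_labs(panel, population = patients$patient_id,
                                coverage = p$dysregulation$coverage)
    groups <- transmute(as_tibble(prof), patient_id,
                        group = if_else(dysregulated, "dysregulated",
                                        "regulated"))
    lc <- lab_contrasts(summaries, groups, alpha = p$dysregulation$alpha)
    out$lab_contrasts <- lc
    emit(lc$manova, "lab_manova")
    emit(lc$ks, "lab_ks")
  }

  manifest <- list(
    package = "phenostrat",
    version = as.character(utils::packageVersion("phenostrat")),
    seed = config$seed,
    stages = stages,
    params = config$params,
    counts = counts
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}

#' Generate a synthetic cohort and write it to disk
#'
#' Convenience entry point pairing [generate_cohort()] with
#' [write_cohort()]; the written files are the canonical inputs of
#' [run_pipeline()].
#'
#' @param config a [cohort_config()].
#' @param dir output directory.
#' @return the cohort, invisibly.
#' @export
simulate_cohort_files <- function(config = cohort_config(), dir) {
  cohort <- generate_cohort(config)
  write_cohort(cohort, dir)
  invisible(cohort)
}
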