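# Glycemic dysregulation: five per-patient criteria (dysregulation and
# hyperglycemia codes, HbA1c change points, estimated HbA1c at diabetes
# onset, severity-bin frequencies), the 0-5 score with the >= 3 flag, and
# lab-panel contrasts between score groups.

#' Preprocess HbA1c series into analysis segments
#'
#' Values outside the biological reference interval (`[15, 184]` mmol/mol)
#' are removed, same-day duplicates are averaged, series are split at
#' measurement gaps longer than `gap_days`, and only segments with at
#' least `min_values` measurements spanning at least `min_span_days`
#' (about the functional lifetime of red blood cells) are kept. Patients
#' without a valid segment are excluded from the HbA1c-based criteria;
#' exclusion is a status, not an error.
#'
#' @param hba1c tibble `patient_id`, `date`, `value` (mmol/mol).
#' @param lower,upper biological reference bounds.
#' @param gap_days gap splitting consecutive segments.
#' @param min_values,min_span_days segment validity rules.
#' @return tibble `patient_id`, `date`, `value`, `segment`, `valid` with
#'   one row per retained measurement; `valid` marks measurements inside a
#'   valid segment.
#' @export
preprocess_hba1c <- function(hba1c, lower = 15, upper = 184,
                             gap_days = 365, min_values = 5L,
                             min_span_days = 90) {
  assert_cols(hba1c, c("patient_id", "date", "value"), "hba1c")
  d <- hba1c |>
    filter(!is.na(value), value >= lower, value <= upper) |>
    mutate(date = as.Date(date)) |>
    group_by(patient_id, date) |>
    summarise(value = mean(value), .groups = "drop") |>
    arrange(patient_id, date)
  if (!nrow(d)) {
    return(mutate(d, segment = integer(), valid = logical()))
  }
  d <- d |>
    group_by(patient_id) |>
    mutate(gap = c(0, diff(as.numeric(date))),
           segment = cumsum(gap > gap_days) + 1L) |>
    group_by(patient_id, segment) |>
    mutate(valid = n() >= min_values &
             as.numeric(max(date) - min(date)) >= min_span_days) |>
    ungroup() |>
    select(-gap)
  d
}

#' Code-based dysregulation criteria
#'
#' Two flags per patient from the combined mined + assigned event stream:
#' the clinic's custom dysregulation code (`sdcL03`) and the ICD-10
#' hyperglycemia codes (`R73`, `E89`).
#'
#' @param events code event stream.
#' @param patient_ids patients to evaluate (defaults to those in
#'   `events`).
#' @param dysreg_code custom dysregulation code.
#' @param hyper_codes hyperglycemia codes.
#' @return tibble `patient_id`, `has_dysreg_code`, `has_hyper_code`.
#' @export
code_criteria <- function(events, patient_ids = NULL,
                          dysreg_code = "sdcL03",
                          hyper_codes = c("R73", "E89")) {
  presence <- patient_code_presence(events)
  ids <- patient_ids %||% sort(unique(presence$patient_id))
  d <- presence |> group_by(patient_id) |>
    summarise(has_dysreg_code = any(code %in% dysreg_code),
              has_hyper_code = any(code %in% hyper_codes))
  out <- tibble(patient_id = ids) |>
    left_join(d, by = "patient_id") |>
    mutate(across(c(has_dysreg_code, has_hyper_code),
                  ~ replace_na(.x, FALSE)))
  out
}

# Bayesian change-point analysis of one series under a Gaussian
# observation model with a Normal-Gamma conjugate prior and a geometric
# (constant-hazard) prior on segment lengths. The forward pass is the
# classical online run-length recursion; because HbA1c series are analysed
# retrospectively, a matching backward pass yields the exact smoothed
# posterior probability that a new segment starts at each index.

# log marginal likelihood of every contiguous stretch x[a..b] under the
# Normal-Gamma prior; returned as an n x n matrix (upper triangle)
segment_log_ml <- function(x, mu0, kappa0, alpha0, beta0) {
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  out <- matrix(-Inf, n, n)
  for (a in seq_len(n)) {
    for (b in a:n) {
      m <- b - a + 1L
      sx <- cs[b] - if (a > 1L) cs[a - 1L] else 0
      sx2 <- cs2[b] - if (a > 1L) cs2[a - 1L] else 0
      xbar <- sx / m
      ss <- max(sx2 - m * xbar^2, 0)
      kap <- kappa0 + m
      alp <- alpha0 + m / 2
      bet <- beta0 + ss / 2 + kappa0 * m * (xbar - mu0)^2 / (2 * kap)
      out[a, b] <- lgamma(alp) - lgamma(alpha0) +
        alpha0 * log(beta0) - alp * log(bet) +
        0.5 * (log(kappa0) - log(kap)) - (m / 2) * log(2 * pi)
    }
  }
  out
}

log_sum_exp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

# exact smoothed posterior P(a new segment starts at index s | x) for
# s = 2..n, via forward-backward recursions over segment marginals
changepoint_posterior <- function(x, hazard = 0.1, mu0 = mean(x),
                                  kappa0 = 1, alpha0 = 2, beta0 = NULL) {
  n <- length(x)
  if (is.null(beta0) || is.na(beta0)) {
    # centre the noise prior on a robust scale estimate from successive
    # differences, which a level shift barely inflates
    sigma2 <- if (n >= 3L) (stats::mad(diff(x)) / sqrt(2))^2 else var(x) / 2
    beta0 <- alpha0 * max(sigma2, 1e-3, na.rm = TRUE)
  }
  lml <- segment_log_ml(x, mu0, kappa0, alpha0, beta0)
  lh <- log(hazard)
  l1h <- log(1 - hazard)
  # forward: A[s] = log P(x[1..s-1], a segment starts at s)
  A <- rep(-Inf, n + 1L)
  A[1L] <- 0
  for (s in 2:(n + 1L)) {
    t <- 1:(s - 1L)
    A[s] <- log_sum_exp(A[t] + lml[cbind(t, s - 1L)] + (s - t - 1L) * l1h) + lh
  }
  # backward: Q[s] = log P(x[s..n] | a segment starts at s)
  Q <- rep(-Inf, n + 1L)
  for (s in n:1L) {
    tail_term <- lml[s, n] + (n - s) * l1h
    if (s < n) {
      e <- s:(n - 1L)
      inner <- lml[cbind(s, e)] + (e - s) * l1h + lh + Q[e + 1L]
      Q[s] <- log_sum_exp(c(inner, tail_term))
    } else {
      Q[s] <- tail_term
    }
  }
  evidence <- Q[1L]
  # joint of (prefix ending in a change, suffix starting fresh) over the
  # total evidence
  p <- exp(A[2:n] + Q[2:n] - evidence)
  c(NA_real_, pmin(p, 1))
}

# change-point candidates for one numeric segment: indices s (s > 1)
# whose smoothed start posterior, pooled over +/- 1 index, reaches
# prob_threshold, gated by the level shift between the flanking stretches.
segment_changepoints <- function(x, prob_threshold = 0.5, min_shift = 5,
                                 hazard = 0.1, ...) {
  n <- length(x)
  if (n < 4L || length(unique(x)) == 1L) {
    return(integer())
  }
  p_start <- changepoint_posterior(x, hazard = hazard, ...)
  support <- numeric(n)
  for (s in 2:n) {
    win <- max(2L, s - 1L):min(n, s + 1L)
    support[s] <- sum(p_start[win], na.rm = TRUE)
  }
  cand <- which(support >= prob_threshold)
  # collapse candidates within two indices to the best-supported one
  if (length(cand) > 1L) {
    cand <- cand[order(-support[cand])]
    out <- integer()
    for (s in cand) {
      if (!length(out) || all(abs(out - s) > 2L)) out <- c(out, s)
    }
    cand <- sort(out)
  }
  # magnitude gate: compare mean levels of the flanking stretches (bounded
  # by neighbouring candidates), which uses all available evidence
  keep <- integer()
  bounds <- c(1L, cand, n + 1L)
  for (ci in seq_along(cand)) {
    s <- cand[ci]
    before <- x[bounds[ci]:(s - 1L)]
    after <- x[s:(bounds[ci + 2L] - 1L)]
    if (abs(mean(after) - mean(before)) >= min_shift) {
      keep <- c(keep, s)
    }
  }
  keep
}

#' Change-point criterion from preprocessed HbA1c segments
#'
#' Runs Bayesian change-point detection (Gaussian observation model with a
#' Normal-Gamma conjugate prior and a geometric segment-length prior) on
#' every valid segment, using the exact smoothed posterior over segment
#' starts. The flag is true when any change point attains posterior mass
#' of at least `prob_threshold` and the associated level shift is at least
#' `min_shift` mmol/mol. Constant segments never flag.
#'
#' @param hba1c a [preprocess_hba1c()] result.
#' @param prob_threshold posterior mass required for a change point.
#' @param min_shift minimum absolute level shift (mmol/mol).
#' @param hazard constant hazard of the geometric run-length prior.
#' @return list with `flags` (tibble `patient_id`, `changepoint`,
#'   `evaluable`) and `changepoints` (tibble `patient_id`, `segment`,
#'   `index` within segment, `date`).
#' @export
changepoint_flag <- function(hba1c, prob_threshold = 0.5, min_shift = 5,
                             hazard = 0.1) {
  assert_cols(hba1c, c("patient_id", "date", "value", "segment", "valid"),
              "hba1c")
  valid <- filter(hba1c, valid)
  ids <- sort(unique(hba1c$patient_id))
  cps <- list()
  flags <- setNames(logical(length(ids)), ids)
  evaluable <- setNames(logical(length(ids)), ids)
  for (pid in unique(valid$patient_id)) {
    evaluable[pid] <- TRUE
    pdat <- filter(valid, patient_id == pid)
    for (seg in unique(pdat$segment)) {
      sdat <- pdat[pdat$segment == seg, ]
      hits <- segment_changepoints(sdat$value, prob_threshold, min_shift,
                                   hazard)
      if (length(hits)) {
        flags[pid] <- TRUE
        cps[[length(cps) + 1L]] <- tibble(
          patient_id = pid, segment = seg, index = hits,
          date = sdat$date[hits])
      }
    }
  }
  list(
    flags = tibble(patient_id = ids, changepoint = unname(flags[ids]),
                   evaluable = unname(evaluable[ids])),
    changepoints = if (length(cps)) bind_rows(cps) else
      tibble(patient_id = character(), segment = integer(),
             index = integer(), date = as.Date(character()))
  )
}

#' Estimated HbA1c at diabetes onset (mixed-effects criterion)
#'
#' Fits a linear mixed model of HbA1c on time since onset with a
#' patient-level random intercept (and random slope when the data support
#' it), and predicts each patient's HbA1c at onset (time zero). Patients
#' with a single measurement shrink toward the population mean. The flag
#' is true when the predicted onset value is at or above `threshold`
#' (53 mmol/mol, the diabetes diagnosis level).
#'
#' @param hba1c a [preprocess_hba1c()] result (valid measurements are
#'   used).
#' @param onsets tibble `patient_id`, `onset_date`.
#' @param threshold onset HbA1c flag threshold (mmol/mol).
#' @param random_slope `"auto"` adds a random slope when the median number
#'   of measurements per patient is at least four (falling back to the
#'   intercept-only model on convergence failure); `"never"` forces the
#'   intercept-only model.
#' @return tibble `patient_id`, `onset_value`, `onset_level`, `evaluable`.
#' @export
onset_level_flag <- function(hba1c, onsets, threshold = 53,
                             random_slope = c("auto", "never")) {
  random_slope <- match.arg(random_slope)
  assert_cols(onsets, c("patient_id", "onset_date"), "onsets")
  valid <- filter(hba1c, valid)
  d <- valid |>
    inner_join(onsets, by = "patient_id") |>
    filter(!is.na(onset_date)) |>
    mutate(time = as.numeric(as.Date(date) - as.Date(onset_date)) / 365.25)
  ids <- sort(unique(hba1c$patient_id))
  # patients with a single measurement stay in the fit; their random
  # intercept shrinks toward the population mean
  if (!nrow(d) || length(unique(d$patient_id)) < 3L) {
    return(tibble(patient_id = ids, onset_value = NA_real_,
                  onset_level = FALSE, evaluable = FALSE))
  }
  use_slope <- random_slope == "auto" &&
    median(count(d, patient_id)$n) >= 4L
  fit <- NULL
  if (use_slope) {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(value ~ time + (1 + time | patient_id), data = d,
                   control = lme4::lmerControl(calc.derivs = FALSE)))),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(value ~ time + (1 | patient_id), data = d,
                 control = lme4::lmerControl(calc.derivs = FALSE))))
  }
  re <- lme4::ranef(fit)$patient_id
  pred <- lme4::fixef(fit)[["(Intercept)"]] + re[["(Intercept)"]]
  est <- tibble(patient_id = rownames(re), onset_value = pred)
  tibble(patient_id = ids) |>
    left_join(est, by = "patient_id") |>
    mutate(evaluable = !is.na(onset_value),
           onset_level = evaluable & onset_value >= threshold)
}

#' Severity-bin criterion from HbA1c values
#'
#' Bins the valid measurements into clinically motivated HbA1c intervals
#' (below diagnosis level, diagnosis band, elevated, critical) and flags
#' patients for whom the fraction of measurements at or above
#' `threshold_value` (53 mmol/mol) exceeds `frac_threshold`.
#'
#' @param hba1c a [preprocess_hba1c()] result.
#' @param bins cut points of the severity bins (mmol/mol).
#' @param threshold_value diagnosis-level threshold.
#' @param frac_threshold flagging fraction.
#' @return list with `flags` (tibble `patient_id`, `severity`,
#'   `frac_above`, `evaluable`) and `bin_freq` (long tibble of per-patient
#'   bin fractions).
#' @export
severity_flag <- function(hba1c, bins = c(48, 53, 75),
                          threshold_value = 53, frac_threshold = 0.5) {
  valid <- filter(hba1c, valid)
  ids <- sort(unique(hba1c$patient_id))
  breaks <- c(-Inf, bins, Inf)
  labels <- paste0("bin_", c(paste0("lt", bins[1L]),
                             paste0(bins[-length(bins)], "_", bins[-1L]),
                             paste0("ge", bins[length(bins)])))
  summ <- valid |>
    group_by(patient_id) |>
    summarise(frac_above = mean(value >= threshold_value), n = n())
  bin_freq <- valid |>
    mutate(bin = cut(value, breaks = breaks, labels = labels,
                     right = FALSE)) |>
    count(patient_id, bin, name = "n_bin") |>
    group_by(patient_id) |>
    mutate(freq = n_bin / sum(n_bin)) |>
    ungroup()
  flags <- tibble(patient_id = ids) |>
    left_join(summ, by = "patient_id") |>
    mutate(evaluable = !is.na(frac_above),
           severity = evaluable & frac_above > frac_threshold) |>
    select(patient_id, severity, frac_above, evaluable)
  list(flags = flags, bin_freq = bin_freq)
}

#' Combine the five criteria into the dysregulation score
#'
#' The score is the number of true criteria (0-5); a patient is called
#' dysregulated when at least three criteria hold. Non-evaluable criteria
#' count as false.
#'
#' @param flags tibble with `patient_id` and logical columns
#'   `has_dysreg_code`, `has_hyper_code`, `changepoint`, `onset_level`,
#'   `severity`.
#' @param min_criteria criteria needed for the dysregulated call.
#' @return the input with `score` (integer 0-5) and `dysregulated`
#'   columns, of class `dysregulation_profile`.
#' @export
dysregulation_score <- function(flags, min_criteria = 3L) {
  crit <- c("has_dysreg_code", "has_hyper_code", "changepoint",
            "onset_level", "severity")
  assert_cols(flags, c("patient_id", crit), "flags")
  m <- as.matrix(flags[, crit])
  storage.mode(m) <- "logical"
  out <- mutate(flags,
                score = as.integer(rowSums(m)),
                dysregulated = score >= min_criteria)
  structure(out, class = c("dysregulation_profile", class(out)),
            min_criteria = min_criteria)
}

#' Full five-criterion dysregulation profile
#'
#' Convenience wrapper: preprocesses the HbA1c series, evaluates the two
#' code criteria and the three HbA1c criteria, and combines them into the
#' score.
#'
#' @param events combined mined + assigned code events.
#' @param hba1c raw HbA1c series (`patient_id`, `date`, `value`).
#' @param onsets tibble `patient_id`, `onset_date`.
#' @param patient_ids cohort patients (defaults to union of inputs).
#' @param min_criteria dysregulated call threshold.
#' @param ... passed to [changepoint_flag()].
#' @return a `dysregulation_profile` tibble with the five flags, score and
#'   dysregulated call; change-point details in `attr(, "changepoints")`.
#' @export
dysregulation_profiles <- function(events, hba1c, onsets,
                                   patient_ids = NULL, min_criteria = 3L,
                                   ...) {
  ids <- patient_ids %||%
    sort(unique(c(events$patient_id, hba1c$patient_id)))
  prep <- preprocess_hba1c(hba1c)
  codes <- code_criteria(events, patient_ids = ids)
  cp <- changepoint_flag(prep, ...)
  onset <- onset_level_flag(prep, onsets)
  sev <- severity_flag(prep)
  flags <- tibble(patient_id = ids) |>
    left_join(codes, by = "patient_id") |>
    left_join(select(cp$flags, patient_id, changepoint), by = "patient_id") |>
    left_join(select(onset, patient_id, onset_level, onset_value),
              by = "patient_id") |>
    left_join(select(sev$flags, patient_id, severity), by = "patient_id") |>
    mutate(across(c(has_dysreg_code, has_hyper_code, changepoint,
                    onset_level, severity), ~ replace_na(.x, FALSE)))
  out <- dysregulation_score(flags, min_criteria)
  attr(out, "changepoints") <- cp$changepoints
  out
}

#' Normalize long-format labs and summarise per patient
#'
#' Applies the coverage filter (tests measured on at least `coverage` of
#' the corpus are kept), log-transforms tests whose values fail a
#' normality check (Shapiro-Wilk on a subsample; only when all values are
#' positive), standardizes each test to mean 0 / SD 1, and returns
#' per-patient mean, median and SD on the normalized scale.
#'
#' @param labs tibble `patient_id`, `test_id`, `date`, `value`.
#' @param population character vector of corpus patient ids (defaults to
#'   patients in `labs`).
#' @param coverage minimum fraction of the corpus measured.
#' @param normality_alpha Shapiro-Wilk level triggering the log
#'   transform.
#' @return tibble `patient_id`, `test_id`, `mean`, `median`, `sd`, with
#'   the retained tests in `attr(, "tests")`.
#' @export
normalize_labs <- function(labs, population = NULL, coverage = 0.75,
                           normality_alpha = 0.05) {
  assert_cols(labs, c("patient_id", "test_id", "value"), "labs")
  pats <- population %||% sort(unique(labs$patient_id))
  labs <- filter(labs, patient_id %in% pats, !is.na(value))
  cov <- labs |>
    distinct(patient_id, test_id) |>
    count(test_id, name = "n_patients") |>
    mutate(frac = n_patients / length(pats))
  keep <- cov$test_id[cov$frac >= coverage]
  labs <- filter(labs, test_id %in% keep)
  out <- list()
  for (tid in keep) {
    idx <- labs$test_id == tid
    x <- labs$value[idx]
    test_sample <- head(x, 4999L)   # deterministic subsample for the check
    logit <- FALSE
    if (length(unique(test_sample)) > 2L && length(test_sample) >= 3L &&
        all(x > 0)) {
      sw <- tryCatch(shapiro.test(test_sample)$p.value,
                     error = function(e) 1)
      logit <- sw < normality_alpha
    }
    if (logit) x <- log(x)
    x <- as.numeric(scale(x))
    out[[tid]] <- tibble(patient_id = labs$patient_id[idx], test_id = tid,
                         value = x)
  }
  norm <- bind_rows(out)
  summ <- norm |>
    group_by(patient_id, test_id) |>
    summarise(mean = mean(value), median = median(value),
              sd = sd(value), .groups = "drop")
  structure(summ, tests = keep)
}

#' Lab-panel contrasts between patient groups
#'
#' One-way MANOVA across groups on the per-patient test means (complete
#' cases), plus per-test two-sample Kolmogorov-Smirnov tests of each group
#' against the rest, Bonferroni-adjusted.
#'
#' @param lab_summaries a [normalize_labs()] result.
#' @param groups tibble `patient_id`, `group` (clusters, symptom groups,
#'   or the dysregulated split).
#' @param alpha significance level on adjusted p-values.
#' @return list with `manova` (overall Pillai test) and `ks` (per test and
#'   group).
#' @export
lab_contrasts <- function(lab_summaries, groups, alpha = 0.05) {
  assert_cols(lab_summaries, c("patient_id", "test_id", "mean"),
              "lab_summaries")
  assert_cols(groups, c("patient_id", "group"), "groups")
  wide <- lab_summaries |>
    select(patient_id, test_id, mean) |>
    pivot_wider(names_from = test_id, values_from = mean) |>
    inner_join(groups, by = "patient_id")
  grp_sizes <- count(wide, group)
  wide <- filter(wide, group %in% grp_sizes$group[grp_sizes$n >= 2L])
  tests <- setdiff(names(wide), c("patient_id", "group"))
  manova_res <- tibble(statistic = NA_real_, p_value = NA_real_)
  cc <- wide[complete.cases(wide[, tests]), ]
  if (length(unique(cc$group)) >= 2L && nrow(cc) > length(tests) + 2L) {
    fit <- manova(as.matrix(cc[, tests]) ~ factor(cc$group))
    sm <- summary(fit, test = "Pillai")$stats
    manova_res <- tibble(statistic = sm[1L, "Pillai"],
                         p_value = sm[1L, "Pr(>F)"])
  }
  ks_rows <- list()
  for (tid in tests) {
    for (g in sort(unique(wide$group))) {
      x <- wide[[tid]][wide$group == g]
      y <- wide[[tid]][wide$group != g]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2L || length(y) < 2L) next
      ks <- suppressWarnings(ks.test(x, y))
      ks_rows[[length(ks_rows) + 1L]] <- tibble(
        test_id = tid, group = g, statistic = unname(ks$statistic),
        mean_diff = mean(x) - mean(y), p_value = ks$p.value)
    }
  }
  ks_res <- bind_rows(ks_rows)
  if (nrow(ks_res)) {
    ks_res$p_adjusted <- p.adjust(ks_res$p_value, method = "bonferroni")
    ks_res$significant <- ks_res$p_adjusted <= alpha
  }
  list(manova = manova_res, ks = ks_res)
}
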