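#' Default synthetic drug catalog
#'
#' Five low-exposure study drugs (antibody-conjugate-like agents) against a
#' background of ten common comparator drugs, with marginal primary-suspect
#' probabilities summing to 1.
#'
#' @return Tibble with columns `drug_id`, `prob`, `study`.
#' @export
default_drug_catalog <- function() {
  study <- tibble(drug_id = paste0("adc_", letters[1:5]),
                  prob = c(0.030, 0.020, 0.015, 0.010, 0.005), study = TRUE)
  bg <- tibble(drug_id = paste0("drug_", sprintf("%02d", 1:10)),
               prob = NA_real_, study = FALSE)
  bg$prob <- (1 - sum(study$prob)) / nrow(bg)
  bind_rows(study, bg)
}

#' Default synthetic PT vocabulary
#'
#' Eight neuropathy-like target terms (the signal set) and twelve common
#' background terms, with baseline per-report reporting weights: target
#' terms are rare, background terms common, mimicking the sparsity of PT
#' counts in spontaneous-report databases.
#'
#' @return Tibble with columns `pt_code`, `pt_name`, `base_prob`, `pns`.
#' @export
default_pt_vocab <- function() {
  pns <- tibble(
    pt_code = sprintf("PT%04d", 1:8),
    pt_name = c("Neuropathy peripheral", "Polyneuropathy",
                "Peripheral sensory neuropathy", "Peripheral motor neuropathy",
                "Peripheral sensorimotor neuropathy", "Demyelinating polyneuropathy",
                "Guillain-Barre syndrome", "Paraesthesia"),
    base_prob = c(0.010, 0.006, 0.005, 0.003, 0.002, 0.001, 0.001, 0.012),
    pns = TRUE)
  bg <- tibble(
    pt_code = sprintf("PT%04d", 101:112),
    pt_name = c("Nausea", "Fatigue", "Pyrexia", "Diarrhoea", "Rash", "Anaemia",
                "Headache", "Vomiting", "Dyspnoea", "Neutropenia", "Dizziness",
                "Arthralgia"),
    base_prob = c(0.30, 0.28, 0.20, 0.22, 0.15, 0.12, 0.14, 0.16, 0.10, 0.08,
                  0.09, 0.07),
    pns = FALSE)
  bind_rows(pns, bg)
}

#' Configuration of the synthetic report generator
#'
#' Describes a synthetic spontaneous-reporting database with known ground
#' truth. Events are modelled as independent per-PT inclusion draws,
#' conditioned on at least one event per report: PT `j` enters a report of
#' drug `g` with probability `min(1, s * base_prob_j * rho(g, j))`, where the
#' scale `s` calibrates the mean number of events per report to
#' `1 + events_lambda`. Conditioning on a non-empty event list keeps every
#' inclusion probability in closed form (see [expected_cells()]).
#'
#' @param n_reports Number of unique cases to generate.
#' @param drugs Catalog tibble (`drug_id`, `prob`, `study`); probabilities
#'   must sum to 1.
#' @param pts Vocabulary tibble (`pt_code`, `pt_name`, `base_prob`, `pns`).
#' @param signals Injected drug-event associations: tibble (`drug_id`,
#'   `pt_code`, `rho`) with `rho > 0` multiplying the baseline inclusion
#'   probability. Empty = null database.
#' @param events_lambda Mean extra events per report beyond the first.
#' @param dup_rate Probability a case emits an earlier superseded version.
#' @param missing Named list of missingness probabilities: `sex`, `age`,
#'   `country`, `therapy_start`, `event_date`, `partial_date` (probability a
#'   present date carries only month precision), `drug_match` (probability
#'   the suspect drug name is not resolvable in the dictionary).
#' @param reporter_probs Mix over MD/PH/HP/consumer.
#' @param outcome_probs Per-category seriousness probabilities (independent
#'   Bernoulli per category).
#' @param onset Per-drug log-normal onset-delay parameters: tibble
#'   (`drug_id`, `meanlog`, `sdlog`) in log-days; drugs not listed use
#'   `meanlog = log(30)`, `sdlog = 0.8`.
#' @param date_window Two receipt dates bounding the reporting window.
#' @param year_weights Optional relative weights over the window's calendar
#'   years (for non-stationary reporting).
#' @param comed Optional confounding scenario: list with `comed_id`,
#'   `prob` (probability a report carries the neurotoxic co-medication) and
#'   `pairs` (tibble `drug_id`, `pt_code`, `rho`): the multiplier applies
#'   only in reports carrying the co-medication, so the association is
#'   attributable to the co-medication, not the suspect drug.
#' @param conc_prob Probability of one additional benign concomitant
#'   mention.
#' @return A validated `synth_config` object.
#' @export
synth_config <- function(n_reports = 50000,
                         drugs = default_drug_catalog(),
                         pts = default_pt_vocab(),
                         signals = NULL,
                         events_lambda = 1.5,
                         dup_rate = 0.10,
                         missing = list(),
                         reporter_probs = c(MD = 0.50, PH = 0.10, HP = 0.20,
                                            consumer = 0.20),
                         outcome_probs = c(death = 0.05, life_threatening = 0.02,
                                           hospitalization = 0.20,
                                           disability = 0.04,
                                           congenital_anomaly = 0.001,
                                           required_intervention = 0.005,
                                           other_serious = 0.55, unknown = 0.08),
                         onset = NULL,
                         date_window = as.Date(c("2015-01-01", "2024-12-31")),
                         year_weights = NULL,
                         comed = NULL,
                         conc_prob = 0.25) {
  drugs <- as_tibble(drugs); pts <- as_tibble(pts)
  stopifnot(n_reports >= 1, all(drugs$prob >= 0), all(pts$base_prob > 0),
            all(pts$base_prob <= 1), events_lambda >= 0,
            dup_rate >= 0, dup_rate <= 1, conc_prob >= 0, conc_prob <= 1)
  if (abs(sum(drugs$prob) - 1) > 1e-8)
    stop("drug catalog probabilities must sum to 1")
  if (abs(sum(reporter_probs) - 1) > 1e-8)
    stop("reporter mix must sum to 1")
  if (any(outcome_probs < 0 | outcome_probs > 1))
    stop("outcome probabilities must be in [0, 1]")
  stopifnot(all(names(reporter_probs) %in% REPORTER_LEVELS),
            all(names(outcome_probs) %in% OUTCOME_LEVELS))
  miss_def <- list(sex = 0.12, age = 0.30, country = 0.05, therapy_start = 0.25,
                   event_date = 0.15, partial_date = 0.10, drug_match = 0.05)
  miss_def[names(missing)] <- missing
  if (any(unlist(miss_def) < 0 | unlist(miss_def) > 1))
    stop("missingness probabilities must be in [0, 1]")
  if (is.null(signals))
    signals <- tibble(drug_id = character(), pt_code = character(),
                      rho = numeric())
  signals <- as_tibble(signals)
  if (nrow(signals)) {
    stopifnot(all(signals$rho > 0),
              all(signals$drug_id %in% drugs$drug_id),
              all(signals$pt_code %in% pts$pt_code))
  }
  if (is.null(onset))
    onset <- tibble(drug_id = character(), meanlog = numeric(),
                    sdlog = numeric())
  if (!is.null(comed)) {
    stopifnot(is.list(comed), !is.null(comed$comed_id), !is.null(comed$prob),
              comed$prob >= 0, comed$prob <= 1, !is.null(comed$pairs),
              all(comed$pairs$rho > 0))
  }
  structure(list(
    n_reports = as.integer(n_reports), drugs = drugs, pts = pts,
    signals = signals, events_lambda = events_lambda, dup_rate = dup_rate,
    missing = miss_def, reporter_probs = reporter_probs,
    outcome_probs = outcome_probs, onset = as_tibble(onset),
    date_window = date_window, year_weights = year_weights, comed = comed,
    conc_prob = conc_prob
  ), class = "synth_config")
}

# Per-drug PT inclusion probability rows under a config; stratum "base"
# (no co-medication) or "comed". Rows = drugs in catalog order, cols = PTs.
inclusion_matrix <- function(config, stratum = c("base", "comed")) {
  stratum <- match.arg(stratum)
  s <- (1 + config$events_lambda) / sum(config$pts$base_prob)
  q0 <- s * config$pts$base_prob
  G <- nrow(config$drugs); J <- nrow(config$pts)
  R <- matrix(1, G, J, dimnames = list(config$drugs$drug_id, config$pts$pt_code))
  if (nrow(config$signals)) {
    idx <- cbind(match(config$signals$drug_id, config$drugs$drug_id),
                 match(config$signals$pt_code, config$pts$pt_code))
    R[idx] <- R[idx] * config$signals$rho
  }
  if (stratum == "comed" && !is.null(config$comed) && nrow(config$comed$pairs)) {
    idx <- cbind(match(config$comed$pairs$drug_id, config$drugs$drug_id),
                 match(config$comed$pairs$pt_code, config$pts$pt_code))
    keep <- !is.na(idx[, 1]) & !is.na(idx[, 2])
    R[idx[keep, , drop = FALSE]] <- R[idx[keep, , drop = FALSE]] *
      config$comed$pairs$rho[keep]
  }
  Q <- sweep(R, 2, q0, `*`)
  pmin(Q, 1)
}

#' Analytic expected 2x2 cells under a synthetic configuration
#'
#' Closed-form expectations of the report-level case-noncase cells for every
#' (catalog drug, PT) pair, derived from the generative model: with
#' per-stratum inclusion probabilities `q` and the all-absent probability
#' `z = prod(1 - q)`, conditioning on a non-empty event list gives
#' `P(PT present) = q / (1 - z)`; co-medication strata are mixed by their
#' prevalence, and suspect-name dictionary misses move a report to the
#' comparator side with its event distribution intact. These expectations —
#' not the raw multiplier `rho` — are the recovery truth for simulation
#' checks, via the implied odds ratio `or_true`.
#'
#' @param config A `synth_config`.
#' @param n_reports Cohort size the expectations refer to (default the
#'   config's); cell counts scale linearly, `or_true` does not depend on it.
#' @return Tibble per (drug, PT): `a`, `b`, `c`, `d` (expected counts),
#'   `p_event_exposed`, `p_event_background`, `or_true`.
#' @export
expected_cells <- function(config, n_reports = NULL) {
  stopifnot(inherits(config, "synth_config"))
  n <- n_reports %||% config$n_reports
  Qb <- inclusion_matrix(config, "base")
  phi <- if (is.null(config$comed)) 0 else config$comed$prob
  Qc <- if (phi > 0) inclusion_matrix(config, "comed") else Qb
  p_in <- function(Q) {
    z <- apply(1 - Q, 1, prod)
    sweep(Q, 1, pmax(1 - z, 1e-300), `/`)
  }
  P <- (1 - phi) * p_in(Qb) + phi * p_in(Qc)   # P(pt j | drug g), mixed over strata
  pi_g <- config$drugs$prob
  m <- 1 - config$missing$drug_match           # dictionary match rate
  G <- nrow(config$drugs); J <- nrow(config$pts)
  rows <- tidyr::expand_grid(gi = seq_len(G), ji = seq_len(J))
  p_exp <- pi_g[rows$gi] * m                   # P(exposed & matched)
  pj_g <- P[cbind(rows$gi, rows$ji)]
  # background side: all other drugs plus this drug's unmatched reports
  tot_j <- as.vector(t(crossprod(pi_g, P)))[rows$ji]  # sum_g pi_g P(j|g)
  p_bg <- (tot_j - pi_g[rows$gi] * m * pj_g) / (1 - p_exp)
  a <- n * p_exp * pj_g
  b <- n * p_exp * (1 - pj_g)
  c <- n * (1 - p_exp) * p_bg
  d <- n * (1 - p_exp) * (1 - p_bg)
  tibble(drug_id = config$drugs$drug_id[rows$gi],
         pt_code = config$pts$pt_code[rows$ji],
         a = a, b = b, c = c, d = d,
         p_event_exposed = pj_g, p_event_background = p_bg,
         or_true = (pj_g / (1 - pj_g)) / (p_bg / (1 - p_bg)))
}

#' Generate a synthetic spontaneous-report database
#'
#' Draws a full report set from a [synth_config()]: one primary-suspect drug
#' per case, a non-empty event list from the per-PT inclusion model,
#' demographics/reporter/outcomes/dates with the configured missingness,
#' optional neurotoxic co-medication mentions (the confounding scenario),
#' and superseded duplicate versions with earlier receipt dates. Output is
#' byte-deterministic given the seed.
#'
#' @param config A `synth_config`.
#' @param seed Integer seed; all randomness flows from it.
#' @return List: `reports` (an `srs_reports` with all versions, ready for
#'   [deduplicate()]), `truth` (per-case assignments, duplicate flags, the
#'   analytic [expected_cells()] table and the config), and `dictionary`
#'   (tibble `name`, `drug_id` resolving the emitted names).
#' @export
generate_srs <- function(config, seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  n <- config$n_reports
  G <- nrow(config$drugs); J <- nrow(config$pts)
  gi <- sample.int(G, n, replace = TRUE, prob = config$drugs$prob)
  phi <- if (is.null(config$comed)) 0 else config$comed$prob
  comed_present <- runif(n) < phi
  Qb <- inclusion_matrix(config, "base")
  Qc <- if (phi > 0) inclusion_matrix(config, "comed") else Qb
  Q <- Qb[gi, , drop = FALSE]
  if (any(comed_present)) Q[comed_present, ] <- Qc[gi[comed_present], , drop = FALSE]
  M <- matrix(runif(n * J), n, J) < Q
  empty <- which(rowSums(M) == 0L)
  while (length(empty)) {      # rejection step: condition on >= 1 event
    M[empty, ] <- matrix(runif(length(empty) * J), length(empty), J) <
      Q[empty, , drop = FALSE]
    empty <- empty[rowSums(M[empty, , drop = FALSE]) == 0L]
  }
  case_id <- sprintf("C%07d", seq_len(n))
  # demographics
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.45, 0.55))
  sex[runif(n) < config$missing$sex] <- "unknown"
  age <- pmin(pmax(round(rnorm(n, 62, 14), 1), 0.1), 100)
  age[runif(n) < config$missing$age] <- NA_real_
  reporter <- sample(names(config$reporter_probs), n, replace = TRUE,
                     prob = config$reporter_probs)
  country <- sample(c("US", "JP", "CA", "FR", "DE"), n, replace = TRUE,
                    prob = c(0.5, 0.15, 0.1, 0.15, 0.1))
  country[runif(n) < config$missing$country] <- NA_character_
  # dates
  years <- seq(as.integer(format(config$date_window[1], "%Y")),
               as.integer(format(config$date_window[2], "%Y")))
  yw <- config$year_weights %||% rep(1, length(years))
  stopifnot(length(yw) == length(years))
  yr <- sample(years, n, replace = TRUE, prob = yw)
  receipt <- as.Date(sprintf("%d-01-01", yr)) +
    floor(runif(n, 0, 364.99))
  receipt <- pmin(pmax(receipt, config$date_window[1]), config$date_window[2])
  onset_par <- tibble(drug_id = config$drugs$drug_id) %>%
    left_join(config$onset, by = "drug_id") %>%
    mutate(meanlog = ifelse(is.na(.data$meanlog), log(30), .data$meanlog),
           sdlog = ifelse(is.na(.data$sdlog), 0.8, .data$sdlog))
  onset_days <- round(rlnorm(n, onset_par$meanlog[gi], onset_par$sdlog[gi]))
  lag <- rpois(n, 20)
  event_date <- receipt - lag
  therapy_start <- event_date - onset_days
  event_full <- rep(TRUE, n); start_full <- rep(TRUE, n)
  part_e <- runif(n) < config$missing$partial_date
  part_s <- runif(n) < config$missing$partial_date
  to_month <- function(d) as.Date(format(d, "%Y-%m-15"))
  event_date[part_e] <- to_month(event_date[part_e]); event_full[part_e] <- FALSE
  therapy_start[part_s] <- to_month(therapy_start[part_s]); start_full[part_s] <- FALSE
  event_date[runif(n) < config$missing$event_date] <- NA
  therapy_start[runif(n) < config$missing$therapy_start] <- NA
  event_full[is.na(event_date)] <- NA; start_full[is.na(therapy_start)] <- NA
  # drug mentions and dictionary
  display <- toupper(gsub("_", " ", config$drugs$drug_id))
  dictionary <- tibble(name = display, drug_id = config$drugs$drug_id)
  unmatched <- runif(n) < config$missing$drug_match
  raw_name <- display[gi]
  raw_name[unmatched] <- paste0(raw_name[unmatched], " UNSPECIFIED")
  ps_drugs <- tibble(case_idx = seq_len(n), raw_name = raw_name,
                     drug_id = ifelse(unmatched, NA_character_,
                                      config$drugs$drug_id[gi]),
                     role = "primary_suspect",
                     therapy_start = therapy_start,
                     therapy_start_full = start_full,
                     therapy_end = as.Date(NA))
  conc_idx <- which(runif(n) < config$conc_prob)
  conc <- tibble(case_idx = conc_idx,
                 gi2 = sample.int(G, length(conc_idx), replace = TRUE,
                                  prob = config$drugs$prob))
  conc <- conc[conc$gi2 != gi[conc$case_idx], ]
  conc_drugs <- tibble(case_idx = conc$case_idx,
                       raw_name = display[conc$gi2],
                       drug_id = config$drugs$drug_id[conc$gi2],
                       role = "concomitant", therapy_start = as.Date(NA),
                       therapy_start_full = NA, therapy_end = as.Date(NA))
  comed_drugs <- if (any(comed_present)) {
    cid <- config$comed$comed_id
    cn <- toupper(gsub("_", " ", cid))
    dictionary <- bind_rows(dictionary, tibble(name = cn, drug_id = cid))
    tibble(case_idx = which(comed_present), raw_name = cn, drug_id = cid,
           role = "concomitant", therapy_start = as.Date(NA),
           therapy_start_full = NA, therapy_end = as.Date(NA))
  } else NULL
  drugs_all <- bind_rows(ps_drugs, conc_drugs, comed_drugs) %>%
    arrange(.data$case_idx)
  # events
  hits <- which(M, arr.ind = TRUE)
  events_all <- tibble(case_idx = hits[, 1],
                       pt_code = config$pts$pt_code[hits[, 2]]) %>%
    arrange(.data$case_idx, .data$pt_code)
  # outcomes
  oc_list <- lapply(names(config$outcome_probs), function(ocat) {
    hit <- runif(n) < config$outcome_probs[[ocat]]
    tibble(case_idx = which(hit), outcome = ocat)
  })
  outcomes_all <- bind_rows(oc_list) %>% arrange(.data$case_idx, .data$outcome)
  # duplicate versions: superseded earlier version for a fraction of cases
  is_dup <- runif(n) < config$dup_rate
  final_id <- paste0(case_id, ifelse(is_dup, "-v2", "-v1"))
  reports <- tibble(
    report_id = final_id, case_id = case_id, receipt_date = receipt,
    sex = sex, age_years = age, age_group = age_group(age),
    reporter = reporter, country = country,
    event_date = event_date, event_date_full = event_full, valid = TRUE
  )
  expand_versions <- function(tab) {
    out <- tab
    out$report_id <- final_id[tab$case_idx]
    if (any(is_dup)) {
      dup <- tab[is_dup[tab$case_idx], ]
      dup$report_id <- paste0(case_id[dup$case_idx], "-v1")
      out <- bind_rows(out, dup)
    }
    out$case_idx <- NULL
    arrange(out, .data$report_id)
  }
  if (any(is_dup)) {
    early <- reports[is_dup, ]
    early$report_id <- paste0(early$case_id, "-v1")
    early$receipt_date <- early$receipt_date - (30 + floor(runif(sum(is_dup), 0, 171)))
    reports <- bind_rows(reports, early)
  }
  reports <- arrange(reports, .data$report_id)
  x <- srs_reports(reports,
                   drugs = expand_versions(drugs_all)[, c("report_id", "raw_name",
                                                          "drug_id", "role",
                                                          "therapy_start",
                                                          "therapy_start_full",
                                                          "therapy_end")],
                   events = expand_versions(events_all)[, c("report_id", "pt_code")],
                   outcomes = expand_versions(outcomes_all)[, c("report_id", "outcome")],
                   database = "synthetic")
  x <- log_attrition(x, "generated", nrow(reports), nrow(reports))
  pns_codes <- config$pts$pt_code[config$pts$pns]
  truth <- list(
    config = config,
    n_cases = n,
    assignments = tibble(case_id = case_id, report_id = final_id,
                         drug_id = config$drugs$drug_id[gi],
                         drug_matched = !unmatched,
                         comed = comed_present, is_duplicate = is_dup,
                         reporter = reporter,
                         n_events = rowSums(M),
                         pns_case = rowSums(M[, config$pts$pns, drop = FALSE]) > 0),
    pns_pt_codes = pns_codes,
    expected = expected_cells(config)
  )
  list(reports = x, truth = truth, dictionary = dictionary)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("<synth_config> %d reports, %d drugs (%d study), %d PTs, ",
                     "%d injected signal(s), dup_rate=%.2f\n"),
              x$n_reports, nrow(x$drugs), sum(x$drugs$study), nrow(x$pts),
              nrow(x$signals), x$dup_rate))
  invisible(x)
}
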