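# Builders for small in-code fixtures.

# A minimal report set from compact tables; unspecified fields get benign
# defaults so tests only state what they are about.
mk_srs <- function(reports, drugs, events, outcomes = NULL, database = "faers") {
  n <- nrow(reports)
  col <- function(df, name) if (name %in% names(df)) df[[name]] else NULL
  def <- tibble::tibble(
    report_id = as.character(reports$report_id),
    case_id = as.character(col(reports, "case_id") %||% reports$report_id),
    receipt_date = as.Date(col(reports, "receipt_date") %||% rep("2022-06-01", n)),
    sex = col(reports, "sex") %||% rep("female", n),
    age_years = col(reports, "age_years") %||% rep(60, n),
    reporter = col(reports, "reporter") %||% rep("MD", n),
    country = col(reports, "country") %||% rep("US", n),
    event_date = as.Date(col(reports, "event_date") %||% rep(NA, n)),
    event_date_full = col(reports, "event_date_full") %||% rep(NA, n),
    valid = col(reports, "valid") %||% rep(TRUE, n)
  )
  def$age_group <- age_group(def$age_years)
  start <- as.Date(col(drugs, "therapy_start") %||% rep(NA, nrow(drugs)))
  drugs <- tibble::tibble(
    report_id = as.character(drugs$report_id),
    raw_name = col(drugs, "raw_name") %||% toupper(drugs$drug_id),
    drug_id = drugs$drug_id,
    role = col(drugs, "role") %||% rep("primary_suspect", nrow(drugs)),
    therapy_start = start,
    therapy_start_full = col(drugs, "therapy_start_full") %||% !is.na(start),
    therapy_end = as.Date(rep(NA, nrow(drugs)))
  )
  events <- tibble::tibble(report_id = as.character(events$report_id),
                           pt_code = as.character(events$pt_code))
  outcomes <- outcomes %||% tibble::tibble(report_id = character(),
                                           outcome = character())
  srs_reports(def, drugs, events, outcomes, database = database)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Null-everywhere cohort used for calibration-style checks.
null_synth_config <- function(n_reports = 50000, n_drugs = 40, n_pts = 30) {
  synth_config(
    n_reports = n_reports,
    drugs = tibble::tibble(drug_id = sprintf("drug_%02d", seq_len(n_drugs)),
                           prob = 1 / n_drugs,
                           study = seq_len(n_drugs) <= 5),
    pts = tibble::tibble(pt_code = sprintf("PT%03d", seq_len(n_pts)),
                         pt_name = sprintf("PT%03d", seq_len(n_pts)),
                         base_prob = 0.07,
                         pns = seq_len(n_pts) <= 8),
    missing = list(drug_match = 0), dup_rate = 0,
    reporter_probs = c(MD = 1))
}

# One study drug against a small background; used by the sensitivity and
# coverage scenarios.
small_synth_config <- function(n_reports = 30000, signals = NULL, comed = NULL) {
  synth_config(
    n_reports = n_reports,
    drugs = tibble::tibble(drug_id = c("adc_x", sprintf("bg_%d", 1:9)),
                           prob = 0.1, study = c(TRUE, rep(FALSE, 9))),
    pts = tibble::tibble(pt_code = sprintf("PT%02d", 1:12),
                         pt_name = sprintf("PT%02d", 1:12),
                         base_prob = c(0.01, 0.008, rep(0.12, 10)),
                         pns = c(TRUE, TRUE, rep(FALSE, 10))),
    signals = signals, comed = comed,
    missing = list(drug_match = 0), dup_rate = 0,
    reporter_probs = c(MD = 1))
}

# Generate, deduplicate and filter in one step.
prepare_cohort <- function(config, seed, study_drugs) {
  g <- generate_srs(config, seed = seed)
  x <- deduplicate(g$reports)
  list(x = apply_inclusion_filters(x, study_drugs), truth = g$truth,
       dictionary = g$dictionary)
}

# Brute-force deduplication oracle: group by key, keep the latest receipt
# date, break ties on the lexicographically largest report id.
dedup_oracle_ids <- function(reports, key_field = "case_id") {
  keys <- split(seq_len(nrow(reports)), reports[[key_field]])
  vapply(keys, function(idx) {
    r <- reports[idx, ]
    r <- r[r$receipt_date == max(r$receipt_date), ]
    max(r$report_id)
  }, character(1))
}

subset_reports_empty <- function(x) {
  srs_reports(x$reports[0, ], x$drugs[0, ], x$events[0, ], x$outcomes[0, ],
              database = srs_database(x))
}

write_pt_fixture <- function(path, n = 5, codes = sprintf("PT%04d", seq_len(n))) {
  readr::write_csv(tibble::tibble(pt_code = codes,
                                  pt_name = paste("Term", codes),
                                  provenance = rep_len(c("smq", "curated"),
                                                       length(codes))),
                   path)
  path
}
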