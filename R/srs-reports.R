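#' @importFrom dplyr %>% filter mutate select arrange group_by summarise ungroup
#'   left_join inner_join anti_join semi_join distinct n bind_rows rename across
#'   slice_max pull count first
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @importFrom stats rbinom rpois rlnorm runif rnorm rgamma quantile median
#'   qgamma pgamma dnbinom rnbinom optim uniroot setNames qnorm chisq.test
#'   digamma ecdf
#' @importFrom utils head
NULL

SEX_LEVELS      <- c("male", "female", "unknown")
REPORTER_LEVELS <- c("MD", "PH", "HP", "consumer", "unknown")
ROLE_LEVELS     <- c("primary_suspect", "secondary_suspect", "concomitant",
                     "interacting", "unknown")
OUTCOME_LEVELS  <- c("death", "life_threatening", "hospitalization", "disability",
                     "congenital_anomaly", "required_intervention", "other_serious",
                     "unknown")
AGE_GROUP_LEVELS <- c("<2", "2-11", "12-17", "18-64", "65-85", ">85", "unknown")

#' Construct a spontaneous-report set
#'
#' The central container of the package: a relational representation of a set
#' of individual case safety reports (ICSRs). Rather than one nested record
#' per report, the set holds four flat tables sharing the `report_id` key,
#' which keeps every downstream operation (deduplication, filtering, 2x2
#' counting) a vectorised join.
#'
#' @param reports One row per report version: `report_id` (unique), `case_id`,
#'   `receipt_date` (`Date`), `sex`, `age_years`, `age_group`, `reporter`,
#'   `country`, `event_date`, `event_date_full` (logical: full day precision),
#'   `valid` (logical: has at least one drug and one event).
#' @param drugs One row per drug mention: `report_id`, `raw_name`, `drug_id`
#'   (`NA` when the dictionary has no match), `role`, `therapy_start`,
#'   `therapy_start_full`, `therapy_end`.
#' @param events One row per (report, PT) pair: `report_id`, `pt_code`.
#' @param outcomes One row per (report, outcome category): `report_id`,
#'   `outcome`. At most one row per category within a report.
#' @param database Label for the source database (e.g. `"faers"`).
#' @param attrition Optional attrition log carried from earlier stages.
#' @return An object of class `srs_reports`.
#' @export
srs_reports <- function(reports, drugs, events, outcomes,
                        database = "unknown", attrition = NULL) {
  reports <- as_tibble(reports)
  drugs   <- as_tibble(drugs)
  events  <- as_tibble(events)
  outcomes <- as_tibble(outcomes)
  stopifnot(!anyDuplicated(reports$report_id))
  bad_sex <- setdiff(unique(reports$sex), SEX_LEVELS)
  if (length(bad_sex)) stop("invalid sex values: ", paste(bad_sex, collapse = ", "))
  bad_rep <- setdiff(unique(reports$reporter), REPORTER_LEVELS)
  if (length(bad_rep)) stop("invalid reporter values: ", paste(bad_rep, collapse = ", "))
  bad_role <- setdiff(unique(drugs$role), ROLE_LEVELS)
  if (length(bad_role)) stop("invalid drug roles: ", paste(bad_role, collapse = ", "))
  bad_out <- setdiff(unique(outcomes$outcome), OUTCOME_LEVELS)
  if (length(bad_out)) stop("invalid outcome categories: ", paste(bad_out, collapse = ", "))
  if (anyDuplicated(outcomes[, c("report_id", "outcome")]))
    stop("more than one outcome entry per category within a report")
  x <- structure(
    list(reports = reports, drugs = drugs, events = events, outcomes = outcomes),
    database = database,
    attrition = attrition %||% empty_attrition(),
    class = "srs_reports"
  )
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_attrition <- function() {
  tibble(stage = character(), n_in = integer(), n_out = integer(),
         n_removed = integer())
}

log_attrition <- function(x, stage, n_in, n_out) {
  attr(x, "attrition") <- bind_rows(
    attr(x, "attrition"),
    tibble(stage = stage, n_in = as.integer(n_in), n_out = as.integer(n_out),
           n_removed = as.integer(n_in - n_out))
  )
  x
}

#' Attrition log of a report set
#'
#' Stage-by-stage record counts: every filtering stage appends one row with
#' the number of reports going in, coming out, and removed, so the total
#' removed across stages reconciles exactly with input minus output.
#'
#' @param x An `srs_reports` object.
#' @return A tibble with columns `stage`, `n_in`, `n_out`, `n_removed`.
#' @export
attrition_log <- function(x) {
  stopifnot(inherits(x, "srs_reports"))
  attr(x, "attrition")
}

#' Database label of a report set
#' @param x An `srs_reports` object.
#' @return Character scalar.
#' @export
srs_database <- function(x) attr(x, "database")

#' Number of report versions in a set
#' @param x An `srs_reports` object.
#' @return Integer count of rows in the report table.
#' @export
n_reports <- function(x) nrow(x$reports)

#' @export
print.srs_reports <- function(x, ...) {
  cat(sprintf("<srs_reports> %s: %d report(s), %d drug mention(s), %d event(s)\n",
              srs_database(x), nrow(x$reports), nrow(x$drugs), nrow(x$events)))
  if (nrow(attrition_log(x)))
    cat("  stages:", paste(attrition_log(x)$stage, collapse = " -> "), "\n")
  invisible(x)
}

# Restrict all four tables to a set of report ids, preserving attributes.
subset_reports <- function(x, keep_ids) {
  srs_reports(
    reports  = x$reports[x$reports$report_id %in% keep_ids, ],
    drugs    = x$drugs[x$drugs$report_id %in% keep_ids, ],
    events   = x$events[x$events$report_id %in% keep_ids, ],
    outcomes = x$outcomes[x$outcomes$report_id %in% keep_ids, ],
    database = srs_database(x),
    attrition = attrition_log(x)
  )
}

#' Parse spontaneous-report date fields
#'
#' Accepts the precisions found in public FAERS extracts: `YYYYMMDD`,
#' `YYYY-MM-DD`, `YYYYMM` (imputed to the 15th) and `YYYY` (imputed to July
#' 1). Partial dates are flagged so that time-to-onset, which requires full
#' day precision, can exclude them while annual trends can still use the
#' year.
#'
#' @param x Character vector of date strings (empty string or `NA` = missing).
#' @return A list with `date` (`Date`, imputed) and `full` (logical, `TRUE`
#'   only for day-precision input; `NA` where missing).
#' @export
parse_srs_date <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA")] <- NA_character_
  digits <- gsub("-", "", x)
  out_date <- rep(as.Date(NA), length(x))
  full <- rep(NA, length(x))
  ok8 <- !is.na(digits) & grepl("^[0-9]{8}$", digits)
  out_date[ok8] <- as.Date(digits[ok8], format = "%Y%m%d")
  full[ok8] <- TRUE
  ok6 <- !is.na(digits) & grepl("^[0-9]{6}$", digits)
  out_date[ok6] <- as.Date(paste0(digits[ok6], "15"), format = "%Y%m%d")
  full[ok6] <- FALSE
  ok4 <- !is.na(digits) & grepl("^[0-9]{4}$", digits)
  out_date[ok4] <- as.Date(paste0(digits[ok4], "0701"), format = "%Y%m%d")
  full[ok4] <- FALSE
  # unparseable non-missing input counts as missing but is not an error
  list(date = out_date, full = full)
}

format_srs_date <- function(date, full) {
  out <- rep(NA_character_, length(date))
  has <- !is.na(date)
  out[has & full %in% TRUE] <- format(date[has & full %in% TRUE], "%Y%m%d")
  out[has & full %in% FALSE] <- format(date[has & full %in% FALSE], "%Y%m")
  out
}

#' Convert reported age to years
#'
#' FAERS codes age with a unit (`YR`, `MON`, `WK`, `DY`, `DEC`); flat extracts
#' report years directly. Unknown units yield `NA`.
#'
#' @param age Numeric vector of reported ages.
#' @param unit Character vector of unit codes (recycled if length one).
#' @return Numeric vector of ages in years.
#' @export
age_to_years <- function(age, unit = "YR") {
  age <- suppressWarnings(as.numeric(age))
  unit <- toupper(trimws(rep_len(as.character(unit), length(age))))
  unit[unit == "" | is.na(unit)] <- "YR"
  mult <- c(YR = 1, MON = 1 / 12, WK = 7 / 365.25, DY = 1 / 365.25, DEC = 10,
            HR = 1 / (24 * 365.25))
  out <- age * unname(mult[unit])
  out[!is.na(out) & (out < 0 | out > 120)] <- NA_real_
  out
}

#' Assign age groups
#'
#' Bins in years, closed on the left: `<2`, `2-11`, `12-17`, `18-64`, `65-85`,
#' `>85`; missing age maps to `"unknown"`.
#'
#' @param age_years Numeric vector of ages in years.
#' @return Character vector of age-group labels.
#' @export
age_group <- function(age_years) {
  out <- rep("unknown", length(age_years))
  has <- !is.na(age_years)
  a <- age_years[has]
  out[has] <- ifelse(a < 2, "<2",
              ifelse(a < 12, "2-11",
              ifelse(a < 18, "12-17",
              ifelse(a < 65, "18-64",
              ifelse(a <= 85, "65-85", ">85")))))
  out
}

#' Normalize a drug name for dictionary lookup
#'
#' Lowercases, trims, and strips all non-alphanumeric characters. Matching
#' downstream is exact on this normal form; no fuzzy matching is attempted
#' (reproducibility over recall).
#'
#' @param x Character vector of raw drug names.
#' @return Character vector of normal forms.
#' @export
normalize_drug_name <- function(x) {
  gsub("[^a-z0-9]", "", tolower(trimws(as.character(x))))
}

#' Read a drug dictionary
#'
#' @param path CSV with columns `name` (brand/generic synonym) and `drug_id`.
#' @return Named character vector mapping normalized synonym to `drug_id`.
#' @export
read_drug_dictionary <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("name", "drug_id") %in% names(d)))
  key <- normalize_drug_name(d$name)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    conf <- vapply(dup, function(k) length(unique(d$drug_id[key == k])) > 1, logical(1))
    if (any(conf)) stop("conflicting dictionary entries for: ",
                        paste(dup[conf], collapse = ", "))
  }
  setNames(d$drug_id, key)[!duplicated(key)]
}
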