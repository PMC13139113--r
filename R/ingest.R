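FAERS_MANDATORY <- c("DEMO", "DRUG", "REAC")

FAERS_COLS <- list(
  DEMO = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age", "age_cod",
           "occp_cod", "reporter_country"),
  DRUG = c("primaryid", "drug_seq", "drugname", "role_cod"),
  REAC = c("primaryid", "pt"),
  OUTC = c("primaryid", "outc_cod"),
  THER = c("primaryid", "drug_seq", "start_dt", "end_dt")
)

FLAT_COLS <- c("report_id", "receipt_date", "sex", "age", "reporter", "country",
               "drugname", "role", "start_date", "end_date", "event_date",
               "outcomes", "pt")

OUTC_CODE_MAP <- c(DE = "death", LT = "life_threatening", HO = "hospitalization",
                   DS = "disability", CA = "congenital_anomaly",
                   RI = "required_intervention", OT = "other_serious",
                   UN = "unknown")

ROLE_CODE_MAP <- c(PS = "primary_suspect", SS = "secondary_suspect",
                   C = "concomitant", I = "interacting")

#' Read a raw spontaneous-report bundle
#'
#' Reads one database extract into memory without interpretation. Two dialects
#' are supported: `"faers"`, a set of `$`-delimited relational tables (DEMO,
#' DRUG, REAC plus optional OUTC, THER) as in the public FAERS ASCII release,
#' and `"jader"`/`"cvard"`, a single flat CSV with one row per
#' (report, drug, event) combination carrying the same semantic columns
#' (`report_id`, `receipt_date`, `sex`, `age`, `reporter`, `country`,
#' `drugname`, `role`, `start_date`, `end_date`, `event_date`, `outcomes`,
#' `pt`).
#'
#' Unknown columns are dropped with a warning; a missing mandatory table is
#' fatal. Rows that fail to parse are counted and reported via a message, not
#' silently dropped.
#'
#' @param paths For `"faers"`: a named list/vector of file paths keyed by
#'   table name. For the flat dialects: a single file path.
#' @param dialect `"faers"`, `"jader"` or `"cvard"`.
#' @param extract_id Free-text identifier of the quarter or extract.
#' @return A `raw_bundle` object: list with `dialect`, `tables` (named list of
#'   tibbles) and `extract_id`.
#' @export
read_bundle <- function(paths, dialect = c("faers", "jader", "cvard"),
                        extract_id = "extract") {
  dialect <- match.arg(dialect)
  if (dialect == "faers") {
    paths <- as.list(paths)
    missing_tab <- setdiff(FAERS_MANDATORY, names(paths))
    if (length(missing_tab))
      stop("mandatory table absent: ", paste(missing_tab, collapse = ", "))
    tables <- lapply(names(paths), function(tab) {
      d <- readr::read_delim(paths[[tab]], delim = "$", show_col_types = FALSE,
                             progress = FALSE, col_types = readr::cols(.default = "c"))
      n_bad <- nrow(readr::problems(d))
      if (n_bad > 0)
        message(sprintf("%s: %d malformed row(s) noted while reading", tab, n_bad))
      keep <- intersect(names(d), FAERS_COLS[[tab]] %||% names(d))
      extra <- setdiff(names(d), keep)
      if (length(extra) && tab %in% names(FAERS_COLS)) {
        warning(sprintf("%s: ignoring unknown column(s): %s", tab,
                        paste(extra, collapse = ", ")))
        d <- d[, keep]
      }
      d
    })
    names(tables) <- names(paths)
  } else {
    stopifnot(length(paths) == 1)
    d <- readr::read_csv(paths[[1]], show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
    n_bad <- nrow(readr::problems(d))
    if (n_bad > 0)
      message(sprintf("flat extract: %d malformed row(s) noted while reading", n_bad))
    extra <- setdiff(names(d), FLAT_COLS)
    if (length(extra)) {
      warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
      d <- d[, intersect(names(d), FLAT_COLS)]
    }
    missing_col <- setdiff(c("report_id", "drugname", "pt"), names(d))
    if (length(missing_col))
      stop("mandatory column absent: ", paste(missing_col, collapse = ", "))
    tables <- list(MAIN = d)
  }
  structure(list(dialect = dialect, tables = tables, extract_id = extract_id),
            class = "raw_bundle")
}

#' @export
print.raw_bundle <- function(x, ...) {
  cat(sprintf("<raw_bundle> dialect=%s extract=%s tables: %s\n", x$dialect,
              x$extract_id,
              paste(sprintf("%s[%d]", names(x$tables),
                            vapply(x$tables, nrow, integer(1))), collapse = " ")))
  invisible(x)
}

map_reporter <- function(code) {
  code <- toupper(trimws(as.character(code)))
  out <- rep("unknown", length(code))
  out[code %in% c("MD")] <- "MD"
  out[code %in% c("PH")] <- "PH"
  out[code %in% c("HP", "OT")] <- "HP"
  out[code %in% c("CN", "CONSUMER")] <- "consumer"
  out[code %in% c("CONSUMER")] <- "consumer"
  out[code %in% REPORTER_LEVELS] <- code[code %in% REPORTER_LEVELS]
  out
}

map_sex <- function(code) {
  code <- toupper(trimws(as.character(code)))
  out <- rep("unknown", length(code))
  out[code %in% c("M", "MALE")] <- "male"
  out[code %in% c("F", "FEMALE")] <- "female"
  out
}

map_outcomes <- function(code) {
  code <- toupper(trimws(as.character(code)))
  out <- unname(OUTC_CODE_MAP[code])
  low <- tolower(code)
  out[is.na(out) & low %in% OUTCOME_LEVELS] <- low[is.na(out) & low %in% OUTCOME_LEVELS]
  out
}

map_role <- function(code) {
  code <- trimws(as.character(code))
  out <- unname(ROLE_CODE_MAP[toupper(code)])
  low <- tolower(code)
  out[is.na(out) & low %in% ROLE_LEVELS] <- low[is.na(out) & low %in% ROLE_LEVELS]
  out[is.na(out)] <- "unknown"
  out
}

#' Assemble a raw bundle into the common report schema
#'
#' Joins the dialect tables into an [srs_reports()] set: one report row per
#' raw report version, drug names normalized and matched case-insensitively
#' (after trimming and punctuation stripping) against the dictionary, event
#' PTs and outcome categories mapped to the common vocabulary. Reports with
#' no drug mention or no coded event are kept but flagged `valid = FALSE`;
#' the inclusion-filter stage removes them with an attrition entry.
#'
#' @param bundle A `raw_bundle` from [read_bundle()].
#' @param drug_dict Named vector from [read_drug_dictionary()] (normalized
#'   synonym -> drug id). Unmatched names get `drug_id = NA`.
#' @return An `srs_reports` object (report versions, not yet deduplicated).
#' @export
assemble_reports <- function(bundle, drug_dict) {
  stopifnot(inherits(bundle, "raw_bundle"))
  if (bundle$dialect == "faers") {
    demo <- bundle$tables$DEMO
    fda <- parse_srs_date(demo$fda_dt)
    evd <- parse_srs_date(demo$event_dt %||% rep(NA_character_, nrow(demo)))
    reports <- tibble(
      report_id = as.character(demo$primaryid),
      case_id = as.character(demo$caseid),
      receipt_date = fda$date,
      sex = map_sex(demo$sex),
      age_years = age_to_years(demo$age, demo$age_cod %||% "YR"),
      reporter = map_reporter(demo$occp_cod %||% ""),
      country = dplyr::na_if(trimws(as.character(demo$reporter_country %||% NA)), ""),
      event_date = evd$date,
      event_date_full = evd$full
    )
    drug_tab <- bundle$tables$DRUG
    ther <- bundle$tables$THER
    drugs <- tibble(
      report_id = as.character(drug_tab$primaryid),
      drug_seq = as.character(drug_tab$drug_seq %||% seq_len(nrow(drug_tab))),
      raw_name = as.character(drug_tab$drugname),
      role = map_role(drug_tab$role_cod)
    )
    if (!is.null(ther)) {
      st <- parse_srs_date(ther$start_dt)
      en <- parse_srs_date(ther$end_dt %||% rep(NA_character_, nrow(ther)))
      ther_tab <- tibble(report_id = as.character(ther$primaryid),
                         drug_seq = as.character(ther$drug_seq),
                         therapy_start = st$date, therapy_start_full = st$full,
                         therapy_end = en$date)
      drugs <- left_join(drugs, ther_tab, by = c("report_id", "drug_seq"))
    } else {
      drugs$therapy_start <- as.Date(NA)
      drugs$therapy_start_full <- NA
      drugs$therapy_end <- as.Date(NA)
    }
    drugs$drug_seq <- NULL
    events <- tibble(report_id = as.character(bundle$tables$REAC$primaryid),
                     pt_code = as.character(bundle$tables$REAC$pt))
    outc <- bundle$tables$OUTC
    outcomes <- if (is.null(outc) || nrow(outc) == 0) {
      tibble(report_id = character(), outcome = character())
    } else {
      tibble(report_id = as.character(outc$primaryid),
             outcome = map_outcomes(outc$outc_cod))
    }
  } else {
    m <- bundle$tables$MAIN
    getc <- function(col) if (col %in% names(m)) m[[col]] else rep(NA_character_, nrow(m))
    rec <- parse_srs_date(getc("receipt_date"))
    evd <- parse_srs_date(getc("event_date"))
    per_report <- !duplicated(m$report_id)
    reports <- tibble(
      report_id = as.character(m$report_id[per_report]),
      case_id = as.character(m$report_id[per_report]),
      receipt_date = rec$date[per_report],
      sex = map_sex(getc("sex")[per_report]),
      age_years = age_to_years(getc("age")[per_report], "YR"),
      reporter = map_reporter(getc("reporter")[per_report]),
      country = dplyr::na_if(trimws(as.character(getc("country")[per_report])), ""),
      event_date = evd$date[per_report],
      event_date_full = evd$full[per_report]
    )
    st <- parse_srs_date(getc("start_date"))
    en <- parse_srs_date(getc("end_date"))
    drugs <- tibble(
      report_id = as.character(m$report_id),
      raw_name = as.character(m$drugname),
      role = map_role(getc("role")),
      therapy_start = st$date, therapy_start_full = st$full,
      therapy_end = en$date
    ) %>% distinct()
    drugs <- drugs[!is.na(drugs$raw_name) & drugs$raw_name != "", ]
    events <- tibble(report_id = as.character(m$report_id),
                     pt_code = as.character(m$pt)) %>% distinct()
    events <- events[!is.na(events$pt_code) & events$pt_code != "", ]
    oc <- tibble(report_id = as.character(m$report_id), raw = getc("outcomes")) %>%
      distinct() %>% filter(!is.na(.data$raw), .data$raw != "")
    outcomes <- if (nrow(oc)) {
      tidyr::separate_rows(oc, "raw", sep = ";") %>%
        mutate(outcome = map_outcomes(trimws(.data$raw))) %>%
        filter(!is.na(.data$outcome)) %>%
        distinct(.data$report_id, .data$outcome)
    } else tibble(report_id = character(), outcome = character())
  }
  drugs <- drugs[!is.na(drugs$raw_name) & trimws(drugs$raw_name) != "", ]
  events <- events[!is.na(events$pt_code) & trimws(events$pt_code) != "", ]
  outcomes <- outcomes[!is.na(outcomes$outcome), ]
  outcomes <- distinct(outcomes)
  drugs$drug_id <- unname(drug_dict[normalize_drug_name(drugs$raw_name)])
  drugs <- drugs[, c("report_id", "raw_name", "drug_id", "role",
                     "therapy_start", "therapy_start_full", "therapy_end")]
  reports$age_group <- age_group(reports$age_years)
  reports$valid <- reports$report_id %in% drugs$report_id &
    reports$report_id %in% events$report_id
  reports <- reports[, c("report_id", "case_id", "receipt_date", "sex",
                         "age_years", "age_group", "reporter", "country",
                         "event_date", "event_date_full", "valid")]
  x <- srs_reports(reports, drugs, events, outcomes, database = bundle$dialect)
  log_attrition(x, "assembled", nrow(reports), nrow(reports))
}

#' Deduplication policy for a database dialect
#'
#' FAERS reports arrive as successive versions of a case: versions share
#' `caseid` and the latest `fda_dt` supersedes earlier ones. JADER- and
#' CVARD-style extracts already carry unique report identifiers, so the key
#' is the report id itself.
#'
#' @param dialect `"faers"`, `"jader"` or `"cvard"`.
#' @return A `dedup_policy` list with `key_field` and `keep_rule`.
#' @export
dedup_policy <- function(dialect = c("faers", "jader", "cvard")) {
  dialect <- match.arg(dialect)
  structure(list(
    dialect = dialect,
    key_field = if (dialect == "faers") "case_id" else "report_id",
    keep_rule = "latest_receipt_date"
  ), class = "dedup_policy")
}

#' Deduplicate report versions
#'
#' One record is retained per key (case id for FAERS, report id otherwise):
#' the version with the latest receipt date; receipt-date ties are broken
#' deterministically by keeping the lexicographically largest report id.
#' Report or case ids listed in `deleted_ids` (the DELETED-file mechanism)
#' are removed first. The operation is idempotent.
#'
#' @param x An `srs_reports` object.
#' @param policy A [dedup_policy()]; defaults to the policy of the set's
#'   database dialect.
#' @param deleted_ids Optional character vector of report/case ids to drop.
#' @return A deduplicated `srs_reports` object with attrition entries
#'   `"deleted_list"` and `"deduplicate"`.
#' @export
deduplicate <- function(x, policy = NULL, deleted_ids = character()) {
  stopifnot(inherits(x, "srs_reports"))
  if (is.null(policy)) {
    dial <- srs_database(x)
    policy <- dedup_policy(if (dial %in% c("faers", "jader", "cvard")) dial else "faers")
  }
  n0 <- nrow(x$reports)
  keep <- !(x$reports$report_id %in% deleted_ids |
              x$reports$case_id %in% deleted_ids)
  x1 <- subset_reports(x, x$reports$report_id[keep])
  x1 <- log_attrition(x1, "deleted_list", n0, nrow(x1$reports))
  key <- x1$reports[[policy$key_field]]
  ord <- order(key,
               x1$reports$receipt_date, x1$reports$report_id,
               decreasing = c(FALSE, TRUE, TRUE), method = "radix")
  winners <- x1$reports$report_id[ord][!duplicated(key[ord])]
  x2 <- subset_reports(x1, winners)
  log_attrition(x2, "deduplicate", nrow(x1$reports), nrow(x2$reports))
}

#' Apply the study inclusion filters
#'
#' Reproduces the restriction of the analysis cohort: records flagged invalid
#' at assembly (no drug or no event) are excluded, then reports whose
#' reporter is not a healthcare professional (MD, PH or HP) are excluded from
#' BOTH the exposed and the comparator set (symmetric design). An `exposed`
#' column is added: `TRUE` iff some drug mention has role `primary_suspect`
#' and a dictionary-matched id in `study_drugs`.
#'
#' @param x A deduplicated `srs_reports` object.
#' @param study_drugs Character vector of study drug ids.
#' @return Filtered `srs_reports`; `x$reports` gains the `exposed` column.
#' @export
apply_inclusion_filters <- function(x, study_drugs) {
  stopifnot(inherits(x, "srs_reports"))
  n0 <- nrow(x$reports)
  x1 <- subset_reports(x, x$reports$report_id[x$reports$valid])
  x1 <- log_attrition(x1, "invalid_records", n0, nrow(x1$reports))
  hcp <- x1$reports$reporter %in% c("MD", "PH", "HP")
  x2 <- subset_reports(x1, x1$reports$report_id[hcp])
  x2 <- log_attrition(x2, "non_hcp_reporter", nrow(x1$reports), nrow(x2$reports))
  ps <- x2$drugs[x2$drugs$role == "primary_suspect" &
                   !is.na(x2$drugs$drug_id) &
                   x2$drugs$drug_id %in% study_drugs, ]
  x2$reports$exposed <- x2$reports$report_id %in% ps$report_id
  x2
}

#' Serialize a report set into a raw dialect bundle
#'
#' The inverse of [read_bundle()] + [assemble_reports()]: writes the set out
#' in one of the three dialects so that synthetic data can exercise the whole
#' ingestion path. Partial dates are written at their stored precision
#' (`YYYYMMDD` or `YYYYMM`), so a write/read/assemble round trip preserves
#' date value and precision.
#'
#' @param x An `srs_reports` object.
#' @param dialect Target dialect.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written (usable as the
#'   `paths` argument of [read_bundle()]).
#' @export
write_bundle <- function(x, dialect = c("faers", "jader", "cvard"), dir) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "srs_reports"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rev_out <- setNames(names(OUTC_CODE_MAP), OUTC_CODE_MAP)
  rev_role <- setNames(names(ROLE_CODE_MAP), ROLE_CODE_MAP)
  if (dialect == "faers") {
    demo <- tibble(
      primaryid = x$reports$report_id,
      caseid = x$reports$case_id,
      fda_dt = format(x$reports$receipt_date, "%Y%m%d"),
      event_dt = format_srs_date(x$reports$event_date, x$reports$event_date_full),
      sex = c(male = "M", female = "F", unknown = "")[x$reports$sex],
      age = ifelse(is.na(x$reports$age_years), "",
                   formatC(x$reports$age_years, format = "fg", digits = 10)),
      age_cod = ifelse(is.na(x$reports$age_years), "", "YR"),
      occp_cod = c(MD = "MD", PH = "PH", HP = "HP", consumer = "CN",
                   unknown = "")[x$reports$reporter],
      reporter_country = ifelse(is.na(x$reports$country), "", x$reports$country)
    )
    dr <- x$drugs %>% group_by(.data$report_id) %>%
      mutate(drug_seq = as.character(dplyr::row_number())) %>% ungroup()
    drug <- tibble(primaryid = dr$report_id, drug_seq = dr$drug_seq,
                   drugname = dr$raw_name,
                   role_cod = ifelse(dr$role == "unknown", "",
                                     unname(rev_role[dr$role])))
    ther <- tibble(primaryid = dr$report_id, drug_seq = dr$drug_seq,
                   start_dt = format_srs_date(dr$therapy_start, dr$therapy_start_full),
                   end_dt = ifelse(is.na(dr$therapy_end), "",
                                   format(dr$therapy_end, "%Y%m%d")))
    ther <- ther[!is.na(ther$start_dt) | ther$end_dt != "", ]
    ther$start_dt[is.na(ther$start_dt)] <- ""
    reac <- tibble(primaryid = x$events$report_id, pt = x$events$pt_code)
    outc <- tibble(primaryid = x$outcomes$report_id,
                   outc_cod = unname(rev_out[x$outcomes$outcome]))
    paths <- c(DEMO = file.path(dir, "demo.txt"), DRUG = file.path(dir, "drug.txt"),
               REAC = file.path(dir, "reac.txt"), OUTC = file.path(dir, "outc.txt"),
               THER = file.path(dir, "ther.txt"))
    wr <- function(d, p) {
      d[is.na(d)] <- ""
      readr::write_delim(d, p, delim = "$", na = "")
    }
    wr(demo, paths["DEMO"]); wr(drug, paths["DRUG"]); wr(reac, paths["REAC"])
    wr(outc, paths["OUTC"]); wr(ther, paths["THER"])
    invisible(paths)
  } else {
    oc <- x$outcomes %>% group_by(.data$report_id) %>%
      summarise(outcomes = paste(sort(.data$outcome), collapse = ";"))
    base <- x$reports %>%
      left_join(oc, by = "report_id") %>%
      mutate(receipt = format(.data$receipt_date, "%Y%m%d"),
             event = format_srs_date(.data$event_date, .data$event_date_full),
             sexc = c(male = "M", female = "F", unknown = "")[.data$sex],
             agec = ifelse(is.na(.data$age_years), "",
                           formatC(.data$age_years, format = "fg", digits = 10)))
    dr <- x$drugs %>%
      mutate(start = format_srs_date(.data$therapy_start, .data$therapy_start_full),
             end = ifelse(is.na(.data$therapy_end), "",
                          format(.data$therapy_end, "%Y%m%d")),
             rolec = ifelse(.data$role == "unknown", "", unname(rev_role[.data$role])))
    flat <- inner_join(
      dr[, c("report_id", "raw_name", "rolec", "start", "end")],
      x$events, by = "report_id", relationship = "many-to-many"
    ) %>%
      left_join(base[, c("report_id", "receipt", "sexc", "agec", "reporter",
                         "country", "event", "outcomes")], by = "report_id")
    out <- tibble(
      report_id = flat$report_id, receipt_date = flat$receipt, sex = flat$sexc,
      age = flat$agec,
      reporter = ifelse(flat$reporter == "unknown", "", flat$reporter),
      country = ifelse(is.na(flat$country), "", flat$country),
      drugname = flat$raw_name, role = flat$rolec,
      start_date = ifelse(is.na(flat$start), "", flat$start),
      end_date = flat$end,
      event_date = ifelse(is.na(flat$event), "", flat$event),
      outcomes = ifelse(is.na(flat$outcomes), "", flat$outcomes),
      pt = flat$pt_code
    )
    p <- file.path(dir, paste0(dialect, ".csv"))
    readr::write_csv(out, p, na = "")
    invisible(c(MAIN = p))
  }
}
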