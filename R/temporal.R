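#' Time-to-onset of classified cases
#'
#' Onset is the day difference between the event date and the earliest
#' therapy-start date of the index drug's primary-suspect mention. A record
#' is evaluable only when both dates carry full day precision and the delta
#' is non-negative; non-evaluable records are excluded from the summaries
#' but counted. Same-day onset counts as 0 days.
#'
#' @param x An `srs_reports` object.
#' @param drug_id Index drug id (primary-suspect role).
#' @param set A `pt_set` or character vector of PT codes defining the cases.
#' @return List: `records` (tibble `report_id`, `drug_id`, `onset_days`,
#'   `evaluable`), `summary` (n, n_evaluable, median, q1, q3), `ecdf`
#'   (integer-day grid with cumulative fraction).
#' @export
compute_tto <- function(x, drug_id, set) {
  if (inherits(set, "pt_set")) set <- set$pt_code
  case_ids <- unique(x$events$report_id[x$events$pt_code %in% set])
  ps <- x$drugs %>%
    filter(.data$role == "primary_suspect", !is.na(.data$drug_id),
           .data$drug_id == !!drug_id, .data$report_id %in% case_ids) %>%
    group_by(.data$report_id) %>%
    summarise(
      therapy_start = if (all(is.na(.data$therapy_start))) as.Date(NA)
                      else min(.data$therapy_start, na.rm = TRUE),
      start_full = {
        i <- which(!is.na(.data$therapy_start))
        if (!length(i)) NA
        else all(.data$therapy_start_full[i[.data$therapy_start[i] ==
                                              min(.data$therapy_start[i])]] %in% TRUE)
      })
  rec <- ps %>%
    left_join(select(x$reports, "report_id", "event_date", "event_date_full"),
              by = "report_id") %>%
    mutate(onset_days = as.integer(.data$event_date - .data$therapy_start),
           evaluable = !is.na(.data$onset_days) & .data$onset_days >= 0 &
             .data$start_full %in% TRUE & .data$event_date_full %in% TRUE,
           drug_id = !!drug_id) %>%
    select("report_id", "drug_id", "onset_days", "evaluable")
  ev <- rec$onset_days[rec$evaluable]
  if (length(ev) == 0) {
    warning("no evaluable time-to-onset record for ", drug_id)
    return(list(records = rec,
                summary = tibble(drug_id = drug_id, n = nrow(rec),
                                 n_evaluable = 0L, median = NA_real_,
                                 q1 = NA_real_, q3 = NA_real_),
                ecdf = tibble(day = integer(), cum_fraction = numeric())))
  }
  qs <- quantile(ev, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  grid <- 0:max(ev)
  fn <- ecdf(ev)
  list(records = rec,
       summary = tibble(drug_id = drug_id, n = nrow(rec),
                        n_evaluable = length(ev), median = qs[2],
                        q1 = qs[1], q3 = qs[3]),
       ecdf = tibble(day = grid, cum_fraction = fn(grid)))
}

#' Annual case counts by drug
#'
#' Stacked per-drug counts of classified cases by receipt year (receipt year
#' is the default basis; event year optional), plus the total line. Each
#' case contributes once to the total; a report with more than one study
#' drug as primary suspect contributes to each drug's series but is counted
#' once in the total. Empty years inside the observed span are reported as
#' 0, not missing.
#'
#' @param x An `srs_reports` object.
#' @param drug_ids Study drug ids.
#' @param set A `pt_set` or character vector of PT codes.
#' @param basis `"receipt"` (default) or `"event"` year.
#' @return List: `by_drug` (tibble `year`, `drug_id`, `n_cases`) and `total`
#'   (tibble `year`, `n_cases`).
#' @export
annual_trend <- function(x, drug_ids, set, basis = c("receipt", "event")) {
  basis <- match.arg(basis)
  if (inherits(set, "pt_set")) set <- set$pt_code
  case_ids <- unique(x$events$report_id[x$events$pt_code %in% set])
  dcol <- if (basis == "receipt") x$reports$receipt_date else x$reports$event_date
  yr <- tibble(report_id = x$reports$report_id,
               year = as.integer(format(dcol, "%Y")))
  ps <- x$drugs %>%
    filter(.data$role == "primary_suspect", !is.na(.data$drug_id),
           .data$drug_id %in% drug_ids, .data$report_id %in% case_ids) %>%
    distinct(.data$report_id, .data$drug_id) %>%
    left_join(yr, by = "report_id") %>%
    filter(!is.na(.data$year))
  if (nrow(ps) == 0)
    return(list(by_drug = tibble(year = integer(), drug_id = character(),
                                 n_cases = integer()),
                total = tibble(year = integer(), n_cases = integer())))
  years <- seq(min(ps$year), max(ps$year))
  by_drug <- tidyr::expand_grid(year = years, drug_id = drug_ids) %>%
    left_join(count(ps, .data$year, .data$drug_id, name = "n_cases"),
              by = c("year", "drug_id")) %>%
    mutate(n_cases = ifelse(is.na(.data$n_cases), 0L, .data$n_cases))
  total <- ps %>% distinct(.data$report_id, .data$year) %>%
    count(.data$year, name = "n_cases")
  total <- tibble(year = years) %>%
    left_join(total, by = "year") %>%
    mutate(n_cases = ifelse(is.na(.data$n_cases), 0L, .data$n_cases))
  list(by_drug = by_drug, total = total)
}

#' Seriousness outcomes per drug
#'
#' Counts and proportions of each seriousness category among the classified
#' cases of each drug, using that drug's case count as the denominator.
#' Drugs with fewer than `small_n` cases are flagged: with limited
#' denominators a single report moves the proportion substantially. Drugs
#' with zero cases are omitted with a warning.
#'
#' @param x An `srs_reports` object.
#' @param drug_ids Study drug ids.
#' @param set A `pt_set` or character vector of PT codes.
#' @param small_n Small-denominator flag threshold (default 20).
#' @return Tibble: `drug_id`, `outcome`, `n`, `denominator`, `proportion`
#'   (percent), `small_denominator`.
#' @export
summarize_seriousness <- function(x, drug_ids, set, small_n = 20) {
  if (inherits(set, "pt_set")) set <- set$pt_code
  case_ids <- unique(x$events$report_id[x$events$pt_code %in% set])
  ps <- x$drugs %>%
    filter(.data$role == "primary_suspect", !is.na(.data$drug_id),
           .data$drug_id %in% drug_ids, .data$report_id %in% case_ids) %>%
    distinct(.data$report_id, .data$drug_id)
  denom <- count(ps, .data$drug_id, name = "denominator")
  absent <- setdiff(drug_ids, denom$drug_id)
  if (length(absent))
    warning("no classified case for: ", paste(absent, collapse = ", "),
            "; omitted from the seriousness summary")
  oc <- inner_join(ps, x$outcomes, by = "report_id",
                   relationship = "many-to-many")
  tidyr::expand_grid(drug_id = denom$drug_id, outcome = OUTCOME_LEVELS) %>%
    left_join(count(oc, .data$drug_id, .data$outcome, name = "n"),
              by = c("drug_id", "outcome")) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) %>%
    left_join(denom, by = "drug_id") %>%
    mutate(proportion = 100 * .data$n / .data$denominator,
           small_denominator = .data$denominator < small_n)
}

#' Baseline-characteristics summary of classified cases
#'
#' Per-drug breakdowns of sex, age group and reporter type among classified
#' cases, with counts, percentages (one decimal) and a formatted
#' `"n (pct%)"` label. Unknown categories are explicit rows, so each block
#' sums to the drug's case count.
#'
#' @param x An `srs_reports` object.
#' @param drug_ids Study drug ids.
#' @param set A `pt_set` or character vector of PT codes.
#' @return Tibble: `drug_id`, `block` (sex/age_group/reporter), `category`,
#'   `n`, `denominator`, `pct`, `label`.
#' @export
summarize_demographics <- function(x, drug_ids, set) {
  if (inherits(set, "pt_set")) set <- set$pt_code
  case_ids <- unique(x$events$report_id[x$events$pt_code %in% set])
  ps <- x$drugs %>%
    filter(.data$role == "primary_suspect", !is.na(.data$drug_id),
           .data$drug_id %in% drug_ids, .data$report_id %in% case_ids) %>%
    distinct(.data$report_id, .data$drug_id) %>%
    left_join(select(x$reports, "report_id", "sex", "age_group", "reporter"),
              by = "report_id")
  blocks <- list(sex = SEX_LEVELS, age_group = AGE_GROUP_LEVELS,
                 reporter = REPORTER_LEVELS)
  denom <- count(ps, .data$drug_id, name = "denominator")
  out <- lapply(names(blocks), function(bl) {
    tidyr::expand_grid(drug_id = denom$drug_id, category = blocks[[bl]]) %>%
      left_join(ps %>% rename(category = dplyr::all_of(bl)) %>%
                  count(.data$drug_id, .data$category, name = "n"),
                by = c("drug_id", "category")) %>%
      mutate(n = ifelse(is.na(.data$n), 0L, .data$n), block = bl)
  })
  bind_rows(out) %>%
    left_join(denom, by = "drug_id") %>%
    mutate(pct = round(100 * .data$n / .data$denominator, 1),
           label = sprintf("%d (%.1f%%)", .data$n, .data$pct)) %>%
    select("drug_id", "block", "category", "n", "denominator", "pct", "label")
}
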