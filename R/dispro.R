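#' Build a case-noncase 2x2 contingency table
#'
#' Cross-classifies a deduplicated, filtered report set by exposure to an
#' index drug set (primary-suspect role only) and occurrence of an index PT
#' set. At `level = "report"` each report is counted once in exactly one
#' cell, so `a + b + c + d` equals the number of reports. At
#' `level = "pt_occurrence"` the unit is the (report, PT) pair: `a` counts
#' exposed co-occurrences (one report may contribute several PTs of the
#' set), `b` exposed pairs with other events, `c` index-PT pairs under other
#' drugs, and `d` the rest — the convention used for pooled class-level
#' tables.
#'
#' @param x An `srs_reports` object with the `exposed` column (from
#'   [apply_inclusion_filters()]) or `drug_ids` given.
#' @param drug_ids Index drug ids (primary suspect defines exposure). When
#'   `NULL`, the precomputed `exposed` flag is used.
#' @param pt_codes Character vector of index PT codes (or a `pt_set`).
#' @param level `"report"` or `"pt_occurrence"`.
#' @return A `contingency_table` object.
#' @export
build_table <- function(x, drug_ids = NULL, pt_codes, level = c("report", "pt_occurrence")) {
  level <- match.arg(level)
  stopifnot(inherits(x, "srs_reports"))
  if (nrow(x$reports) == 0) stop("zero reports: cannot build a contingency table")
  if (inherits(pt_codes, "pt_set")) pt_codes <- pt_codes$pt_code
  exposed_ids <- if (is.null(drug_ids)) {
    if (!"exposed" %in% names(x$reports))
      stop("no `exposed` flag: give drug_ids or run apply_inclusion_filters()")
    x$reports$report_id[x$reports$exposed]
  } else {
    unique(x$drugs$report_id[x$drugs$role == "primary_suspect" &
                               !is.na(x$drugs$drug_id) &
                               x$drugs$drug_id %in% drug_ids])
  }
  if (level == "report") {
    case_ids <- unique(x$events$report_id[x$events$pt_code %in% pt_codes])
    e <- x$reports$report_id %in% exposed_ids
    k <- x$reports$report_id %in% case_ids
    a <- sum(e & k); b <- sum(e & !k); c <- sum(!e & k); d <- sum(!e & !k)
  } else {
    ev <- distinct(x$events, .data$report_id, .data$pt_code)
    e <- ev$report_id %in% exposed_ids
    k <- ev$pt_code %in% pt_codes
    a <- sum(e & k); b <- sum(e & !k); c <- sum(!e & k); d <- sum(!e & !k)
  }
  contingency_table(a, b, c, d, level = level, database = srs_database(x))
}

#' Construct a contingency table from counts
#'
#' @param a,b,c,d Non-negative counts: index drug & index event(s); index
#'   drug & other events; other drugs & index event(s); other drugs & other
#'   events.
#' @param level Counting unit the cells refer to.
#' @param database Source database label.
#' @return A `contingency_table` object.
#' @export
contingency_table <- function(a, b, c, d, level = "report", database = "unknown") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0)) stop("cell counts must be non-negative")
  if (sum(counts) <= 0) stop("empty contingency table")
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d,
                 level = level, database = database),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s (%s level)\n", x$database, x$level))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("index drug", "other drugs"),
                              c("index event", "other events")))
  print(m)
  invisible(x)
}

unpack_table <- function(a, b, c, d) {
  if (inherits(a, "contingency_table")) list(a = a$a, b = a$b, c = a$c, d = a$d)
  else list(a = a, b = b, c = c, d = d)
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = (a d)/(b c)`; the two-sided interval is
#' `exp(log ROR -/+ z * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is zero
#' the Haldane-Anscombe correction (+0.5 to all four cells) is applied and
#' flagged. Vectorised over cells.
#'
#' @param a A `contingency_table`, or the `a` cell count(s).
#' @param b,c,d Remaining cell counts when `a` is numeric.
#' @param z Normal quantile for the interval (default 1.96 for 95%).
#' @return A tibble with columns `ror`, `ci_low`, `ci_high`, `corrected`.
#' @export
ror_with_ci <- function(a, b = NULL, c = NULL, d = NULL, z = 1.96) {
  t <- unpack_table(a, b, c, d)
  corrected <- t$a == 0 | t$b == 0 | t$c == 0 | t$d == 0
  a <- as.numeric(t$a) + 0.5 * corrected; b <- as.numeric(t$b) + 0.5 * corrected
  c <- as.numeric(t$c) + 0.5 * corrected; d <- as.numeric(t$d) + 0.5 * corrected
  lror <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble(ror = exp(lror), ci_low = exp(lror - z * se), ci_high = exp(lror + z * se),
         corrected = corrected)
}

#' Proportional reporting ratio with chi-square statistic
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` and the Pearson chi-square of the 2x2, with
#' the Yates continuity correction by default (the common convention for the
#' `PRR >= 2 with chi-square >= 4` criterion). A zero `c` cell gets the +0.5
#' correction for the PRR and is flagged. Vectorised.
#'
#' @inheritParams ror_with_ci
#' @param yates Apply the continuity correction to the chi-square.
#' @return A tibble with columns `prr`, `chi2`, `corrected`.
#' @export
prr_with_chi2 <- function(a, b = NULL, c = NULL, d = NULL, yates = TRUE) {
  t <- unpack_table(a, b, c, d)
  a <- as.numeric(t$a); b <- as.numeric(t$b)
  c <- as.numeric(t$c); d <- as.numeric(t$d)
  if (any(a + b <= 0) || any(c + d <= 0)) stop("empty margin: PRR undefined")
  corrected <- c == 0
  ac <- a + 0.5 * corrected; bc <- b + 0.5 * corrected
  cc <- c + 0.5 * corrected; dc <- d + 0.5 * corrected
  prr <- (ac / (ac + bc)) / (cc / (cc + dc))
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (isTRUE(yates)) num <- pmax(num - n / 2, 0)
  chi2 <- n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  chi2[(a + c) == 0 | (b + d) == 0] <- 0
  tibble(prr = prr, chi2 = chi2, corrected = corrected)
}

#' Information component with lower credibility bound
#'
#' The observed/expected shrinkage form of the Bayesian confidence
#' propagation statistic: with `E = (a+b)(a+c)/N`,
#' `IC = log2((a + 0.5)/(E + 0.5))`, and `IC025` is the 2.5th percentile of
#' the gamma posterior `Gamma(shape = a + 0.5, rate = E + 0.5)` on the
#' reporting-rate ratio, on the log2 scale. Vectorised.
#'
#' @inheritParams ror_with_ci
#' @return A tibble with columns `ic`, `ic025`, `expected` (the E count).
#' @export
ic_with_ic025 <- function(a, b = NULL, c = NULL, d = NULL) {
  t <- lapply(unpack_table(a, b, c, d), as.numeric)
  n <- t$a + t$b + t$c + t$d
  if (any(n <= 0)) stop("empty table")
  e <- (t$a + t$b) * (t$a + t$c) / n
  ic <- log2((t$a + 0.5) / (e + 0.5))
  ic025 <- log2(qgamma(0.025, shape = t$a + 0.5, rate = e + 0.5))
  tibble(ic = ic, ic025 = ic025, expected = e)
}

#' Signal-positivity thresholds
#'
#' The predefined rule: a drug-event pair is a positive signal only when all
#' four algorithms pass — ROR lower 95% bound > 1; PRR >= 2 with chi-square
#' >= 4; IC025 > 0; EBGM05 >= 2 — and the pair has at least `min_reports`
#' co-occurrence reports (pairs below the floor are not evaluable and no
#' statistics are reported for them).
#'
#' @param z Normal quantile for the ROR interval.
#' @param prr_min,chi2_min,ic025_min,eb05_min Algorithm thresholds.
#' @param min_reports Co-occurrence floor (default 3).
#' @param eb_quantile Posterior percentile used for EBGM05 (default 0.05, the
#'   MGPS convention).
#' @param yates Continuity correction for the chi-square.
#' @return A `signal_thresholds` list.
#' @export
signal_thresholds <- function(z = 1.96, prr_min = 2, chi2_min = 4,
                              ic025_min = 0, eb05_min = 2, min_reports = 3,
                              eb_quantile = 0.05, yates = TRUE) {
  stopifnot(z > 0, prr_min > 0, chi2_min >= 0, eb05_min > 0, min_reports >= 1,
            eb_quantile > 0, eb_quantile < 1)
  structure(list(z = z, prr_min = prr_min, chi2_min = chi2_min,
                 ic025_min = ic025_min, eb05_min = eb05_min,
                 min_reports = min_reports, eb_quantile = eb_quantile,
                 yates = yates), class = "signal_thresholds")
}

#' Evaluate the combined signal rule on one table
#'
#' Computes all four disproportionality statistics and applies the combined
#' positivity rule of [signal_thresholds()]. Tables with `a` below the
#' co-occurrence floor return `status = "not_evaluable"` with `NA`
#' statistics. Besides the four-algorithm `status`, a `status_ror` column
#' reports the ROR-only reading (lower bound > 1), since pooled class-level
#' tables are often judged on the ROR alone.
#'
#' @param table A `contingency_table`.
#' @param prior A fitted [fit_mgps_prior()] object for the same database
#'   (required for the EBGM criterion unless `a < min_reports`).
#' @param thresholds A [signal_thresholds()] object.
#' @return One-row tibble (`DisproResult`): cells, the eight statistics,
#'   per-algorithm flags, `n_algorithms_positive`, `status`, `status_ror`.
#' @export
evaluate_signal <- function(table, prior = NULL, thresholds = signal_thresholds()) {
  stopifnot(inherits(table, "contingency_table"))
  base <- tibble(database = table$database, level = table$level,
                 a = table$a, b = table$b, c = table$c, d = table$d)
  if (table$a < thresholds$min_reports) {
    return(mutate(base, ror = NA_real_, ror_ci_low = NA_real_, ror_ci_high = NA_real_,
                  prr = NA_real_, chi2 = NA_real_, ic = NA_real_, ic025 = NA_real_,
                  ebgm = NA_real_, ebgm05 = NA_real_, corrected = NA,
                  ror_pos = NA, prr_pos = NA, ic_pos = NA, ebgm_pos = NA,
                  n_algorithms_positive = NA_integer_,
                  status = "not_evaluable", status_ror = "not_evaluable"))
  }
  if (is.null(prior)) stop("a fitted MGPS prior is required to evaluate the EBGM criterion")
  r <- ror_with_ci(table, z = thresholds$z)
  p <- prr_with_chi2(table, yates = thresholds$yates)
  i <- ic_with_ic025(table)
  eb <- ebgm_with_eb05(table$a, i$expected, prior, quantile = thresholds$eb_quantile)
  flags <- c(ror = r$ci_low > 1,
             prr = p$prr >= thresholds$prr_min & p$chi2 >= thresholds$chi2_min,
             ic = i$ic025 > thresholds$ic025_min,
             ebgm = eb$ebgm05 >= thresholds$eb05_min)
  mutate(base,
         ror = r$ror, ror_ci_low = r$ci_low, ror_ci_high = r$ci_high,
         prr = p$prr, chi2 = p$chi2, ic = i$ic, ic025 = i$ic025,
         ebgm = eb$ebgm, ebgm05 = eb$ebgm05,
         corrected = r$corrected | p$corrected,
         ror_pos = flags[["ror"]], prr_pos = flags[["prr"]],
         ic_pos = flags[["ic"]], ebgm_pos = flags[["ebgm"]],
         n_algorithms_positive = as.integer(sum(flags)),
         status = ifelse(all(flags), "positive", "negative"),
         status_ror = ifelse(flags[["ror"]], "positive", "negative"))
}

# Report-level pair counts for every (drug, pt) combination: a for the pair,
# exposure margin n_drug, event margin n_pt, and N. Exposure is by
# primary-suspect role. Vectorised over all pairs at once.
pair_counts <- function(x, drug_ids = NULL, pt_codes = NULL) {
  ps <- x$drugs %>%
    filter(.data$role == "primary_suspect", !is.na(.data$drug_id)) %>%
    distinct(.data$report_id, .data$drug_id)
  ev <- distinct(x$events, .data$report_id, .data$pt_code)
  if (!is.null(drug_ids)) ps <- filter(ps, .data$drug_id %in% drug_ids)
  if (!is.null(pt_codes)) ev <- filter(ev, .data$pt_code %in% pt_codes)
  n_total <- nrow(x$reports)
  n_drug <- ps %>% count(.data$drug_id, name = "n_drug")
  n_pt <- ev %>% count(.data$pt_code, name = "n_pt")
  pair <- inner_join(ps, ev, by = "report_id", relationship = "many-to-many") %>%
    count(.data$drug_id, .data$pt_code, name = "a")
  full <- tidyr::expand_grid(drug_id = n_drug$drug_id, pt_code = n_pt$pt_code) %>%
    left_join(pair, by = c("drug_id", "pt_code")) %>%
    mutate(a = ifelse(is.na(.data$a), 0L, .data$a)) %>%
    left_join(n_drug, by = "drug_id") %>%
    left_join(n_pt, by = "pt_code") %>%
    mutate(n = n_total)
  full
}

#' Per-PT disproportionality signal table
#'
#' Runs the full four-algorithm evaluation for each PT of a set (and
#' optionally each index drug separately) against the comparator background
#' of all other reports in the same database. Cells with `a` below the
#' co-occurrence floor are reported as `not_evaluable`.
#'
#' @param x A deduplicated, filtered `srs_reports` object.
#' @param drug_ids Study drug ids. With `by = "pt"` they are pooled into one
#'   index class; with `by = "drug_pt"` each drug is analysed separately.
#' @param set A `pt_set` (or character vector of PT codes).
#' @param prior Optional [fit_mgps_prior()] fit for this database; fitted on
#'   all drug-PT cells of the database when omitted.
#' @param thresholds A [signal_thresholds()] object.
#' @param by `"pt"` (drug class level) or `"drug_pt"`.
#' @return A tibble with one row per (drug,) PT: cells, statistics, flags,
#'   `n_algorithms_positive`, `status`, `status_ror`.
#' @export
compute_signals <- function(x, drug_ids, set, prior = NULL,
                            thresholds = signal_thresholds(),
                            by = c("pt", "drug_pt")) {
  by <- match.arg(by)
  if (inherits(set, "pt_set")) set <- set$pt_code
  if (is.null(prior)) prior <- fit_mgps_prior(mgps_cells(x))
  n_total <- nrow(x$reports)
  if (by == "pt") {
    ps <- x$drugs %>%
      filter(.data$role == "primary_suspect", !is.na(.data$drug_id),
             .data$drug_id %in% drug_ids) %>%
      distinct(.data$report_id)
    ev <- x$events %>% filter(.data$pt_code %in% set) %>%
      distinct(.data$report_id, .data$pt_code)
    n_drug <- nrow(ps)
    counts <- ev %>%
      mutate(exposed = .data$report_id %in% ps$report_id) %>%
      group_by(.data$pt_code) %>%
      summarise(a = sum(.data$exposed), n_pt = dplyr::n()) %>%
      mutate(drug_id = paste(drug_ids, collapse = "+"), n_drug = n_drug,
             n = n_total)
    counts <- tibble(pt_code = set) %>%
      left_join(counts, by = "pt_code") %>%
      mutate(a = ifelse(is.na(.data$a), 0L, .data$a),
             n_pt = ifelse(is.na(.data$n_pt), 0L, .data$n_pt),
             drug_id = paste(drug_ids, collapse = "+"),
             n_drug = n_drug, n = n_total)
  } else {
    counts <- pair_counts(x, drug_ids = drug_ids, pt_codes = set)
    counts <- tidyr::expand_grid(drug_id = drug_ids, pt_code = set) %>%
      left_join(counts, by = c("drug_id", "pt_code")) %>%
      mutate(a = ifelse(is.na(.data$a), 0L, .data$a),
             n_drug = ifelse(is.na(.data$n_drug), 0L, .data$n_drug),
             n_pt = ifelse(is.na(.data$n_pt), 0L, .data$n_pt),
             n = n_total)
  }
  signal_stats(counts, prior, thresholds, database = srs_database(x))
}

# Shared vectorised evaluation on a counts frame with columns
# drug_id, pt_code, a, n_drug, n_pt, n.
signal_stats <- function(counts, prior, thresholds, database = "unknown") {
  counts <- mutate(counts, across(c("a", "n_drug", "n_pt", "n"), as.numeric))
  a <- counts$a
  b <- counts$n_drug - a
  c <- counts$n_pt - a
  d <- counts$n - counts$n_drug - counts$n_pt + a
  ev <- a >= thresholds$min_reports
  out <- tibble(database = database, drug_id = counts$drug_id,
                pt_code = counts$pt_code, a = a, b = b, c = c, d = d,
                ror = NA_real_, ror_ci_low = NA_real_, ror_ci_high = NA_real_,
                prr = NA_real_, chi2 = NA_real_, ic = NA_real_, ic025 = NA_real_,
                ebgm = NA_real_, ebgm05 = NA_real_, corrected = NA,
                ror_pos = NA, prr_pos = NA, ic_pos = NA, ebgm_pos = NA,
                n_algorithms_positive = NA_integer_,
                status = "not_evaluable", status_ror = "not_evaluable")
  if (any(ev)) {
    r <- ror_with_ci(a[ev], b[ev], c[ev], d[ev], z = thresholds$z)
    p <- prr_with_chi2(a[ev], b[ev], c[ev], d[ev], yates = thresholds$yates)
    i <- ic_with_ic025(a[ev], b[ev], c[ev], d[ev])
    eb <- ebgm_with_eb05(a[ev], i$expected, prior, quantile = thresholds$eb_quantile)
    out$ror[ev] <- r$ror; out$ror_ci_low[ev] <- r$ci_low; out$ror_ci_high[ev] <- r$ci_high
    out$prr[ev] <- p$prr; out$chi2[ev] <- p$chi2
    out$ic[ev] <- i$ic; out$ic025[ev] <- i$ic025
    out$ebgm[ev] <- eb$ebgm; out$ebgm05[ev] <- eb$ebgm05
    out$corrected[ev] <- r$corrected | p$corrected
    out$ror_pos[ev] <- r$ci_low > 1
    out$prr_pos[ev] <- p$prr >= thresholds$prr_min & p$chi2 >= thresholds$chi2_min
    out$ic_pos[ev] <- i$ic025 > thresholds$ic025_min
    out$ebgm_pos[ev] <- eb$ebgm05 >= thresholds$eb05_min
    out$n_algorithms_positive[ev] <- out$ror_pos[ev] + out$prr_pos[ev] +
      out$ic_pos[ev] + out$ebgm_pos[ev]
    out$status[ev] <- ifelse(out$n_algorithms_positive[ev] == 4L, "positive", "negative")
    out$status_ror[ev] <- ifelse(out$ror_pos[ev], "positive", "negative")
  }
  out
}

#' Co-medication sensitivity rerun
#'
#' Drops every report that mentions any excluded drug in any role (the
#' confounding-by-co-medication exclusion), reruns the full signal pipeline
#' on the remainder with a freshly fitted shrinkage prior, and classifies
#' each PT's status change against the primary run (`retained`, `lost`,
#' `gained`, or unchanged negative/not-evaluable states).
#'
#' @param x A deduplicated, filtered `srs_reports` object.
#' @param excluded_drug_ids Drug ids whose presence (any role) excludes a
#'   report.
#' @param drug_ids,set,thresholds,by As in [compute_signals()].
#' @param primary Optional precomputed primary signal table (recomputed when
#'   omitted).
#' @return List with `primary`, `sensitivity` (signal tables), `delta`
#'   (per-PT status comparison) and `n_excluded`.
#' @export
run_sensitivity <- function(x, excluded_drug_ids, drug_ids, set,
                            thresholds = signal_thresholds(),
                            by = c("pt", "drug_pt"), primary = NULL) {
  by <- match.arg(by)
  stopifnot(length(excluded_drug_ids) > 0)
  if (is.null(primary))
    primary <- compute_signals(x, drug_ids, set, thresholds = thresholds, by = by)
  drop_ids <- unique(x$drugs$report_id[!is.na(x$drugs$drug_id) &
                                         x$drugs$drug_id %in% excluded_drug_ids])
  xs <- subset_reports(x, setdiff(x$reports$report_id, drop_ids))
  xs <- log_attrition(xs, "comed_exclusion", nrow(x$reports), nrow(xs$reports))
  sens <- compute_signals(xs, drug_ids, set, thresholds = thresholds, by = by)
  key <- intersect(c("drug_id", "pt_code"), names(primary))
  delta <- primary %>%
    select(dplyr::all_of(key), primary_status = "status") %>%
    left_join(select(sens, dplyr::all_of(key), sensitivity_status = "status"),
              by = key) %>%
    mutate(change = dplyr::case_when(
      .data$primary_status == "positive" & .data$sensitivity_status == "positive" ~ "retained",
      .data$primary_status == "positive" & .data$sensitivity_status != "positive" ~ "lost",
      .data$primary_status != "positive" & .data$sensitivity_status == "positive" ~ "gained",
      TRUE ~ "unchanged"))
  list(primary = primary, sensitivity = sens, delta = delta,
       n_excluded = length(drop_ids))
}

#' Cumulative yearly ROR trend
#'
#' For each calendar year from the anchor (approval) year onward, builds the
#' 2x2 table cumulative through that year and reports the ROR with its
#' interval; years with fewer than `min_reports` co-occurrences are marked
#' not evaluable.
#'
#' @param x A deduplicated, filtered `srs_reports` object.
#' @param drug_ids Index drug ids.
#' @param set A `pt_set` or character vector of PT codes.
#' @param anchor_year First year of the series (e.g. the approval year).
#' @param z Normal quantile for the interval.
#' @param min_reports Co-occurrence floor.
#' @return Tibble: `year`, cumulative `a`, `b`, `c`, `d`, `ror`, `ci_low`,
#'   `ci_high`, `evaluable`.
#' @export
yearly_ror_trend <- function(x, drug_ids, set, anchor_year = NULL, z = 1.96,
                             min_reports = 3) {
  if (inherits(set, "pt_set")) set <- set$pt_code
  yr <- as.integer(format(x$reports$receipt_date, "%Y"))
  keep <- !is.na(yr)
  ids <- x$reports$report_id[keep]; yr <- yr[keep]
  if (!length(yr)) stop("no receipt years available")
  anchor_year <- anchor_year %||% min(yr)
  exposed_ids <- unique(x$drugs$report_id[x$drugs$role == "primary_suspect" &
                                            !is.na(x$drugs$drug_id) &
                                            x$drugs$drug_id %in% drug_ids])
  case_ids <- unique(x$events$report_id[x$events$pt_code %in% set])
  e <- ids %in% exposed_ids
  k <- ids %in% case_ids
  years <- seq(anchor_year, max(yr))
  rows <- lapply(years, function(y) {
    in_win <- yr <= y
    tibble(year = y, a = sum(e & k & in_win), b = sum(e & !k & in_win),
           c = sum(!e & k & in_win), d = sum(!e & !k & in_win))
  })
  out <- bind_rows(rows)
  out$evaluable <- out$a >= min_reports & (out$a + out$b + out$c + out$d) > 0
  out$ror <- NA_real_; out$ci_low <- NA_real_; out$ci_high <- NA_real_
  if (any(out$evaluable)) {
    r <- ror_with_ci(out$a[out$evaluable], out$b[out$evaluable],
                     out$c[out$evaluable], out$d[out$evaluable], z = z)
    out$ror[out$evaluable] <- r$ror
    out$ci_low[out$evaluable] <- r$ci_low
    out$ci_high[out$evaluable] <- r$ci_high
  }
  out
}
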