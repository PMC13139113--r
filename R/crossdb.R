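#' Cross-database algorithm-count matrix
#'
#' Summarises, for each PT and each database, how many of the four
#' disproportionality algorithms flagged the PT positive (0-4), with `NA`
#' where the PT was not reported or fell below the co-occurrence floor in
#' that database. Rows are ordered by cross-database replication strength:
#' number of databases with all four algorithms positive, then total
#' algorithm count, then the reference database's count.
#'
#' @param signal_tables Named list of per-database signal tables from
#'   [compute_signals()] (names are the database labels; the first is treated
#'   as the reference/discovery database).
#' @param pt_codes PT codes to include (or a `pt_set`); defaults to the union
#'   of PTs in the tables.
#' @return A wide tibble: `pt_code` plus one integer column per database.
#' @export
build_crossdb_matrix <- function(signal_tables, pt_codes = NULL) {
  stopifnot(is.list(signal_tables), !is.null(names(signal_tables)))
  if (inherits(pt_codes, "pt_set")) pt_codes <- pt_codes$pt_code
  long <- bind_rows(lapply(names(signal_tables), function(db) {
    s <- signal_tables[[db]]
    tibble(pt_code = s$pt_code, database = db,
           n_algorithms_positive = ifelse(s$status == "not_evaluable",
                                          NA_integer_,
                                          as.integer(s$n_algorithms_positive)))
  }))
  if (is.null(pt_codes)) pt_codes <- unique(long$pt_code)
  wide <- tidyr::expand_grid(pt_code = pt_codes,
                             database = names(signal_tables)) %>%
    left_join(long, by = c("pt_code", "database")) %>%
    tidyr::pivot_wider(names_from = "database",
                       values_from = "n_algorithms_positive")
  dbs <- names(signal_tables)
  m <- as.matrix(wide[, dbs, drop = FALSE])
  strength <- rowSums(m == 4L, na.rm = TRUE)
  total <- rowSums(m, na.rm = TRUE)
  ref <- ifelse(is.na(m[, 1]), -1L, m[, 1])
  wide[order(-strength, -total, -ref, wide$pt_code), ]
}

#' Replication calls across databases
#'
#' A FAERS-style discovery signal is called replicated when the effect
#' direction is consistent (ROR > 1) with the confidence interval excluding
#' unity in at least two databases — the discovery database counts towards
#' the two. PTs not evaluable everywhere are reported as such rather than as
#' failures.
#'
#' @param signal_tables Named list of per-database [compute_signals()]
#'   tables.
#' @param pt_codes PT codes to call (or a `pt_set`); defaults to the union.
#' @return Tibble: `pt_code`, `replicated` (logical, `NA` when nowhere
#'   evaluable), `n_supporting`, `basis` (comma-joined supporting
#'   databases), `evaluable_in`.
#' @export
call_replication <- function(signal_tables, pt_codes = NULL) {
  if (inherits(pt_codes, "pt_set")) pt_codes <- pt_codes$pt_code
  long <- bind_rows(lapply(names(signal_tables), function(db) {
    s <- signal_tables[[db]]
    tibble(pt_code = s$pt_code, database = db,
           evaluable = s$status != "not_evaluable",
           supports = !is.na(s$ror_ci_low) & s$ror > 1 & s$ror_ci_low > 1)
  }))
  if (is.null(pt_codes)) pt_codes <- unique(long$pt_code)
  long %>%
    filter(.data$pt_code %in% pt_codes) %>%
    group_by(.data$pt_code) %>%
    summarise(
      n_supporting = sum(.data$supports, na.rm = TRUE),
      basis = paste(.data$database[.data$supports %in% TRUE], collapse = ","),
      evaluable_in = sum(.data$evaluable),
      replicated = ifelse(.data$evaluable_in == 0, NA,
                          .data$n_supporting >= 2)
    ) %>%
    ungroup() %>%
    select("pt_code", "replicated", "n_supporting", "basis", "evaluable_in")
}
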