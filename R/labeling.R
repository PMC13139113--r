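#' Load a prescribing-information label map
#'
#' Reads the curated mapping of labeled adverse reactions to PT codes per
#' drug. The mapping is an input file: the package never parses PI documents
#' themselves.
#'
#' @param path CSV with columns `drug_id`, `pt_code` and optional
#'   `source_section`.
#' @return Tibble with one row per labeled (drug, PT) pair.
#' @export
load_labels <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("drug_id", "pt_code") %in% names(d)))
  if (!"source_section" %in% names(d)) d$source_section <- NA_character_
  distinct(as_tibble(d), .data$drug_id, .data$pt_code, .keep_all = TRUE)
}

#' Label concordance of positive signals
#'
#' Classifies each four-algorithm-positive (drug, PT) signal as `known`
#' (listed in the drug's prescribing information) or `new_signal` (detected
#' but absent from labeling). Labeled PTs with no positive signal are
#' reported as `labeled_not_detected` for completeness but excluded from the
#' per-drug stacked counts by default. Classification depends only on set
#' membership, never on input order.
#'
#' @param signals A per-drug signal table from
#'   `compute_signals(..., by = "drug_pt")`; only rows with
#'   `status == "positive"` are classified.
#' @param labels A label map from [load_labels()].
#' @param include_not_detected Keep `labeled_not_detected` rows in `calls`.
#' @return List: `calls` (tibble `drug_id`, `pt_code`, `category`) and
#'   `per_drug` (tibble `drug_id`, `known`, `new_signal`, `n_positive`).
#' @export
classify_concordance <- function(signals, labels, include_not_detected = TRUE) {
  pos <- filter(signals, .data$status == "positive")
  missing_drugs <- setdiff(unique(pos$drug_id), unique(labels$drug_id))
  if (length(missing_drugs))
    stop("no label entry for drug(s): ", paste(missing_drugs, collapse = ", "))
  lab_key <- paste(labels$drug_id, labels$pt_code)
  calls <- tibble(
    drug_id = pos$drug_id, pt_code = pos$pt_code,
    category = as.character(ifelse(paste(pos$drug_id, pos$pt_code) %in% lab_key,
                                   "known", "new_signal")))
  if (include_not_detected) {
    nd <- anti_join(labels[, c("drug_id", "pt_code")],
                    calls[, c("drug_id", "pt_code")],
                    by = c("drug_id", "pt_code")) %>%
      filter(.data$drug_id %in% unique(pos$drug_id)) %>%
      mutate(category = "labeled_not_detected")
    calls <- bind_rows(calls, nd)
  }
  per_drug <- calls %>%
    filter(.data$category %in% c("known", "new_signal")) %>%
    count(.data$drug_id, .data$category) %>%
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (col in c("known", "new_signal"))
    if (!col %in% names(per_drug)) per_drug[[col]] <- 0L
  per_drug <- mutate(per_drug, n_positive = .data$known + .data$new_signal)
  calls <- arrange(calls, .data$drug_id, .data$pt_code)
  list(calls = calls, per_drug = arrange(per_drug, .data$drug_id))
}
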