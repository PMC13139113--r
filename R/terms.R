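#' Load a preferred-term set
#'
#' Reads a curated PT list (for instance an SMQ-derived peripheral-neuropathy
#' set supplemented by expert-curated terms) from CSV. Matching elsewhere in
#' the package is by `pt_code`, never by display name, to avoid locale
#' issues.
#'
#' @param path CSV with columns `pt_code`, `pt_name`, `provenance`
#'   (`smq` | `curated` | `mixed` per term).
#' @param name Label for the set.
#' @param version Free-text vocabulary version tag.
#' @return A `pt_set` object: tibble of terms with attributes `name` and
#'   `version`.
#' @export
load_pt_set <- function(path, name = "PNS_curated", version = "unversioned") {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(d) == 0) stop("PT set file is empty")
  stopifnot(all(c("pt_code", "pt_name", "provenance") %in% names(d)))
  pt_set(d$pt_code, d$pt_name, d$provenance, name = name, version = version)
}

#' Construct a preferred-term set in code
#'
#' @param pt_code Character vector of unique PT codes.
#' @param pt_name Display names (defaults to the codes).
#' @param provenance Per-term provenance tag: `"smq"`, `"curated"` or
#'   `"mixed"`.
#' @param name,version Set label and vocabulary version.
#' @return A `pt_set` object.
#' @export
pt_set <- function(pt_code, pt_name = pt_code, provenance = "curated",
                   name = "pt_set", version = "unversioned") {
  pt_code <- as.character(pt_code)
  if (length(pt_code) == 0) stop("PT set must be non-empty")
  if (anyDuplicated(pt_code))
    stop("duplicate PT code(s): ",
         paste(unique(pt_code[duplicated(pt_code)]), collapse = ", "))
  provenance <- rep_len(as.character(provenance), length(pt_code))
  bad <- setdiff(unique(provenance), c("smq", "curated", "mixed"))
  if (length(bad)) stop("invalid provenance tag(s): ", paste(bad, collapse = ", "))
  structure(
    tibble(pt_code = pt_code, pt_name = as.character(pt_name),
           provenance = provenance),
    name = name, version = version,
    class = c("pt_set", "tbl_df", "tbl", "data.frame")
  )
}

#' @export
print.pt_set <- function(x, ...) {
  cat(sprintf("<pt_set> %s (%s): %d term(s)\n", attr(x, "name"),
              attr(x, "version"), nrow(x)))
  NextMethod()
}

#' Look up PT codes by display name
#'
#' Convenience for fixtures and label files that are written with names.
#' Matching is exact after trimming and case-folding.
#'
#' @param names Character vector of PT display names.
#' @param set A `pt_set`.
#' @return Character vector of codes (`NA` where the name is not in the set).
#' @export
pt_name_to_code <- function(names, set) {
  idx <- match(tolower(trimws(names)), tolower(trimws(set$pt_name)))
  set$pt_code[idx]
}

#' Classify reports against a PT set
#'
#' A report is a case iff at least one of its coded events is in the set
#' (exact code match). The unique-case notion counts each matching report
#' once; PT-level co-occurrence counting (one report contributing to several
#' PTs) is done downstream on the `matches` table.
#'
#' @param x An `srs_reports` object.
#' @param set A `pt_set`.
#' @return A list with `matches` (tibble `report_id`, `pt_code`: every
#'   event-level hit), `case_ids` (report ids with at least one hit) and
#'   `n_cases`.
#' @export
classify_reports <- function(x, set) {
  stopifnot(inherits(x, "srs_reports"), inherits(set, "pt_set"))
  matches <- x$events %>%
    filter(.data$pt_code %in% set$pt_code) %>%
    distinct(.data$report_id, .data$pt_code)
  case_ids <- unique(matches$report_id)
  list(matches = matches, case_ids = case_ids, n_cases = length(case_ids))
}
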