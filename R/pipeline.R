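#' Run the full signal-detection pipeline
#'
#' Orchestrates the end-to-end analysis over one or more databases:
#' ingestion, deduplication, inclusion filters, PT classification,
#' per-database four-algorithm signal tables, cross-database matrix and
#' replication calls, the co-medication sensitivity rerun on the discovery
#' database, time-to-onset, annual trends, demographics and seriousness
#' summaries, and label concordance. Every stage's input/output record
#' counts are logged; all artifacts are written as UTF-8 CSV with ISO dates.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{databases}{named list; each element a list with `paths` (named
#'       vector for the FAERS dialect, single path otherwise), `dialect`,
#'       and optional `deleted_path` (one id per line). The first database
#'       is the discovery database.}
#'     \item{pt_set_path, drug_dict_path}{inputs for [load_pt_set()] and
#'       [read_drug_dictionary()].}
#'     \item{labels_path}{optional, enables the concordance stage.}
#'     \item{study_drugs}{character vector of study drug ids.}
#'     \item{sensitivity_drugs}{optional excluded co-medication ids.}
#'     \item{thresholds}{optional list of [signal_thresholds()] arguments.}
#'     \item{anchor_year}{optional first year of the ROR trend.}
#'     \item{out_dir}{output directory.}
#'     \item{seed}{integer; seeds any stochastic step.}
#'   }
#' @return Invisibly, a list of the computed artifacts (also written to
#'   `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$databases), !is.null(config$out_dir),
            !is.null(config$pt_set_path), !is.null(config$drug_dict_path),
            !is.null(config$study_drugs))
  set.seed(config$seed %||% 1L)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  thresholds <- do.call(signal_thresholds, config$thresholds %||% list())
  pt <- load_pt_set(config$pt_set_path)
  dict <- read_drug_dictionary(config$drug_dict_path)
  study_drugs <- config$study_drugs
  stage <- "setup"
  run_db <- function(name, dbcfg) {
    stage <<- paste0("ingest:", name)
    bundle <- read_bundle(dbcfg$paths, dialect = dbcfg$dialect)
    x <- assemble_reports(bundle, dict)
    deleted <- if (!is.null(dbcfg$deleted_path) && file.exists(dbcfg$deleted_path))
      readLines(dbcfg$deleted_path) else character()
    stage <<- paste0("deduplicate:", name)
    x <- deduplicate(x, deleted_ids = deleted)
    stage <<- paste0("filters:", name)
    x <- apply_inclusion_filters(x, study_drugs)
    al <- attrition_log(x)
    for (i in seq_len(nrow(al)))
      say("[%s] %s: %d -> %d (-%d)", name, al$stage[i], al$n_in[i],
          al$n_out[i], al$n_removed[i])
    x
  }
  result <- list()
  tryCatch({
    dbs <- lapply(names(config$databases), function(nm)
      run_db(nm, config$databases[[nm]]))
    names(dbs) <- names(config$databases)
    stage <- "signals"
    signal_tables <- lapply(names(dbs), function(nm) {
      s <- compute_signals(dbs[[nm]], study_drugs, pt, thresholds = thresholds)
      s$database <- nm
      readr::write_csv(s, file.path(out_dir, sprintf("signals_%s.csv", nm)))
      say("[%s] signal table: %d PT(s), %d positive", nm, nrow(s),
          sum(s$status == "positive"))
      s
    })
    names(signal_tables) <- names(dbs)
    result$signals <- signal_tables
    stage <- "crossdb"
    mat <- build_crossdb_matrix(signal_tables, pt)
    rep_calls <- call_replication(signal_tables, pt)
    readr::write_csv(mat, file.path(out_dir, "crossdb_matrix.csv"))
    readr::write_csv(rep_calls, file.path(out_dir, "replication_calls.csv"))
    result$crossdb <- list(matrix = mat, replication = rep_calls)
    disc_name <- names(dbs)[1]
    disc <- dbs[[disc_name]]
    if (!is.null(config$sensitivity_drugs)) {
      stage <- "sensitivity"
      sens <- run_sensitivity(disc, config$sensitivity_drugs, study_drugs, pt,
                              thresholds = thresholds,
                              primary = signal_tables[[disc_name]])
      readr::write_csv(sens$delta, file.path(out_dir, "sensitivity_delta.csv"))
      readr::write_csv(sens$sensitivity,
                       file.path(out_dir, "signals_sensitivity.csv"))
      say("[%s] sensitivity: %d report(s) excluded; %d signal(s) lost",
          disc_name, sens$n_excluded, sum(sens$delta$change == "lost"))
      result$sensitivity <- sens
    }
    stage <- "temporal"
    tto <- lapply(study_drugs, function(dg)
      suppressWarnings(compute_tto(disc, dg, pt)))
    tto_summary <- bind_rows(lapply(tto, `[[`, "summary"))
    tto_ecdf <- bind_rows(lapply(seq_along(tto), function(i)
      mutate(tto[[i]]$ecdf, drug_id = study_drugs[i])))
    readr::write_csv(tto_summary, file.path(out_dir, "tto_summary.csv"))
    readr::write_csv(tto_ecdf, file.path(out_dir, "tto_ecdf.csv"))
    trend <- annual_trend(disc, study_drugs, pt)
    readr::write_csv(trend$by_drug, file.path(out_dir, "annual_trend_by_drug.csv"))
    readr::write_csv(trend$total, file.path(out_dir, "annual_trend_total.csv"))
    demo <- summarize_demographics(disc, study_drugs, pt)
    serious <- suppressWarnings(summarize_seriousness(disc, study_drugs, pt))
    readr::write_csv(demo, file.path(out_dir, "demographics.csv"))
    readr::write_csv(serious, file.path(out_dir, "seriousness.csv"))
    if (!is.null(config$anchor_year)) {
      ror_trend <- yearly_ror_trend(disc, study_drugs, pt,
                                    anchor_year = config$anchor_year,
                                    z = thresholds$z,
                                    min_reports = thresholds$min_reports)
      readr::write_csv(ror_trend, file.path(out_dir, "ror_trend.csv"))
      result$ror_trend <- ror_trend
    }
    result$temporal <- list(tto = tto_summary, trend = trend,
                            demographics = demo, seriousness = serious)
    if (!is.null(config$labels_path)) {
      stage <- "labeling"
      labels <- load_labels(config$labels_path)
      per_drug_signals <- compute_signals(disc, study_drugs, pt,
                                          thresholds = thresholds,
                                          by = "drug_pt")
      conc <- classify_concordance(per_drug_signals, labels)
      readr::write_csv(conc$calls, file.path(out_dir, "concordance_calls.csv"))
      readr::write_csv(conc$per_drug, file.path(out_dir, "concordance_per_drug.csv"))
      result$concordance <- conc
    }
    attr_all <- bind_rows(lapply(names(dbs), function(nm)
      mutate(attrition_log(dbs[[nm]]), database = nm)))
    readr::write_csv(attr_all, file.path(out_dir, "attrition.csv"))
    result$attrition <- attr_all
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s\nlog so far:\n%s",
                 stage, conditionMessage(e), paste(log_lines, collapse = "\n")),
         call. = FALSE)
  })
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(result)
}
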