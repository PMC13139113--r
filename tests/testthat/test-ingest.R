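test_that("FAERS bundles load with row counts preserved and strict table checks", {
  dir <- withr::local_tempdir()
  demo <- tibble::tibble(primaryid = as.character(1:5), caseid = as.character(1:5),
                         fda_dt = "20220101", event_dt = "20211215", sex = "F",
                         age = "60", age_cod = "YR", occp_cod = "MD",
                         reporter_country = "US")
  drug <- tibble::tibble(primaryid = as.character(1:5), drug_seq = "1",
                         drugname = "ADCETRIS", role_cod = "PS")
  reac <- tibble::tibble(primaryid = as.character(1:5), pt = "10029331")
  readr::write_delim(demo, file.path(dir, "demo.txt"), delim = "$")
  readr::write_delim(drug, file.path(dir, "drug.txt"), delim = "$")
  readr::write_delim(reac, file.path(dir, "reac.txt"), delim = "$")
  paths <- c(DEMO = file.path(dir, "demo.txt"), DRUG = file.path(dir, "drug.txt"),
             REAC = file.path(dir, "reac.txt"))
  b <- read_bundle(paths, "faers")
  expect_equal(nrow(b$tables$DEMO), 5)
  expect_error(read_bundle(paths[c("DEMO", "DRUG")], "faers"),
               "mandatory table absent")
  # unknown columns are dropped with a warning, not an error
  demo$mystery <- "x"
  readr::write_delim(demo, file.path(dir, "demo.txt"), delim = "$")
  expect_warning(b2 <- read_bundle(paths, "faers"), "unknown column")
  expect_false("mystery" %in% names(b2$tables$DEMO))
})

test_that("date parsing handles the FAERS precisions and flags partial dates", {
  p <- parse_srs_date(c("20220315", "2022-03-15", "202203", "2022", "", "bogus"))
  expect_equal(p$date[1:2], rep(as.Date("2022-03-15"), 2))
  expect_equal(p$date[3], as.Date("2022-03-15"))   # month precision -> day 15
  expect_equal(p$date[4], as.Date("2022-07-01"))   # year precision -> July 1
  expect_true(all(is.na(p$date[5:6])))
  expect_equal(p$full[1:4], c(TRUE, TRUE, FALSE, FALSE))
})

test_that("age units convert to years and bins are closed on the left", {
  expect_equal(age_to_years(c(60, 6, 730, 7), c("YR", "MON", "DY", "DEC")),
               c(60, 0.5, 730 / 365.25, 70))
  expect_true(is.na(age_to_years(300, "YR")))  # implausible
  expect_equal(age_group(c(1.9, 2, 11.9, 12, 17.9, 18, 64.9, 65, 85, 85.1, NA)),
               c("<2", "2-11", "2-11", "12-17", "12-17", "18-64", "18-64",
                 "65-85", "65-85", ">85", "unknown"))
})

test_that("deduplication keeps the latest version, breaks ties deterministically, and is idempotent", {
  x <- mk_srs(
    reports = tibble::tibble(report_id = c("R1", "R2", "R3", "R4"),
                             case_id = c("C1", "C1", "C2", "C2"),
                             receipt_date = c("2024-01-01", "2024-06-01",
                                              "2024-03-01", "2024-03-01")),
    drugs = tibble::tibble(report_id = c("R1", "R2", "R3", "R4"),
                           drug_id = "brentuximab_vedotin"),
    events = tibble::tibble(report_id = c("R1", "R2", "R3", "R4"),
                            pt_code = "10029331"))
  d <- deduplicate(x)
  expect_setequal(d$reports$report_id, c("R2", "R4"))  # June version; tie -> R4
  expect_identical(deduplicate(d)$reports, d$reports)  # idempotent
  # no duplicates -> identity
  x1 <- subset(x$reports, case_id == "C1")
  expect_equal(nrow(deduplicate(mk_srs(
    tibble::tibble(report_id = "R9", case_id = "C9"),
    tibble::tibble(report_id = "R9", drug_id = "a"),
    tibble::tibble(report_id = "R9", pt_code = "p")))$reports), 1)
  # DELETED-list ids are removed before keying
  d2 <- deduplicate(x, deleted_ids = "C1")
  expect_setequal(d2$reports$report_id, "R4")
  expect_equal(attrition_log(d2)$n_removed[attrition_log(d2)$stage == "deleted_list"], 2L)
})

test_that("deduplication matches the brute-force oracle on small random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:50, 1)
    reports <- tibble::tibble(
      report_id = sprintf("R%02d", sample(n)),
      case_id = sprintf("C%02d", sample.int(max(2, n %/% 3), n, replace = TRUE)),
      receipt_date = as.Date("2020-01-01") + sample.int(400, n, replace = TRUE))
    x <- mk_srs(reports,
                tibble::tibble(report_id = reports$report_id, drug_id = "a"),
                tibble::tibble(report_id = reports$report_id, pt_code = "p"))
    got <- sort(deduplicate(x)$reports$report_id)
    want <- sort(unname(dedup_oracle_ids(x$reports)))
    expect_identical(got, want)
  }
})

test_that("inclusion filters drop non-HCP reports symmetrically and set exposure by primary-suspect role", {
  x <- mk_srs(
    reports = tibble::tibble(report_id = c("R1", "R2", "R3", "R4"),
                             reporter = c("consumer", "MD", "PH", "unknown")),
    drugs = tibble::tibble(report_id = c("R1", "R2", "R3", "R4"),
                           drug_id = c("adc", "adc", "other", "adc"),
                           role = c("primary_suspect", "concomitant",
                                    "primary_suspect", "primary_suspect")),
    events = tibble::tibble(report_id = c("R1", "R2", "R3", "R4"), pt_code = "p"))
  f <- apply_inclusion_filters(x, "adc")
  # consumer ADC case excluded; unknown reporter excluded from BOTH sides
  expect_setequal(f$reports$report_id, c("R2", "R3"))
  # MD report with the study drug as concomitant only: retained, unexposed
  expect_false(f$reports$exposed[f$reports$report_id == "R2"])
  expect_false(f$reports$exposed[f$reports$report_id == "R3"])
  # attrition reconciles: removed counts sum to input minus output
  al <- attrition_log(f)
  expect_equal(sum(al$n_removed), al$n_in[1] - al$n_out[nrow(al)])
  expect_true(all(al$n_out <= al$n_in))
  # empty input passes through empty
  e <- apply_inclusion_filters(subset_reports_empty(x), "adc")
  expect_equal(nrow(e$reports), 0)
})

test_that("records without drugs or events are flagged invalid and unmatched names keep NA drug ids", {
  cfg <- synth_config(n_reports = 400, missing = list(drug_match = 0.10))
  g <- generate_srs(cfg, seed = 21)
  dict <- stats::setNames(g$dictionary$drug_id,
                          normalize_drug_name(g$dictionary$name))
  dir <- withr::local_tempdir()
  paths <- write_bundle(g$reports, "faers", dir)
  x <- assemble_reports(read_bundle(paths, "faers"), dict)
  d <- deduplicate(x)
  ps <- d$drugs[d$drugs$role == "primary_suspect", ]
  truth <- g$truth$assignments
  expect_setequal(ps$report_id[is.na(ps$drug_id)],
                  truth$report_id[!truth$drug_matched])
  # normalization: case/punctuation insensitive exact match on the packaged
  # dictionary
  pkg_dict <- read_drug_dictionary(srsignal_example("adc_drug_dictionary_standin.csv"))
  expect_equal(unname(pkg_dict[normalize_drug_name("  Adcetris!! ")]),
               "brentuximab_vedotin")
  # a report with zero event rows is assembled as invalid
  x2 <- mk_srs(tibble::tibble(report_id = c("R1", "R2"), valid = c(TRUE, FALSE)),
               tibble::tibble(report_id = c("R1", "R2"), drug_id = "a"),
               tibble::tibble(report_id = "R1", pt_code = "p"))
  f <- apply_inclusion_filters(x2, "a")
  expect_setequal(f$reports$report_id, "R1")
})

test_that("synthetic bundles survive a write/read/assemble round trip in every dialect", {
  cfg <- synth_config(n_reports = 150)
  g <- generate_srs(cfg, seed = 3)
  dict <- stats::setNames(g$dictionary$drug_id,
                          normalize_drug_name(g$dictionary$name))
  for (dial in c("faers", "jader", "cvard")) {
    dir <- withr::local_tempdir()
    paths <- write_bundle(g$reports, dial, dir)
    x2 <- assemble_reports(read_bundle(paths, dial), dict)
    r1 <- dplyr::arrange(g$reports$reports, report_id)
    r2 <- dplyr::arrange(x2$reports, report_id)
    if (dial != "faers") r1$case_id <- r1$report_id  # flat dialects key on report id
    expect_equal(as.data.frame(r1), as.data.frame(r2))
    expect_equal(
      as.data.frame(dplyr::arrange(g$reports$drugs, report_id, raw_name, role)),
      as.data.frame(dplyr::arrange(x2$drugs, report_id, raw_name, role)))
    expect_equal(
      as.data.frame(dplyr::arrange(g$reports$events, report_id, pt_code)),
      as.data.frame(dplyr::arrange(x2$events, report_id, pt_code)))
    expect_equal(
      as.data.frame(dplyr::arrange(g$reports$outcomes, report_id, outcome)),
      as.data.frame(dplyr::arrange(x2$outcomes, report_id, outcome)))
  }
})
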