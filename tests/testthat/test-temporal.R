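test_that("onset summaries use order statistics and exclude non-evaluable records", {
  x <- mk_srs(
    tibble::tibble(report_id = sprintf("R%d", 1:5),
                   event_date = c("2022-02-10", "2022-02-20", "2022-03-02",
                                  "2022-01-01", "2022-02-01"),
                   event_date_full = c(TRUE, TRUE, TRUE, TRUE, FALSE)),
    tibble::tibble(report_id = sprintf("R%d", 1:5), drug_id = "adc",
                   therapy_start = c("2022-01-31", "2022-01-31", "2022-01-31",
                                     "2022-02-01", "2022-01-01"),
                   therapy_start_full = c(TRUE, TRUE, TRUE, TRUE, TRUE)),
    tibble::tibble(report_id = sprintf("R%d", 1:5), pt_code = "P1"))
  out <- compute_tto(x, "adc", "P1")
  # onsets 10, 20, 30 evaluable; R4 negative delta, R5 partial event date
  expect_equal(sort(out$records$onset_days[out$records$evaluable]), c(10, 20, 30))
  expect_false(out$records$evaluable[out$records$report_id == "R4"])
  expect_false(out$records$evaluable[out$records$report_id == "R5"])
  expect_equal(out$summary$median, 20)
  expect_equal(c(out$summary$q1, out$summary$q3), c(15, 25))  # type-7 quantiles
  # ECDF: non-decreasing, reaches 1 at the maximum onset
  expect_true(all(diff(out$ecdf$cum_fraction) >= 0))
  expect_equal(out$ecdf$cum_fraction[nrow(out$ecdf)], 1)
  expect_equal(out$ecdf$day, 0:30)
  # same-day onset is evaluable at 0 days
  x0 <- mk_srs(tibble::tibble(report_id = "R1", event_date = "2022-01-05",
                              event_date_full = TRUE),
               tibble::tibble(report_id = "R1", drug_id = "adc",
                              therapy_start = "2022-01-05",
                              therapy_start_full = TRUE),
               tibble::tibble(report_id = "R1", pt_code = "P1"))
  expect_equal(compute_tto(x0, "adc", "P1")$summary$median, 0)
  # no evaluable record: empty summary with a warning
  expect_warning(empty <- compute_tto(x0, "other", "P1"), "no evaluable")
  expect_equal(empty$summary$n_evaluable, 0L)
})

test_that("log-normal onset delays are recovered from synthetic cohorts", {
  cfg <- synth_config(
    n_reports = 3000,
    drugs = tibble::tibble(drug_id = c("adc_x", "bg"), prob = c(0.5, 0.5),
                           study = c(TRUE, FALSE)),
    pts = tibble::tibble(pt_code = c("P1", "P2"), pt_name = c("P1", "P2"),
                         base_prob = c(0.5, 0.6), pns = c(TRUE, FALSE)),
    onset = tibble::tibble(drug_id = "adc_x", meanlog = log(25), sdlog = 0.6),
    missing = list(therapy_start = 0, event_date = 0, partial_date = 0,
                   drug_match = 0),
    dup_rate = 0, reporter_probs = c(MD = 1))
  co <- prepare_cohort(cfg, seed = 55, study_drugs = "adc_x")
  out <- compute_tto(co$x, "adc_x", "P1")
  expect_gt(out$summary$n_evaluable, 500)
  expect_lt(abs(out$summary$median - 25) / 25, 0.10)
})

test_that("annual trends count each case once with explicit zero years", {
  x <- mk_srs(
    tibble::tibble(report_id = sprintf("R%d", 1:5),
                   receipt_date = c("2019-05-01", "2019-08-01", "2021-01-01",
                                    "2021-06-01", "2021-07-01")),
    tibble::tibble(report_id = sprintf("R%d", 1:5), drug_id = "adc"),
    tibble::tibble(report_id = sprintf("R%d", 1:5), pt_code = "P1"))
  tr <- annual_trend(x, "adc", "P1")
  expect_equal(tr$total$year, 2019:2021)
  expect_equal(tr$total$n_cases, c(2L, 0L, 3L))       # empty 2020 is 0, not missing
  expect_equal(tr$by_drug$n_cases, tr$total$n_cases)  # single drug: series = total
})

test_that("a doubling reporting rate is visible in the annual series within noise", {
  cfg <- synth_config(
    n_reports = 6000,
    drugs = tibble::tibble(drug_id = c("adc_x", "bg"), prob = c(0.5, 0.5),
                           study = c(TRUE, FALSE)),
    pts = tibble::tibble(pt_code = c("P1", "P2"), pt_name = c("P1", "P2"),
                         base_prob = c(0.5, 0.6), pns = c(TRUE, FALSE)),
    date_window = as.Date(c("2018-01-01", "2021-12-31")),
    year_weights = c(1, 2, 4, 8),
    dup_rate = 0, missing = list(drug_match = 0), reporter_probs = c(MD = 1))
  co <- prepare_cohort(cfg, seed = 66, study_drugs = "adc_x")
  tr <- annual_trend(co$x, "adc_x", "P1")
  n <- tr$total$n_cases
  expect_equal(tr$total$year, 2018:2021)
  ratios <- n[-1] / n[-length(n)]
  # Poisson noise around a true ratio of 2
  expect_true(all(ratios > 1.4 & ratios < 2.8))
})

test_that("seriousness proportions use the case count as denominator", {
  x <- mk_srs(
    tibble::tibble(report_id = sprintf("R%d", 1:8)),
    tibble::tibble(report_id = sprintf("R%d", 1:8), drug_id = "mylo"),
    tibble::tibble(report_id = sprintf("R%d", 1:8), pt_code = "P1"),
    outcomes = tibble::tibble(report_id = sprintf("R%d", 1:6),
                              outcome = "hospitalization"))
  s <- suppressWarnings(summarize_seriousness(x, c("mylo", "ghost"), "P1"))
  hosp <- s[s$drug_id == "mylo" & s$outcome == "hospitalization", ]
  expect_equal(hosp$n, 6L)
  expect_equal(hosp$denominator, 8L)
  expect_equal(hosp$proportion, 75.0)
  expect_true(hosp$small_denominator)
  expect_false("ghost" %in% s$drug_id)
  expect_warning(summarize_seriousness(x, c("mylo", "ghost"), "P1"),
                 "no classified case")
  # synthetic multinomial outcomes recovered within a binomial interval
  cfg <- synth_config(n_reports = 3000, dup_rate = 0,
                      missing = list(drug_match = 0))
  co <- prepare_cohort(cfg, seed = 91,
                       study_drugs = cfg$drugs$drug_id[cfg$drugs$study])
  pns <- pt_set(cfg$pts$pt_code[cfg$pts$pns])
  ss <- summarize_seriousness(co$x, "adc_a", pns)
  p_hat <- ss$proportion[ss$outcome == "hospitalization"] / 100
  n_den <- ss$denominator[1]
  p0 <- cfg$outcome_probs[["hospitalization"]]
  expect_lt(abs(p_hat - p0), 3 * sqrt(p0 * (1 - p0) / n_den))
})

test_that("demographic blocks sum to the case count with explicit unknown rows", {
  x <- mk_srs(
    tibble::tibble(report_id = sprintf("R%d", 1:10),
                   sex = c(rep("female", 7), rep("male", 2), "unknown")),
    tibble::tibble(report_id = sprintf("R%d", 1:10), drug_id = "besp"),
    tibble::tibble(report_id = sprintf("R%d", 1:10), pt_code = "P1"))
  d <- summarize_demographics(x, "besp", "P1")
  fem <- d[d$block == "sex" & d$category == "female", ]
  expect_equal(fem$label, "7 (70.0%)")
  for (bl in unique(d$block)) {
    blk <- d[d$block == bl, ]
    expect_equal(sum(blk$n), blk$denominator[1])
  }
  # all-unknown sex is a 100% unknown row
  x2 <- mk_srs(tibble::tibble(report_id = "R1", sex = "unknown"),
               tibble::tibble(report_id = "R1", drug_id = "besp"),
               tibble::tibble(report_id = "R1", pt_code = "P1"))
  d2 <- summarize_demographics(x2, "besp", "P1")
  expect_equal(d2$pct[d2$block == "sex" & d2$category == "unknown"], 100)
  # generator truth: exact recovery of a known sex split
  cfg <- synth_config(n_reports = 2000, dup_rate = 0,
                      missing = list(sex = 0, drug_match = 0))
  g <- generate_srs(cfg, seed = 14)
  pns <- pt_set(cfg$pts$pt_code[cfg$pts$pns])
  dd <- summarize_demographics(g$reports, "adc_a", pns)
  truth_ids <- g$truth$assignments$report_id[
    g$truth$assignments$drug_id == "adc_a" & g$truth$assignments$drug_matched &
      g$truth$assignments$pns_case]
  n_fem <- sum(g$reports$reports$sex[g$reports$reports$report_id %in% truth_ids] ==
                 "female")
  expect_equal(dd$n[dd$block == "sex" & dd$category == "female"], n_fem)
})
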