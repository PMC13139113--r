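test_that("2x2 tables place each report in exactly one cell and match a brute-force count", {
  x <- mk_srs(tibble::tibble(report_id = sprintf("R%d", 1:4)),
              tibble::tibble(report_id = sprintf("R%d", 1:4),
                             drug_id = c("adc", "adc", "oth", "oth")),
              tibble::tibble(report_id = sprintf("R%d", 1:4),
                             pt_code = c("P1", "X", "P1", "X")))
  t <- build_table(x, drug_ids = "adc", pt_codes = "P1")
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 1))
  expect_error(build_table(subset_reports_empty(x), drug_ids = "adc",
                           pt_codes = "P1"), "zero reports")
  # brute-force double loop over a synthetic cohort
  cfg <- synth_config(n_reports = 400, dup_rate = 0)
  g <- generate_srs(cfg, seed = 31)
  xx <- g$reports
  pns <- g$truth$pns_pt_codes
  tt <- build_table(xx, drug_ids = "adc_a", pt_codes = pns)
  ps_ids <- unique(xx$drugs$report_id[xx$drugs$role == "primary_suspect" &
                                        !is.na(xx$drugs$drug_id) &
                                        xx$drugs$drug_id == "adc_a"])
  cells <- c(a = 0, b = 0, c = 0, d = 0)
  for (rid in xx$reports$report_id) {
    e <- rid %in% ps_ids
    k <- any(xx$events$pt_code[xx$events$report_id == rid] %in% pns)
    cells[ifelse(e, ifelse(k, "a", "b"), ifelse(k, "c", "d"))] <-
      cells[ifelse(e, ifelse(k, "a", "b"), ifelse(k, "c", "d"))] + 1
  }
  expect_equal(c(tt$a, tt$b, tt$c, tt$d), unname(cells))
  expect_equal(tt$n, nrow(xx$reports))
  # occurrence level counts (report, PT) pairs, so one report can hit twice
  to <- build_table(xx, drug_ids = "adc_a", pt_codes = pns,
                    level = "pt_occurrence")
  expect_gte(to$a, tt$a)
  expect_equal(to$n, nrow(dplyr::distinct(xx$events, report_id, pt_code)))
})

test_that("ROR matches a direct log-odds oracle and handles symmetry and zero cells", {
  r <- ror_with_ci(219, 11046, 3927, 4117708)
  # independent recomputation through the odds p/(1-p) formulation
  p1 <- 219 / (219 + 11046); p0 <- 3927 / (3927 + 4117708)
  expect_equal(r$ror, (p1 / (1 - p1)) / (p0 / (1 - p0)), tolerance = 1e-10)
  s <- ror_with_ci(10, 10, 10, 10)
  expect_equal(s$ror, 1)
  expect_lt(s$ci_low, 1); expect_gt(s$ci_high, 1)
  z <- ror_with_ci(0, 10, 10, 10)
  expect_true(z$corrected)
  expect_equal(z$ror, (0.5 * 10.5) / (10.5 * 10.5))
})

test_that("PRR and chi-square agree with hand margins and with the Pearson test", {
  t2 <- list(a = 1477, b = 87534, c = 79020, d = 21658884)
  p <- prr_with_chi2(t2$a, t2$b, t2$c, t2$d)
  expect_equal(p$prr, (t2$a / (t2$a + t2$b)) / (t2$c / (t2$c + t2$d)),
               tolerance = 1e-12)
  # homogeneous table: prr exactly 1, uncorrected chi2 exactly 0
  h <- prr_with_chi2(10, 90, 20, 180, yates = FALSE)
  expect_equal(h$prr, 1); expect_equal(h$chi2, 0)
  # both corrections against stats::chisq.test on random tables
  set.seed(42)
  for (i in 1:20) {
    m <- matrix(rpois(4, lambda = sample(c(5, 50, 500), 1)) + 1, 2)
    ours_y <- prr_with_chi2(m[1, 1], m[1, 2], m[2, 1], m[2, 2], yates = TRUE)
    ours_n <- prr_with_chi2(m[1, 1], m[1, 2], m[2, 1], m[2, 2], yates = FALSE)
    expect_equal(ours_y$chi2,
                 unname(suppressWarnings(chisq.test(m, correct = TRUE))$statistic),
                 tolerance = 1e-10)
    expect_equal(ours_n$chi2,
                 unname(suppressWarnings(chisq.test(m, correct = FALSE))$statistic),
                 tolerance = 1e-10)
  }
})

test_that("IC uses the shrunken observed/expected form with a gamma lower bound", {
  # margin arithmetic oracle on the pooled class-level counts
  i <- ic_with_ic025(1477, 87534, 79020, 21658884)
  E <- (89011 * 80497) / 21826915
  expect_equal(i$expected, E, tolerance = 1e-12)
  expect_equal(i$ic, log2(1477.5 / (E + 0.5)), tolerance = 1e-12)
  expect_lt(i$ic025, i$ic)
  # balanced table (a = E): the +0.5 shrinkage gives ic exactly 0 and a
  # strictly lower credibility bound
  b <- ic_with_ic025(1000, 9000, 1000, 9000)
  expect_equal(b$expected, 1000)
  expect_equal(b$ic, 0)
  expect_lt(b$ic025, 0)
})

test_that("ROR and PRR agree under the rare-event condition", {
  set.seed(7)
  for (i in 1:20) {
    n <- 1e6
    n_drug <- rpois(1, 4000); n_pt <- rpois(1, 5000)
    a <- rpois(1, n_drug * n_pt / n) + 1
    tab <- list(a = a, b = n_drug - a, c = n_pt - a, d = n - n_drug - n_pt + a)
    if (tab$b <= 0 || tab$c <= 0) next
    ror <- ror_with_ci(tab$a, tab$b, tab$c, tab$d)$ror
    prr <- prr_with_chi2(tab$a, tab$b, tab$c, tab$d)$prr
    expect_lt(abs(ror - prr) / prr, 0.05)
  }
})

test_that("the combined rule is a strict conjunction with a co-occurrence floor", {
  prior <- mgps_prior(0.2, 0.1, 2, 4, 1 / 3)
  # below the floor: no statistics reported
  low <- evaluate_signal(contingency_table(2, 100, 50, 10000), prior)
  expect_equal(low$status, "not_evaluable")
  expect_true(is.na(low$ror))
  # strong ROR but PRR below 2: negative despite ror_pos
  t <- contingency_table(60, 40, 3000, 6000)
  r <- evaluate_signal(t, prior)
  expect_true(r$ror_pos)
  expect_lt(r$prr, 2)
  expect_equal(r$status, "negative")
  expect_equal(r$n_algorithms_positive,
               sum(r$ror_pos, r$prr_pos, r$ic_pos, r$ebgm_pos))
  # positive requires every flag
  strong <- evaluate_signal(contingency_table(100, 900, 1000, 98000), prior)
  if (strong$status == "positive")
    expect_true(strong$ror_pos && strong$prr_pos && strong$ic_pos && strong$ebgm_pos)
})

test_that("per-PT signal tables match single-table evaluation", {
  co <- prepare_cohort(small_synth_config(
    n_reports = 8000,
    signals = tibble::tibble(drug_id = "adc_x", pt_code = "PT01", rho = 6)),
    seed = 77, study_drugs = "adc_x")
  prior <- fit_mgps_prior(mgps_cells(co$x))
  s <- compute_signals(co$x, "adc_x", c("PT01", "PT02"), prior = prior)
  for (ptc in c("PT01", "PT02")) {
    row <- s[s$pt_code == ptc, ]
    tab <- build_table(co$x, drug_ids = "adc_x", pt_codes = ptc)
    one <- evaluate_signal(tab, prior)
    expect_equal(row$a, one$a)
    if (row$status != "not_evaluable") {
      expect_equal(row$ror, one$ror, tolerance = 1e-12)
      expect_equal(row$ebgm05, one$ebgm05, tolerance = 1e-9)
      expect_equal(row$status, one$status)
    }
  }
})

test_that("cumulative yearly ROR series is monotone in co-occurrences", {
  cfg <- small_synth_config(
    n_reports = 6000,
    signals = tibble::tibble(drug_id = "adc_x", pt_code = "PT01", rho = 5))
  co <- prepare_cohort(cfg, seed = 13, study_drugs = "adc_x")
  tr <- yearly_ror_trend(co$x, "adc_x", c("PT01", "PT02"), anchor_year = 2016)
  expect_true(all(diff(tr$a) >= 0))
  expect_true(all(diff(tr$a + tr$b + tr$c + tr$d) >= 0))
  expect_equal(tr$year, seq(2016, max(tr$year)))
  # single-year cohort gives a one-point series
  one <- mk_srs(tibble::tibble(report_id = sprintf("R%d", 1:6),
                               receipt_date = "2020-05-01"),
                tibble::tibble(report_id = sprintf("R%d", 1:6),
                               drug_id = c(rep("adc", 3), rep("oth", 3))),
                tibble::tibble(report_id = sprintf("R%d", 1:6),
                               pt_code = c("P1", "P1", "P1", "P1", "X", "X")))
  tr1 <- yearly_ror_trend(one, "adc", "P1")
  expect_equal(nrow(tr1), 1)
  expect_equal(tr1$a, 3)
})
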