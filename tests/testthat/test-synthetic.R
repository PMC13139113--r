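test_that("generation is byte-deterministic under a seed", {
  cfg <- synth_config(n_reports = 300)
  g1 <- generate_srs(cfg, seed = 5)
  g2 <- generate_srs(cfg, seed = 5)
  expect_identical(g1$reports$reports, g2$reports$reports)
  expect_identical(g1$reports$drugs, g2$reports$drugs)
  expect_identical(g1$reports$events, g2$reports$events)
  expect_identical(g1$truth$assignments, g2$truth$assignments)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_bundle(g1$reports, "faers", d1)
  p2 <- write_bundle(g2$reports, "faers", d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  g3 <- generate_srs(cfg, seed = 6)
  expect_false(identical(g1$reports$reports, g3$reports$reports))
})

test_that("config validation rejects inconsistent probabilities", {
  expect_error(synth_config(drugs = tibble::tibble(
    drug_id = c("a", "b"), prob = c(0.6, 0.6), study = c(TRUE, FALSE))),
    "sum to 1")
  expect_error(synth_config(reporter_probs = c(MD = 0.5, PH = 0.1)), "sum to 1")
  expect_error(synth_config(missing = list(sex = 1.4)), "\\[0, 1\\]")
  expect_error(synth_config(signals = tibble::tibble(
    drug_id = "adc_a", pt_code = "PT0001", rho = -1)))
})

test_that("analytic expected cells match a hand computation on a two-drug toy", {
  cfg <- synth_config(
    n_reports = 1000,
    drugs = tibble::tibble(drug_id = c("g1", "g2"), prob = c(0.3, 0.7),
                           study = c(TRUE, FALSE)),
    pts = tibble::tibble(pt_code = c("p1", "p2"), pt_name = c("p1", "p2"),
                         base_prob = c(0.2, 0.5), pns = c(TRUE, FALSE)),
    signals = tibble::tibble(drug_id = "g1", pt_code = "p1", rho = 2),
    events_lambda = 0.5, missing = list(drug_match = 0))
  e <- expected_cells(cfg)
  # by hand: s = 1.5/0.7; q(g1) = (min(1, .2*s*2), min(1, .5*s)) = (6/7, 1)
  # q(g2) = (3/7, 1); the p2 probability is 1 so no report is empty and
  # P(p1|g) = q(p1|g) exactly
  r <- e[e$drug_id == "g1" & e$pt_code == "p1", ]
  expect_equal(r$a, 1000 * 0.3 * 6 / 7, tolerance = 1e-12)
  expect_equal(r$b, 1000 * 0.3 * 1 / 7, tolerance = 1e-12)
  expect_equal(r$c, 1000 * 0.7 * 3 / 7, tolerance = 1e-12)
  expect_equal(r$d, 1000 * 0.7 * 4 / 7, tolerance = 1e-12)
  expect_equal(r$or_true, ((6 / 7) / (1 / 7)) / ((3 / 7) / (4 / 7)),
               tolerance = 1e-12)
  # with rho = 1 everywhere the implied odds ratios are exactly 1
  cfg0 <- synth_config(n_reports = 1000, missing = list(drug_match = 0))
  expect_true(all(abs(expected_cells(cfg0)$or_true - 1) < 1e-12))
})

test_that("raising rho weakly increases expected co-occurrence and odds ratio", {
  mk <- function(rho) synth_config(
    n_reports = 10000,
    signals = tibble::tibble(drug_id = "adc_a", pt_code = "PT0001", rho = rho),
    missing = list(drug_match = 0))
  get <- function(rho) {
    e <- expected_cells(mk(rho))
    e[e$drug_id == "adc_a" & e$pt_code == "PT0001", ]
  }
  rhos <- c(1, 2, 4, 8)
  a_vals <- vapply(rhos, function(r) get(r)$a, numeric(1))
  or_vals <- vapply(rhos, function(r) get(r)$or_true, numeric(1))
  expect_true(all(diff(a_vals) >= 0))
  expect_true(all(diff(or_vals) >= 0))
})

test_that("empirical cell counts sit within 4 sigma of the analytic expectations", {
  cfg <- synth_config(
    n_reports = 50000,
    signals = tibble::tibble(drug_id = "adc_a", pt_code = "PT0001", rho = 5),
    dup_rate = 0, missing = list(drug_match = 0))
  g <- generate_srs(cfg, seed = 8)
  e <- expected_cells(cfg)
  checks <- list(c("adc_a", "PT0001"), c("adc_a", "PT0101"),
                 c("drug_01", "PT0001"), c("adc_b", "PT0002"))
  for (ck in checks) {
    tab <- build_table(g$reports, drug_ids = ck[1], pt_codes = ck[2])
    ee <- e[e$drug_id == ck[1] & e$pt_code == ck[2], ]
    for (cell in c("a", "b", "c", "d")) {
      p <- ee[[cell]] / cfg$n_reports
      sdv <- sqrt(cfg$n_reports * p * (1 - p))
      expect_lt(abs(tab[[cell]] - ee[[cell]]), 4 * sdv + 1)
    }
  }
})

test_that("duplicate emission respects the configured rate and ground truth", {
  cfg <- synth_config(n_reports = 5000, dup_rate = 0.15)
  g <- generate_srs(cfg, seed = 44)
  expect_equal(nrow(g$reports$reports),
               5000 + sum(g$truth$assignments$is_duplicate))
  d <- deduplicate(g$reports)
  expect_equal(nrow(d$reports), g$truth$n_cases)
  expect_setequal(d$reports$report_id, g$truth$assignments$report_id)
  # the duplicate share is near its Bernoulli expectation
  p_hat <- mean(g$truth$assignments$is_duplicate)
  expect_lt(abs(p_hat - 0.15), 4 * sqrt(0.15 * 0.85 / 5000))
})
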