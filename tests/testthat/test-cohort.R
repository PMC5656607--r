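test_that("one-sided Fisher matches closed forms and the stats oracle", {
  # all-or-nothing table: C(5,5)C(5,0)/C(10,5) = 1/252
  expect_equal(fisher_one_sided(5, 0, 0, 5), 1 / 252)
  expect_warning(p <- fisher_one_sided(0, 0, 10, 10), "degenerate")
  expect_equal(p, 1)
  # agreement with fisher.test on random non-degenerate tables
  set.seed(13)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8) + c(1, 1, 1, 1), 2)
    expect_equal(fisher_one_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
})

test_that("log-rank detects no difference between identical groups", {
  time <- c(5, 10, 15, 20, 25, 30)
  event <- c(1, 1, 0, 1, 0, 1)
  fit <- log_rank(c(time, time), c(event, event),
                  rep(c("x", "y"), each = 6))
  expect_equal(fit$statistic, 0, tolerance = 1e-12)
  expect_equal(fit$p, 1)
  expect_error(log_rank(time, event, rep("x", 6)), "two")
  expect_error(log_rank(time, rep(0, 6), rep(c("x", "y"), 3)), "events")
})

test_that("KM curve with zero censoring equals the empirical survivor", {
  set.seed(17)
  t1 <- rexp(40, 1 / 100); t2 <- rexp(40, 1 / 50)
  fit <- log_rank(c(t1, t2), rep(1, 80), rep(c("g1", "g2"), each = 40))
  km1 <- fit$km[fit$km$group == "g1", ]
  emp <- vapply(km1$time, function(tt) mean(t1 > tt), numeric(1))
  expect_equal(km1$surv, emp, tolerance = 1e-12)
  # survival curves are non-increasing from 1
  expect_true(all(diff(km1$surv) <= 0))
  expect_true(all(km1$surv <= 1 & km1$surv >= 0))
})

test_that("log-rank has power against a planted hazard ratio", {
  set.seed(19)
  cfg <- sim_config()  # HR 2, n = 69/36, ~40% censoring
  ps <- vapply(1:100, function(i) {
    ch <- simulate_validation_cohort(cfg, seed = 5000 + i)
    fit <- log_rank(ch$clinical$os_days, ch$clinical$os_event,
                    ch$loh_status[ch$clinical$patient_id])
    fit$p
  }, numeric(1))
  expect_lt(median(ps), 0.05)
})

test_that("the cohort endpoint reproduces printed marginal counts", {
  # 20/69 non-responders with LOH vs 4/36 responders + long-term survivors
  clinical <- data.frame(
    patient_id = sprintf("P%03d", 1:105),
    response_group = rep(c("nonresponder", "responder", "long_term_survivor"),
                         times = c(69, 26, 10)),
    os_days = seq(100, 2180, by = 20),
    os_event = rep(c(1L, 0L), length.out = 105))
  loh <- rep(FALSE, 105)
  loh[1:20] <- TRUE          # 20 of 69 non-responders
  loh[70:73] <- TRUE         # 4 of 36 responders/LTS
  ep <- loh_enrichment_endpoint(clinical,
                                setNames(loh, clinical$patient_id))
  expect_equal(as.vector(ep$table), c(20, 49, 4, 32))
  expect_equal(ep$fisher_p, fisher_one_sided(20, 4, 49, 32))
  expect_s3_class(ep$survfit, "escape_survfit")
  expect_error(loh_enrichment_endpoint(clinical, setNames(loh[-1],
    clinical$patient_id[-1])), "P001")
})

test_that("an LOH-free cohort degenerates to p = 1", {
  clinical <- data.frame(patient_id = c("A", "B", "C", "D"),
                         response_group = c("nonresponder", "nonresponder",
                                            "responder", "responder"),
                         os_days = c(100, 200, 300, 400),
                         os_event = c(1L, 1L, 0L, 1L))
  expect_warning(ep <- loh_enrichment_endpoint(
    clinical, setNames(rep(FALSE, 4), clinical$patient_id)), "degenerate")
  expect_equal(ep$fisher_p, 1)
  expect_null(ep$survfit)
})

test_that("expression scores are pseudocounted geometric means", {
  expect_equal(expression_score(c(g1 = 3, g2 = 8), c("g1", "g2")), 6)
  expect_equal(expression_score(c(g1 = 0, g2 = 0), c("g1", "g2")), 1)
  expect_equal(expression_score(c(g = 10), "g"), 11)
  expect_warning(s <- expression_score(c(g1 = 3, g2 = 8), c("g1", "gX")),
                 "gX")
  expect_equal(s, 4)
  expect_error(suppressWarnings(expression_score(c(g1 = 1), "gX")),
               "no gene")
  # monotone in any TPM
  base <- expression_score(c(a = 2, b = 5, c = 9), c("a", "b", "c"))
  expect_gt(expression_score(c(a = 4, b = 5, c = 9), c("a", "b", "c")), base)
})

test_that("IHC bins, ddPCR abundance and competition score follow their formulas", {
  expect_equal(as.character(ihc_bin(c(5, 10, 49.9, 50, 79, 80, 100))),
               c("minimal", "low", "low", "intermediate", "intermediate",
                 "high", "high"))
  expect_equal(as.character(ihc_bin(0)), "minimal")
  expect_error(ihc_bin(101), "\\[0, 100\\]")

  expect_equal(ddpcr_fractional_abundance(0, 100), 0)
  expect_equal(ddpcr_fractional_abundance(50, 50), 50)
  expect_equal(ddpcr_fractional_abundance(25, 75), 25)
  expect_error(ddpcr_fractional_abundance(0, 0), "zero total")

  expect_equal(competition_score(50, 50, 50, 50), 0)
  expect_equal(competition_score(0, 50, 100, 50), 100)
  expect_equal(competition_score(25, 50, 75, 50), (1 - 0.5 / 1.5) * 100)
  expect_error(competition_score(25, 50, 0, 50), "wild-type")
  expect_error(competition_score(25, 0, 75, 50), "baseline")
})
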