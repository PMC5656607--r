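test_that("read simulation respects the allelic model limits", {
  # zero signal
  r0 <- simulate_reads(ccf = 0, purity = 0.6, cn_t = 2, m = 1, depth = 500,
                       seed = 1)
  expect_equal(r0$alt_count, 0L)
  expect_equal(r0$ref_count, 500L)
  # saturated VAF = 1
  r1 <- simulate_reads(ccf = 1, purity = 1, cn_t = 2, m = 2, depth = 100,
                       seed = 1)
  expect_equal(r1$alt_count, 100L)
  # binomial mean at the expected VAF (0.5 * 0.5 * 1 / 2 = 0.125)
  rr <- simulate_reads(rep(0.5, 1000), purity = 0.5, cn_t = 2, m = 1,
                       depth = rep(10000, 1000), seed = 2)
  p_hat <- sum(rr$alt_count) / sum(rr$alt_count + rr$ref_count)
  se <- sqrt(0.125 * 0.875 / 1e7)
  expect_lt(abs(p_hat - 0.125), 3 * se)
  expect_error(simulate_reads(1, 1, cn_t = 1, m = 3, depth = 10),
               "inconsistent")
})

test_that("seeded simulation is deterministic and leaves the RNG alone", {
  cfg <- sim_config(n_background_mutations = 30L)
  a <- simulate_longitudinal_patient(cfg, seed = 42, patient_id = "P")
  b <- simulate_longitudinal_patient(cfg, seed = 42, patient_id = "P")
  expect_identical(a, b)
  c2 <- simulate_longitudinal_patient(cfg, seed = 43, patient_id = "P")
  expect_false(identical(a$variants$alt_count, c2$variants$alt_count))

  set.seed(123); before <- runif(5)
  set.seed(123); invisible(simulate_longitudinal_patient(cfg, seed = 1))
  expect_identical(runif(5), before)

  v1 <- simulate_validation_cohort(sim_config(), seed = 7)
  v2 <- simulate_validation_cohort(sim_config(), seed = 7)
  expect_identical(v1, v2)
})

test_that("escape scenarios plant exactly the advertised structure", {
  cfg <- sim_config(n_background_mutations = 40L)
  p <- simulate_longitudinal_patient(cfg, seed = 3, patient_id = "P")
  prog <- p$samples$sample_id[p$samples$disease_state == "progression"]
  esc <- p$variants[p$variants$gene == "B2M", ]
  expect_setequal(unique(esc$effect), "frameshift")
  expect_equal(length(unique(paste(esc$chrom, esc$pos))), 2L)
  # deletion over the locus in every progression biopsy, nowhere else
  les <- p$segments[p$segments$minor_cn == 0L & p$segments$chrom == "15" &
                      p$segments$start <= 45003675 &
                      p$segments$end >= 45011075, ]
  expect_setequal(les$sample_id, prog)
  # truth lists only entities present in the cohort
  expect_true(all(p$truth$variants$variant_id %in%
                    with(p$variants, paste(chrom, pos, ref, alt, sep = ":"))))
  expect_true(all(p$truth$loh_samples %in% p$samples$sample_id))

  none <- simulate_longitudinal_patient(
    sim_config(n_background_mutations = 40L, escape_scenario = "none"),
    seed = 3, patient_id = "P")
  expect_false(any(none$variants$gene == "B2M"))
  expect_false(any(none$segments$chrom == "15" & none$segments$minor_cn == 0L))

  loh_only <- simulate_longitudinal_patient(
    sim_config(n_background_mutations = 40L, escape_scenario = "loh_only"),
    seed = 3, patient_id = "P")
  expect_false(any(loh_only$variants$gene == "B2M"))
  expect_true(any(loh_only$segments$chrom == "15" &
                    loh_only$segments$minor_cn == 0L))
})

test_that("synthetic patients write and re-read through the canonical TSVs", {
  cfg <- sim_config(n_background_mutations = 20L)
  p <- simulate_longitudinal_patient(cfg, seed = 11, patient_id = "P")
  dir <- tempfile()
  write_synthetic_patient(p, dir)
  v <- read_variant_table(file.path(dir, "variants.tsv"))
  expect_equal(v$alt_count, p$variants$alt_count)
  s <- read_samples(file.path(dir, "samples.tsv"))
  expect_equal(s$purity, p$samples$purity)
  seg <- read_segments(file.path(dir, "segments.tsv"))
  expect_equal(nrow(seg), nrow(p$segments))
})

test_that("validation cohorts hit their planted prevalences and censoring", {
  cfg <- sim_config()
  loh_nr <- 0L; loh_r <- 0L; n_nr <- 0L; n_r <- 0L
  for (i in 1:200) {
    ch <- simulate_validation_cohort(cfg, seed = i)
    nr <- ch$clinical$response_group == "nonresponder"
    loh <- ch$loh_status[ch$clinical$patient_id]
    loh_nr <- loh_nr + sum(loh[nr]); n_nr <- n_nr + sum(nr)
    loh_r <- loh_r + sum(loh[!nr]); n_r <- n_r + sum(!nr)
  }
  # empirical fractions within 95% binomial bounds of the planted rates
  expect_lt(abs(loh_nr / n_nr - 0.289), 1.96 * sqrt(0.289 * 0.711 / n_nr))
  expect_lt(abs(loh_r / n_r - 0.111), 1.96 * sqrt(0.111 * 0.889 / n_r))

  no_cens <- simulate_validation_cohort(sim_config(censoring_rate = 0),
                                        seed = 5)
  expect_true(all(no_cens$clinical$os_event == 1L))
})

test_that("log-rank p-values are uniform under a unit hazard ratio", {
  cfg <- sim_config(survival_hazard_ratio_loh = 1)
  ps <- vapply(1:1000, function(i) {
    ch <- simulate_validation_cohort(cfg, seed = 20000 + i)
    loh <- ch$loh_status[ch$clinical$patient_id]
    if (length(unique(loh)) < 2 || !any(ch$clinical$os_event == 1))
      return(NA_real_)
    log_rank(ch$clinical$os_days, ch$clinical$os_event, loh)$p
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
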