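test_that("expected VAF follows the allelic model", {
  expect_equal(expected_vaf(purity = 1, cn_t = 2, m = 1, ccf = 1), 0.5)
  expect_equal(expected_vaf(purity = 0.5, cn_t = 2, m = 1, ccf = 1), 0.25)
  expect_equal(expected_vaf(purity = 0.5, cn_t = 2, m = 1, ccf = 0), 0)
  expect_equal(expected_vaf(purity = 1, cn_t = 2, m = 2, ccf = 1), 1)
  # multiplicity inconsistent with local copy number
  expect_error(expected_vaf(purity = 1, cn_t = 1, m = 3, ccf = 1),
               "inconsistent")
  expect_error(expected_vaf(purity = 0, cn_t = 2, m = 1, ccf = 1), "purity")
})

test_that("multiplicity estimation rounds and clamps", {
  expect_equal(estimate_multiplicity(vaf = 0.9, purity = 1, cn_t = 2), 2L)
  expect_equal(estimate_multiplicity(vaf = 0.25, purity = 0.5, cn_t = 2), 1L)
  expect_equal(estimate_multiplicity(vaf = 0.01, purity = 0.5, cn_t = 2), 1L)
  expect_equal(estimate_multiplicity(vaf = 1, purity = 1, cn_t = 4), 4L)
  expect_equal(estimate_multiplicity(vaf = 1, purity = 1, cn_t = 1), 1L)
})

test_that("CCF point estimates invert the expected VAF", {
  est <- estimate_ccf(alt = 25, ref = 75, purity = 0.5, cn_t = 2, m = 1)
  expect_equal(est$ccf, 1.0)
  expect_true(est$ci_low <= est$ccf && est$ccf <= est$ci_high)
  est0 <- estimate_ccf(alt = 0, ref = 100, purity = 0.5, cn_t = 2, m = 1)
  expect_equal(est0$ccf, 0)
  expect_equal(est0$ci_low, 0)
  expect_error(estimate_ccf(alt = 0, ref = 0, purity = 0.5, cn_t = 2, m = 1),
               "alt \\+ ref")

  # property: mapping the estimate back through the model returns the VAF,
  # whenever the estimate is interior (not clamped at 1)
  set.seed(21)
  for (i in 1:200) {
    purity <- runif(1, 0.1, 1); cn_t <- sample(1:4, 1)
    m <- sample(seq_len(cn_t), 1)
    alt <- sample(0:80, 1); ref <- sample(20:200, 1)
    est <- estimate_ccf(alt, ref, purity, cn_t, m)
    if (est$ccf < 1) {
      expect_equal(expected_vaf(purity, cn_t, m, est$ccf), alt / (alt + ref),
                   tolerance = 1e-12)
    }
  }
})

test_that("CCF estimation recovers simulated truth increasingly with depth", {
  set.seed(31)
  mae <- vapply(c(50, 150, 1000), function(depth) {
    truth <- runif(300, 0.1, 0.9)
    purity <- runif(300, 0.4, 0.9)
    reads <- simulate_reads(truth, purity, cn_t = 2, m = 1,
                            depth = rep(depth, 300))
    est <- estimate_ccf(reads$alt_count, reads$ref_count, purity, 2, 1)
    mean(abs(est$ccf - truth))
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
  # binomial error shrinks like 1/sqrt(depth): 50 -> 1000 is a ~4.5x drop
  expect_lt(mae[3], mae[1] / 3)
})

test_that("detection power is a binomial tail, monotone in its drivers", {
  expect_equal(detection_power(depth = 2, purity = 1, cn_t = 2, m = 1,
                               k_min = 3), 0)
  # binomial tail oracle at depth 150, VAF 0.25
  expect_equal(detection_power(150, 0.5, 2, 1, k_min = 3),
               1 - pbinom(2, 150, 0.25))
  expect_gt(detection_power(150, 0.5, 2, 1), 0.9)

  depths <- seq(0, 400, by = 10)
  pw <- detection_power(depths, 0.3, 2, 1)
  expect_true(all(diff(pw) >= 0))
  expect_gt(pw[length(pw)], 0.999)
  purities <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(detection_power(60, purities, 2, 1)) >= 0))
  expect_true(all(diff(detection_power(60, 0.3, 2, c(1, 2))) >= 0))
})

test_that("annotated CCF matrices pick up purity and local copy number", {
  samples <- data.frame(sample_id = c("S1", "S2"), purity = c(0.5, 1))
  segments <- data.frame(sample_id = c("S1", "S2"), chrom = "15",
                         start = 1L, end = 1000000L,
                         total_cn = c(1, 2), major_cn = 1L,
                         minor_cn = c(0L, 1L), copy_ratio = c(0.5, 1))
  fc <- data.frame(variant_id = "15:500:A:T", sample_id = c("S1", "S2"),
                   chrom = "15", pos = 500L, gene = "B2M",
                   effect = "frameshift", alt_count = c(25L, 50L),
                   ref_count = c(75L, 50L))
  ann <- estimate_ccf_matrix(fc, samples, segments)
  expect_equal(ann$cn_t, c(1, 2))
  # S1: vaf 0.25, denom 0.5*1+0.5*2=1.5 -> ccf = 0.25*1.5/0.5 = 0.75
  expect_equal(ann$ccf[1], 0.75)
  # S2: clonal het at purity 1
  expect_equal(ann$ccf[2], 1)
  expect_error(estimate_ccf_matrix(fc, samples[1, ], segments), "S2")
})
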