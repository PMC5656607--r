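test_that("power filter requires the threshold in every biopsy", {
  sids <- c("S1", "S2", "S3")
  ccf <- rbind(ccf_rows("v_ok", sids, "G1", "missense", 0.5,
                        power = c(0.95, 0.99, 0.91)),
               ccf_rows("v_low", sids, "G2", "missense", 0.5,
                        power = c(0.95, 0.89, 0.99)))
  expect_equal(power_filter(ccf, sids), "v_ok")
  expect_setequal(power_filter(ccf, sids, min_power = 0), c("v_ok", "v_low"))
  expect_error(power_filter(ccf[-2, ], sids), "v_ok.*S2")
})

test_that("the worked-example patient yields exactly the escape gene", {
  fx <- escape_patient_fixture()
  hits <- screen_patient(fx$ccf, fx$loh, fx$samples)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$gene, "B2M")
  expect_equal(hits$n_nonsilent, 2L)
  expect_true(hits$loh_in_progression)
  expect_equal(hits$max_ccf_progression, 0.74)
  expect_match(hits$passing_variants, "fs1")
  expect_match(hits$passing_variants, "fs2")
  # audit decomposition: every criterion individually true for the hit
  audit <- attr(hits, "audit")
  b2m <- audit[audit$gene == "B2M", ]
  expect_true(b2m$multiple_nonsilent && b2m$ccf_pattern &&
                b2m$loh_in_progression)
})

test_that("perturbing any single criterion removes the hit", {
  fx <- escape_patient_fixture()
  # (i) escape variant also present while responding
  ccf_bad <- fx$ccf
  i <- ccf_bad$variant_id == "fs1" & ccf_bad$sample_id == "reg"
  ccf_bad$ccf[i] <- 0.6
  ccf_bad$ci_low[i] <- 0.5; ccf_bad$ci_high[i] <- 0.7
  expect_equal(nrow(screen_patient(ccf_bad, fx$loh, fx$samples)), 0L)
  # (ii) LOH absent in a progression biopsy where a variant is dominant
  loh_bad <- fx$loh
  loh_bad$loh[loh_bad$gene == "B2M" & loh_bad$sample_id == "prog1"] <- FALSE
  expect_equal(nrow(screen_patient(fx$ccf, loh_bad, fx$samples)), 0L)
  # (iii) inadequate power in one biopsy
  ccf_pw <- fx$ccf
  ccf_pw$power[ccf_pw$variant_id == "fs2" & ccf_pw$sample_id == "reg"] <- 0.85
  expect_equal(nrow(screen_patient(ccf_pw, fx$loh, fx$samples)), 0L)
  # (iv) relaxing min_nonsilent restores a single-lesion hit
  hits1 <- screen_patient(ccf_pw, fx$loh, fx$samples,
                          pipeline_config(min_nonsilent = 1))
  expect_equal(hits1$gene, "B2M")
})

test_that("the screen is longitudinal: progression and response required", {
  fx <- escape_patient_fixture()
  only_prog <- fx$samples[fx$samples$disease_state == "progression", ]
  expect_error(screen_patient(fx$ccf[fx$ccf$sample_id %in%
                                       only_prog$sample_id, ],
                              fx$loh, only_prog), class =
                 "escapescreen_inapplicable")
  no_prog <- fx$samples[fx$samples$disease_state != "progression", ]
  expect_error(screen_patient(fx$ccf[fx$ccf$sample_id %in%
                                       no_prog$sample_id, ],
                              fx$loh, no_prog), class =
                 "escapescreen_inapplicable")
})

test_that("tightening thresholds never adds hits", {
  fx <- escape_patient_fixture()
  base <- screen_patient(fx$ccf, fx$loh, fx$samples)$gene
  for (cfg in list(pipeline_config(ccf_prog_min = 0.8),
                   pipeline_config(ccf_reg_max = 0.01),
                   pipeline_config(min_nonsilent = 3),
                   pipeline_config(min_power = 0.999))) {
    tighter <- screen_patient(fx$ccf, fx$loh, fx$samples, cfg)$gene
    expect_true(all(tighter %in% base))
  }
})

test_that("the screen matches a brute-force evaluation on random cohorts", {
  set.seed(77)
  samples <- data.frame(
    sample_id = c("a", "b", "c", "d"),
    disease_state = c("baseline", "regression", "progression", "progression"))
  cfg <- pipeline_config()
  for (rep in 1:30) {
    genes <- paste0("G", 1:5)
    vids <- paste0("v", 1:15)
    gene_of <- sample(genes, 15, replace = TRUE)
    ccf <- do.call(rbind, lapply(1:15, function(i) {
      x <- runif(4)
      half <- runif(4, 0, 0.2)
      data.frame(variant_id = vids[i], sample_id = samples$sample_id,
                 gene = gene_of[i],
                 effect = sample(c("missense", "frameshift", "silent"), 1,
                                 prob = c(0.5, 0.3, 0.2)),
                 ccf = x, ci_low = pmax(0, x - half),
                 ci_high = pmin(1, x + half),
                 power = runif(4, 0.85, 1))
    }))
    loh <- expand.grid(sample_id = samples$sample_id, gene = genes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    loh$loh <- runif(nrow(loh)) < 0.5
    got <- screen_patient(ccf, loh, samples, cfg)$gene
    want <- brute_force_screen(ccf, loh, samples, cfg)
    expect_setequal(got, want)
  }
})

test_that("hits sort by progression CCF, descending", {
  sids <- four_biopsy_samples()$sample_id
  two_genes <- rbind(
    ccf_rows("a1", sids, "GA", "missense", c(0.01, 0.01, 0.55, 0.01)),
    ccf_rows("a2", sids, "GA", "missense", c(0.01, 0.01, 0.01, 0.60)),
    ccf_rows("b1", sids, "GB", "frameshift", c(0.01, 0.01, 0.90, 0.01)),
    ccf_rows("b2", sids, "GB", "frameshift", c(0.01, 0.01, 0.01, 0.85)))
  loh <- expand.grid(sample_id = sids, gene = c("GA", "GB"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  loh$loh <- TRUE
  hits <- screen_patient(two_genes, loh, four_biopsy_samples())
  expect_equal(hits$gene, c("GB", "GA"))
})
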