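# Synthetic tumor-cohort generator.
#
# Two generators cover the two study designs the pipeline serves:
#   * simulate_longitudinal_patient(): multi-biopsy patients (baseline,
#     regression, progression) in which an escape lineage may be planted:
#     a focal deletion (minor copy number 0) over an escape gene in every
#     progression biopsy plus two distinct frameshift mutations, each
#     dominant in a different progression biopsy and near-absent
#     elsewhere, on top of state-independent background mutations.
#   * simulate_validation_cohort(): a cross-sectional cohort with
#     per-group LOH prevalence and exponential proportional-hazards
#     survival coupled to LOH status.
# Read counts are binomial at the expected VAF of the allelic CCF model,
# with Poisson-distributed per-locus depth. All randomness is controlled
# by an explicit seed; identical (config, seed) gives identical output.

# hg19 chromosome lengths (autosomes), used to lay out synthetic segments
CHROM_LENGTHS <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566)

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' 17-patient longitudinal cohorts at a target tumor depth of 150x,
#' purities between 0.3 and 0.9, roughly 250 powered mutations per
#' patient, planted escape-frameshift CCFs of 0.74 and 0.55 (each dominant
#' in a distinct progression biopsy, 0.01 elsewhere), and a validation
#' cohort of 69 non-responders vs 26 responders + 10 long-term survivors
#' with LOH prevalences 28.9% / 11.1%.
#'
#' @param n_patients Patients in a longitudinal cohort.
#' @param biopsies_per_patient Biopsies per patient; laid out as one
#'   baseline, one regression, and the remainder progression (minimum 3,
#'   and at least 4 for the two-frameshift escape scenario).
#' @param depth_mean Mean sequencing depth per locus (Poisson).
#' @param purity_range Per-biopsy tumor purity is drawn uniformly from
#'   this interval.
#' @param n_background_mutations State-independent somatic mutations per
#'   patient (two per background gene).
#' @param escape_gene One-row data frame `gene, chrom, start, end`;
#'   default is the B2M locus (hg19).
#' @param escape_scenario `"none"`, `"loh_only"`, or
#'   `"loh_plus_frameshift"`.
#' @param ccf_prog Planted frameshift CCFs, one per escape variant, each
#'   realised in its own progression biopsy.
#' @param ccf_other Planted frameshift CCF everywhere else.
#' @param background_loh_rate Per-sample probability that a background
#'   chromosome is under whole-chromosome LOH.
#' @param clonal_fraction Fraction of background mutations that are
#'   clonal (CCF 1); the rest draw a CCF uniform on \[0.05, 1\].
#' @param n_nonresponders,n_responders,n_long_term Validation-cohort group
#'   sizes.
#' @param loh_prevalence_nonresponder,loh_prevalence_responder LOH
#'   prevalence per response group in the validation cohort.
#' @param survival_hazard_ratio_loh Hazard ratio of death for LOH carriers.
#' @param baseline_hazard Exponential death hazard per day for
#'   non-carriers.
#' @param censoring_rate Target fraction of patients censored (independent
#'   exponential censoring).
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 17L,
                       biopsies_per_patient = 4L,
                       depth_mean = 150,
                       purity_range = c(0.3, 0.9),
                       n_background_mutations = 246L,
                       escape_gene = data.frame(gene = "B2M", chrom = "15",
                                                start = 45003675L,
                                                end = 45011075L),
                       escape_scenario = c("loh_plus_frameshift", "loh_only",
                                           "none"),
                       ccf_prog = c(0.74, 0.55),
                       ccf_other = 0.01,
                       background_loh_rate = 0.1,
                       clonal_fraction = 0.6,
                       n_nonresponders = 69L,
                       n_responders = 26L,
                       n_long_term = 10L,
                       loh_prevalence_nonresponder = 0.289,
                       loh_prevalence_responder = 0.111,
                       survival_hazard_ratio_loh = 2,
                       baseline_hazard = 1 / 1000,
                       censoring_rate = 0.4) {
  cfg <- list(n_patients = as.integer(n_patients),
              biopsies_per_patient = as.integer(biopsies_per_patient),
              depth_mean = depth_mean, purity_range = purity_range,
              n_background_mutations = as.integer(n_background_mutations),
              escape_gene = escape_gene,
              escape_scenario = match.arg(escape_scenario),
              ccf_prog = ccf_prog, ccf_other = ccf_other,
              background_loh_rate = background_loh_rate,
              clonal_fraction = clonal_fraction,
              n_nonresponders = as.integer(n_nonresponders),
              n_responders = as.integer(n_responders),
              n_long_term = as.integer(n_long_term),
              loh_prevalence_nonresponder = loh_prevalence_nonresponder,
              loh_prevalence_responder = loh_prevalence_responder,
              survival_hazard_ratio_loh = survival_hazard_ratio_loh,
              baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate)
  if (cfg$depth_mean <= 0) stop_param("depth_mean must be > 0")
  if (length(cfg$purity_range) != 2L || any(cfg$purity_range <= 0) ||
      any(cfg$purity_range > 1) || diff(cfg$purity_range) < 0)
    stop_param("purity_range must be an increasing interval within (0, 1]")
  for (nm in c("loh_prevalence_nonresponder", "loh_prevalence_responder",
               "censoring_rate", "background_loh_rate", "clonal_fraction"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop_param(nm, " must be in [0, 1]")
  if (cfg$survival_hazard_ratio_loh <= 0)
    stop_param("survival_hazard_ratio_loh must be > 0")
  if (cfg$baseline_hazard <= 0) stop_param("baseline_hazard must be > 0")
  if (any(cfg$ccf_prog < 0 | cfg$ccf_prog > 1) ||
      cfg$ccf_other < 0 || cfg$ccf_other > 1)
    stop_param("planted CCFs must be in [0, 1]")
  if (cfg$biopsies_per_patient < 3L)
    stop_param("biopsies_per_patient must be >= 3 (baseline, regression, ",
               "progression)")
  if (cfg$escape_scenario == "loh_plus_frameshift" &&
      cfg$biopsies_per_patient < 2L + length(cfg$ccf_prog))
    stop_param("need one progression biopsy per planted frameshift")
  class(cfg) <- "sim_config"
  cfg
}

#' Draw alt/ref read counts for a variant
#'
#' Binomial read sampling at the expected VAF of the allelic CCF model:
#' `alt ~ Binomial(depth, expected_vaf(purity, cn_t, m, ccf))`.
#'
#' @inheritParams expected_vaf
#' @param depth Total reads drawn at the locus (vectorised).
#' @param seed Optional seed (the caller's RNG state is preserved).
#' @return Data frame with integer columns `alt_count`, `ref_count`
#'   summing to `depth` rowwise.
#' @export
simulate_reads <- function(ccf, purity, cn_t, m, depth, seed = NULL) {
  if (any(depth < 0)) stop_param("depth must be >= 0")
  p <- expected_vaf(purity, cn_t, m, ccf)
  with_seed(seed, {
    n <- max(length(p), length(depth))
    alt <- rbinom(n, size = depth, prob = p)
    data.frame(alt_count = alt, ref_count = rep(depth, length.out = n) - alt)
  })
}

# background whole-chromosome segments for one sample; `loh_chroms` get
# total CN 1 / minor 0, others are diploid balanced
background_segments <- function(sample_id, loh_chroms) {
  chroms <- names(CHROM_LENGTHS)
  loh <- chroms %in% loh_chroms
  data.frame(sample_id = sample_id, chrom = chroms, start = 1L,
             end = as.integer(CHROM_LENGTHS),
             total_cn = ifelse(loh, 1, 2),
             major_cn = 1L, minor_cn = ifelse(loh, 0L, 1L),
             copy_ratio = ifelse(loh, 0.5, 1.0))
}

# carve a focal deletion (total 1, minor 0) spanning the escape locus
# +/- 5 Mb out of a sample's chr segment
plant_deletion <- function(segments, locus) {
  chrom_len <- as.integer(CHROM_LENGTHS[[locus$chrom]])
  les_start <- max(1L, locus$start - 5000000L)
  les_end <- min(chrom_len, locus$end + 5000000L)
  i <- which(segments$chrom == locus$chrom)
  base <- segments[i[1L], ]
  pieces <- list()
  if (les_start > 1L) {
    left <- base; left$end <- les_start - 1L; pieces <- c(pieces, list(left))
  }
  les <- base
  les$start <- les_start; les$end <- les_end
  les$total_cn <- 1; les$major_cn <- 1L; les$minor_cn <- 0L
  les$copy_ratio <- 0.5
  pieces <- c(pieces, list(les))
  if (les_end < chrom_len) {
    right <- base; right$start <- les_end + 1L; pieces <- c(pieces, list(right))
  }
  rbind(segments[-i[1L], ], do.call(rbind, pieces))
}

# total copy number of the segment containing (chrom, pos) in one sample;
# diploid fallback when no segment covers the position
cn_lookup <- function(segments, sample_id, chrom, pos) {
  key <- paste(segments$sample_id, segments$chrom, sep = "\r")
  q <- paste(sample_id, chrom, sep = "\r")
  out <- rep(2, length(q))
  for (k in unique(q)) {
    seg <- segments[key == k, , drop = FALSE]
    sel <- q == k
    if (!nrow(seg)) next
    hit <- findInterval(pos[sel], seg$start)
    ok <- hit >= 1 & pos[sel] <= seg$end[pmax(hit, 1)]
    out[sel][ok] <- seg$total_cn[hit[ok]]
  }
  out
}

#' Simulate one longitudinal multi-biopsy patient
#'
#' Generates a patient fragment: biopsy metadata (one baseline, one
#' regression, the rest progression), per-sample allele-specific segments,
#' and a force-called variant table covering every variant in every
#' biopsy. Background mutations (two per background gene) have
#' state-independent CCFs. Under the `"loh_plus_frameshift"` scenario the
#' progression biopsies carry a focal deletion over the escape gene plus
#' one planted frameshift per element of `ccf_prog`, each at its target
#' CCF in its own progression biopsy and at `ccf_other` elsewhere; under
#' `"loh_only"` only the deletion is planted; under `"none"` the escape
#' gene is untouched.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; identical (config, seed) yields identical
#'   output.
#' @param patient_id Identifier used in all generated tables.
#' @return A list of class `"synthetic_patient"` with elements `samples`,
#'   `variants`, `segments`, `gene_loci`, and `truth` (planted gene,
#'   variant keys, per-sample planted CCFs and LOH status).
#' @export
simulate_longitudinal_patient <- function(config = sim_config(), seed = 1L,
                                          patient_id = "P001") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    nb <- config$biopsies_per_patient
    states <- c("baseline", "regression", rep("progression", nb - 2L))
    samples <- data.frame(
      sample_id = sprintf("%s_S%02d", patient_id, seq_len(nb)),
      patient_id = patient_id,
      timepoint_days = as.integer(round(seq(-14, 420, length.out = nb))),
      disease_state = states,
      purity = round(runif(nb, config$purity_range[1], config$purity_range[2]), 3),
      ploidy = 2)
    prog_ids <- samples$sample_id[states == "progression"]

    # background LOH chromosomes per sample (escape chromosome excluded so
    # the planted lesion is the only LOH over the escape gene)
    bg_chroms <- setdiff(names(CHROM_LENGTHS), config$escape_gene$chrom)
    seg_list <- lapply(seq_len(nb), function(i) {
      loh_chroms <- bg_chroms[runif(length(bg_chroms)) < config$background_loh_rate]
      background_segments(samples$sample_id[i], loh_chroms)
    })
    plant <- config$escape_scenario != "none"
    if (plant) {
      for (i in which(states == "progression"))
        seg_list[[i]] <- plant_deletion(seg_list[[i]], config$escape_gene)
    }
    segments <- do.call(rbind, seg_list)
    segments <- segments[order(segments$sample_id, segments$chrom,
                               segments$start), ]
    rownames(segments) <- NULL

    # background mutations: two per gene, state-independent CCFs, on the
    # retained allele (multiplicity 1)
    n_mut <- config$n_background_mutations
    n_genes <- ceiling(n_mut / 2)
    gene_chrom <- sample(bg_chroms, n_genes, replace = TRUE)
    gene_center <- vapply(gene_chrom, function(ch)
      as.integer(sample.int(CHROM_LENGTHS[[ch]] - 100000L, 1L)) + 50000L,
      integer(1))
    gene_loci <- data.frame(gene = sprintf("BG%04d", seq_len(n_genes)),
                            chrom = gene_chrom,
                            start = gene_center - 25000L,
                            end = gene_center + 25000L)
    mut_gene_idx <- rep(seq_len(n_genes), each = 2L)[seq_len(n_mut)]
    mut <- data.frame(
      gene = gene_loci$gene[mut_gene_idx],
      chrom = gene_loci$chrom[mut_gene_idx],
      pos = gene_center[mut_gene_idx] +
        sample(-20000:20000, n_mut, replace = TRUE),
      ref = sample(c("A", "C", "G", "T"), n_mut, replace = TRUE),
      effect = sample(c("missense", "silent", "nonsense", "splice_site"),
                      n_mut, replace = TRUE, prob = c(0.6, 0.25, 0.1, 0.05)))
    mut$alt <- vapply(mut$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    clonal <- runif(n_mut) < config$clonal_fraction
    mut$true_ccf <- ifelse(clonal, 1, round(runif(n_mut, 0.05, 1), 3))

    truth <- list(patient_id = patient_id, scenario = config$escape_scenario,
                  gene = if (plant) config$escape_gene$gene else NA_character_,
                  loh_samples = if (plant) prog_ids else character(0),
                  variants = NULL)
    planted <- NULL
    if (config$escape_scenario == "loh_plus_frameshift") {
      k <- length(config$ccf_prog)
      gene <- config$escape_gene
      planted <- data.frame(
        gene = gene$gene, chrom = gene$chrom,
        pos = as.integer(gene$start + 70L + 3L * seq_len(k)),
        ref = vapply(seq_len(k), function(i)
          paste(sample(c("A", "C", "G", "T"), 2L, replace = TRUE),
                collapse = ""), character(1)),
        effect = "frameshift")
      planted$alt <- substr(planted$ref, 1L, 1L)   # 1-bp deletions
      # CCF matrix: variant i dominant only in progression biopsy i
      planted_ccf <- matrix(config$ccf_other, nrow = k, ncol = nb,
                            dimnames = list(NULL, samples$sample_id))
      for (i in seq_len(k)) planted_ccf[i, prog_ids[i]] <- config$ccf_prog[i]
      truth$variants <- data.frame(
        variant_id = variant_key(planted$chrom, planted$pos, planted$ref,
                                 planted$alt),
        planted_ccf)
    }

    all_mut <- rbind(cbind(mut[, c("gene", "chrom", "pos", "ref", "alt",
                                   "effect")], planted_bg = TRUE),
                     if (!is.null(planted))
                       cbind(planted[, c("gene", "chrom", "pos", "ref", "alt",
                                         "effect")], planted_bg = FALSE))
    n_all <- nrow(all_mut)

    # force-called counts: every variant in every sample
    rows <- vector("list", nb)
    for (i in seq_len(nb)) {
      sid <- samples$sample_id[i]
      ccf_i <- rep(NA_real_, n_all)
      ccf_i[all_mut$planted_bg] <- mut$true_ccf
      if (!is.null(planted))
        ccf_i[!all_mut$planted_bg] <- truth$variants[, 1L + i]
      cn <- cn_lookup(segments[segments$sample_id == sid, ], sid,
                      all_mut$chrom, all_mut$pos)
      depth <- rpois(n_all, config$depth_mean)
      reads <- simulate_reads(ccf_i, samples$purity[i], cn, m = 1,
                              depth = depth)
      # caller agreement concentrates at the detection margin: variants
      # with ample alt support are reported by >= 2 of 3 callers, those
      # near the 3-read limit split the callers
      marginal <- sample(1:3, n_all, replace = TRUE, prob = c(0.3, 0.3, 0.4))
      solid <- sample(2:3, n_all, replace = TRUE, prob = c(0.1, 0.9))
      n_callers <- ifelse(reads$alt_count >= 8L, solid,
                          ifelse(reads$alt_count >= 3L, marginal, 0L))
      caller_sets <- c("", "strelka", "strelka;mutect",
                       "strelka;mutect;vardict")
      rows[[i]] <- data.frame(
        patient_id = patient_id, sample_id = sid,
        chrom = all_mut$chrom, pos = all_mut$pos, ref = all_mut$ref,
        alt = all_mut$alt, ref_count = reads$ref_count,
        alt_count = reads$alt_count, gene = all_mut$gene,
        effect = all_mut$effect, callers = caller_sets[n_callers + 1L])
    }
    variants <- do.call(rbind, rows)
    rownames(variants) <- NULL
    gene_loci <- rbind(gene_loci,
                       config$escape_gene[, c("gene", "chrom", "start", "end")])

    out <- list(samples = samples, variants = variants, segments = segments,
                gene_loci = gene_loci, truth = truth)
    class(out) <- "synthetic_patient"
    out
  })
}

#' Simulate a cross-sectional validation cohort
#'
#' Per-patient LOH status is Bernoulli with the group-specific prevalence;
#' death times are exponential with the baseline hazard multiplied by
#' `survival_hazard_ratio_loh` for LOH carriers; censoring is an
#' independent exponential whose rate is matched to the target censoring
#' fraction.
#'
#' @inheritParams simulate_longitudinal_patient
#' @return A list of class `"synthetic_cohort"` with elements `clinical`
#'   (a [read_clinical()]-layout data frame) and `loh_status` (named
#'   logical vector of planted LOH carriers).
#' @export
simulate_validation_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    groups <- rep(c("nonresponder", "responder", "long_term_survivor"),
                  times = c(config$n_nonresponders, config$n_responders,
                            config$n_long_term))
    n <- length(groups)
    prev <- ifelse(groups == "nonresponder",
                   config$loh_prevalence_nonresponder,
                   config$loh_prevalence_responder)
    loh <- runif(n) < prev
    hazard <- config$baseline_hazard *
      ifelse(loh, config$survival_hazard_ratio_loh, 1)
    t_death <- rexp(n, rate = hazard)
    if (config$censoring_rate > 0) {
      # exponential censoring rate giving the target censored fraction
      # against the baseline death hazard
      cens_rate <- config$baseline_hazard * config$censoring_rate /
        (1 - config$censoring_rate)
      t_cens <- rexp(n, rate = cens_rate)
    } else t_cens <- rep(Inf, n)
    clinical <- data.frame(
      patient_id = sprintf("V%03d", seq_len(n)),
      response_group = groups,
      os_days = round(pmin(t_death, t_cens), 1),
      os_event = as.integer(t_death <= t_cens))
    out <- list(clinical = clinical,
                loh_status = setNames(loh, clinical$patient_id),
                config = config)
    class(out) <- "synthetic_cohort"
    out
  })
}

#' Write a synthetic patient's tables to canonical TSVs
#'
#' @param patient A `"synthetic_patient"` object.
#' @param dir Output directory (created if absent); writes
#'   `samples.tsv`, `variants.tsv`, `segments.tsv`, `gene_loci.tsv`, and
#'   `truth.yaml` (the latter only when the `yaml` package is available).
#' @return `dir`, invisibly.
#' @export
write_synthetic_patient <- function(patient, dir) {
  stopifnot(inherits(patient, "synthetic_patient"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_samples(patient$samples, file.path(dir, "samples.tsv"))
  write_variant_table(patient$variants, file.path(dir, "variants.tsv"))
  write_segments(patient$segments, file.path(dir, "segments.tsv"))
  write_gene_loci(patient$gene_loci, file.path(dir, "gene_loci.tsv"))
  if (requireNamespace("yaml", quietly = TRUE)) {
    tr <- patient$truth
    tr$variants <- if (!is.null(tr$variants)) as.list(tr$variants)
    yaml::write_yaml(tr, file.path(dir, "truth.yaml"))
  }
  invisible(dir)
}
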