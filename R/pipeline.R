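# End-to-end per-patient pipeline: consensus vote -> force-called union
# matrix -> CCF/power estimation -> gene-level LOH -> escape screen.

#' Split a variant table into per-caller call sets
#'
#' Inverts the semicolon-joined `callers` column of a variant table into
#' the named list [consensus_vote()] expects. Rows with an empty `callers`
#' field (force-called counts at loci no caller reported in that sample)
#' contribute to no call set.
#'
#' @param variants Data frame in the [read_variant_table()] layout.
#' @return Named list of data frames, one per caller.
#' @export
split_caller_sets <- function(variants) {
  callers <- strsplit(variants$callers, ";", fixed = TRUE)
  idx <- rep(seq_len(nrow(variants)), lengths(callers))
  caller <- unlist(callers)
  keep <- nzchar(caller)
  split(variants[idx[keep], setdiff(names(variants), "callers"), drop = FALSE],
        caller[keep])
}

#' Estimate CCF, confidence limits and power for a force-called matrix
#'
#' Annotates every (variant, sample) cell of a force-called count matrix
#' with the local total copy number (from the sample's segments, diploid
#' where unsegmented), an estimated multiplicity, the CCF point estimate
#' with exact 95% limits ([estimate_ccf()]), and the clonal detection
#' power at the cell's observed depth ([detection_power()]).
#'
#' @param fc Force-called long-format matrix from
#'   [build_force_call_matrix()] (or any data frame with columns
#'   `variant_id, sample_id, chrom, pos, gene, effect, alt_count,
#'   ref_count`).
#' @param samples Sample metadata with columns `sample_id, purity`.
#' @param segments Segment table covering the samples.
#' @param k_min Minimum supporting reads defining detection (default 3).
#' @return `fc` with added columns `purity, cn_t, vaf, m, ccf, ci_low,
#'   ci_high, power`.
#' @export
estimate_ccf_matrix <- function(fc, samples, segments, k_min = 3L) {
  idx <- match(fc$sample_id, samples$sample_id)
  if (anyNA(idx))
    stop_param("samples table lacks metadata for sample(s): ",
               paste(unique(fc$sample_id[is.na(idx)]), collapse = ", "))
  purity <- samples$purity[idx]
  cn_t <- cn_lookup(segments, fc$sample_id, fc$chrom, fc$pos)
  depth <- fc$alt_count + fc$ref_count
  if (any(depth == 0))
    stop_param("zero force-called depth for variant ",
               fc$variant_id[which(depth == 0)[1L]])
  m <- estimate_multiplicity(fc$alt_count / depth, purity, cn_t)
  est <- estimate_ccf(fc$alt_count, fc$ref_count, purity, cn_t, m)
  fc$purity <- purity
  fc$cn_t <- cn_t
  fc$vaf <- est$vaf
  fc$m <- m
  fc$ccf <- est$ccf
  fc$ci_low <- est$ci_low
  fc$ci_high <- est$ci_high
  fc$power <- detection_power(depth, purity, cn_t, m = 1L, k_min = k_min)
  fc
}

#' Run the full escape screen on one synthetic or assembled patient
#'
#' Chains the pipeline stages for a single patient: per-sample consensus
#' voting over the caller sets, patient-wide union with force-called
#' counts, CCF/power estimation, gene-level LOH calling over the loci of
#' all candidate genes plus the configured panel, and the longitudinal
#' screen.
#'
#' @param patient A `"synthetic_patient"` object, or a list with elements
#'   `samples`, `variants`, `segments`, `gene_loci` in the canonical
#'   layouts.
#' @param config A [pipeline_config()] object.
#' @return The [screen_patient()] hit table, with the annotated CCF matrix
#'   attached as attribute `"ccf"` and the LOH calls as attribute
#'   `"loh_calls"`.
#' @export
run_patient_screen <- function(patient, config = pipeline_config()) {
  variants <- patient$variants
  samples <- patient$samples
  if (config$min_alt_count > 0L)
    variants <- variants[variants$alt_count >= config$min_alt_count |
                           !nzchar(variants$callers), , drop = FALSE]
  consensus <- consensus_vote(split_caller_sets(variants),
                              min_callers = config$min_callers)
  if (nrow(consensus) == 0L)
    return(screen_patient(
      data.frame(variant_id = character(), sample_id = character(),
                 gene = character(), effect = character(), ccf = numeric(),
                 ci_low = numeric(), ci_high = numeric(), power = numeric()),
      data.frame(sample_id = character(), gene = character(), loh = logical()),
      samples, config))
  fc <- build_force_call_matrix(consensus, variants, samples$sample_id)
  ccf <- estimate_ccf_matrix(fc, samples, patient$segments,
                             k_min = config$k_min)
  genes <- union(unique(ccf$gene), config$gene_panel)
  loci <- patient$gene_loci[patient$gene_loci$gene %in% genes, , drop = FALSE]
  loh_calls <- call_loh_matrix(patient$segments, loci,
                               min_covered_fraction = config$loh_covered_fraction)
  hits <- screen_patient(ccf, loh_calls, samples, config)
  attr(hits, "ccf") <- ccf
  attr(hits, "loh_calls") <- loh_calls
  hits
}
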