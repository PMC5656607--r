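# Gene-level loss-of-heterozygosity calling from allele-specific segments.
#
# A gene has LOH in a sample when at least `min_covered_fraction` of its
# length lies inside segments with minor allele copy number zero. All
# interval arithmetic is on 1-based closed intervals. Overlapping segments
# are first resolved first-wins in (chrom, start) order; the resolved
# segments are pairwise disjoint, so the union of their intersections with
# the gene locus is just the sum of the pairwise intersection widths.

resolve_overlaps_first_wins <- function(segments) {
  # trim each segment to start after the previous segment's end, per
  # (sample, chrom), in (sample_id, chrom, start) order
  o <- order(segments$sample_id, segments$chrom, segments$start)
  segments <- segments[o, , drop = FALSE]
  grp <- paste(segments$sample_id, segments$chrom, sep = "\r")
  new_start <- segments$start
  if (nrow(segments) > 1L) {
    run_end <- segments$end[1L]
    for (i in seq_len(nrow(segments))[-1L]) {
      if (grp[i] == grp[i - 1L]) {
        new_start[i] <- max(new_start[i], run_end + 1L)
        run_end <- max(run_end, segments$end[i])
      } else run_end <- segments$end[i]
    }
  }
  segments$start <- new_start
  segments[segments$start <= segments$end, , drop = FALSE]
}

# worker over already-resolved (disjoint) segments of one sample
loh_one_locus <- function(seg, sample_id, locus, min_covered_fraction) {
  seg <- seg[seg$chrom == locus$chrom, , drop = FALSE]
  gene_len <- locus$end - locus$start + 1L
  if (nrow(seg) == 0L) {
    warning("no segments on chromosome ", locus$chrom, " for sample ",
            sample_id, "; treating gene ", locus$gene,
            " as having no LOH evidence", call. = FALSE)
    return(data.frame(sample_id = sample_id, gene = locus$gene, loh = FALSE,
                      covered_fraction = 0, mean_copy_ratio = NA_real_,
                      both_copies_lost = FALSE))
  }
  ov <- pmax(0, pmin(seg$end, locus$end) - pmax(seg$start, locus$start) + 1)
  covered <- sum(ov[seg$minor_cn == 0L]) / gene_len
  lost_both <- sum(ov[seg$total_cn == 0]) / gene_len
  mean_cr <- if (any(ov > 0)) sum(seg$copy_ratio * ov) / sum(ov) else NA_real_
  data.frame(sample_id = sample_id, gene = locus$gene,
             loh = covered >= min_covered_fraction,
             covered_fraction = covered, mean_copy_ratio = mean_cr,
             both_copies_lost = lost_both >= min_covered_fraction)
}

#' Call loss of heterozygosity over a gene locus in one sample
#'
#' Computes the fraction of the gene interval covered by minor-copy-zero
#' segments and calls LOH when that fraction reaches
#' `min_covered_fraction`. Overlapping segments are resolved first-wins in
#' `(chrom, start)` order before any arithmetic, so the call is invariant
#' to splitting a segment into adjacent pieces with identical copy number.
#'
#' @param segments Data frame of one sample's segments in the
#'   [read_segments()] layout.
#' @param locus One-row data frame (or list) with `gene, chrom, start, end`,
#'   1-based inclusive.
#' @param min_covered_fraction Gene-length fraction that must be minor-copy
#'   zero to call LOH (default 1.0: the whole gene).
#' @return A one-row data frame: `sample_id`, `gene`, `loh` (logical),
#'   `covered_fraction`, `mean_copy_ratio` (length-weighted over all
#'   segments overlapping the locus; `NA` when none), and
#'   `both_copies_lost` (the same coverage rule applied to total copy
#'   number zero, i.e. homozygous deletion). A locus on a chromosome with
#'   no segments yields `loh = FALSE`, `covered_fraction = 0` and a
#'   warning: absence of segments is treated as absence of evidence.
#' @examples
#' seg <- data.frame(sample_id = "S1", chrom = "15", start = 1L,
#'                   end = 100e6L, total_cn = 1, major_cn = 1L,
#'                   minor_cn = 0L, copy_ratio = 0.56)
#' b2m <- data.frame(gene = "B2M", chrom = "15",
#'                   start = 45003675L, end = 45011075L)
#' call_gene_loh(seg, b2m)
#' @export
call_gene_loh <- function(segments, locus, min_covered_fraction = 1.0) {
  if (min_covered_fraction < 0 || min_covered_fraction > 1)
    stop_param("min_covered_fraction must be in [0, 1]")
  locus <- as.list(locus)
  sample_id <- unique(segments$sample_id)
  if (length(sample_id) > 1L)
    stop_param("call_gene_loh() expects segments of a single sample; got ",
               length(sample_id))
  if (length(sample_id) == 0L) sample_id <- NA_character_
  loh_one_locus(resolve_overlaps_first_wins(segments), sample_id, locus,
                min_covered_fraction)
}

#' Call gene-level LOH across samples and a gene panel
#'
#' Applies the [call_gene_loh()] rule to every (sample, gene) combination,
#' resolving each sample's segment overlaps once.
#'
#' @param segments Data frame of segments for one or more samples.
#' @param loci Data frame of gene loci in the [read_gene_loci()] layout.
#' @inheritParams call_gene_loh
#' @return Data frame with one row per sample x gene.
#' @export
call_loh_matrix <- function(segments, loci, min_covered_fraction = 1.0) {
  if (min_covered_fraction < 0 || min_covered_fraction > 1)
    stop_param("min_covered_fraction must be in [0, 1]")
  samples <- unique(segments$sample_id)
  n_loci <- nrow(loci)
  out <- lapply(samples, function(s) {
    seg <- resolve_overlaps_first_wins(
      segments[segments$sample_id == s, , drop = FALSE])
    by_chrom <- split(seg[c("start", "end", "minor_cn", "total_cn",
                            "copy_ratio")], seg$chrom)
    covered <- lost <- numeric(n_loci)
    mean_cr <- rep(NA_real_, n_loci)
    for (i in seq_len(n_loci)) {
      sc <- by_chrom[[loci$chrom[i]]]
      if (is.null(sc)) {
        warning("no segments on chromosome ", loci$chrom[i], " for sample ",
                s, "; treating gene ", loci$gene[i],
                " as having no LOH evidence", call. = FALSE)
        next
      }
      ov <- pmax(0, pmin(sc$end, loci$end[i]) - pmax(sc$start, loci$start[i]) + 1)
      gene_len <- loci$end[i] - loci$start[i] + 1
      covered[i] <- sum(ov[sc$minor_cn == 0L]) / gene_len
      lost[i] <- sum(ov[sc$total_cn == 0]) / gene_len
      if (any(ov > 0)) mean_cr[i] <- sum(sc$copy_ratio * ov) / sum(ov)
    }
    data.frame(sample_id = s, gene = loci$gene,
               loh = covered >= min_covered_fraction,
               covered_fraction = covered, mean_copy_ratio = mean_cr,
               both_copies_lost = lost >= min_covered_fraction)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate per-sample LOH calls to patient level
#'
#' @param loh_calls Data frame of per-sample calls for one gene in one
#'   patient (needs a logical `loh` column; one row per sample).
#' @param rule `"any_sample"` (default): LOH in at least one biopsy;
#'   `"all_samples"`: LOH in every biopsy.
#' @return Single logical.
#' @export
patient_loh_status <- function(loh_calls, rule = c("any_sample", "all_samples")) {
  rule <- match.arg(rule)
  if (NROW(loh_calls) < 1L) stop_param("at least one sample-level call required")
  loh <- if (is.data.frame(loh_calls)) loh_calls$loh else as.logical(loh_calls)
  if (anyNA(loh)) stop_param("LOH calls contain NA")
  if (rule == "any_sample") any(loh) else all(loh)
}
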