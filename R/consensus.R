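# Consensus voting over per-caller somatic call sets and the force-called
# union count matrix across a patient's biopsies.

#' Classify a variant effect as protein-altering
#'
#' @param effect Character vector of effect labels drawn from [EFFECT_LEVELS].
#' @return Logical vector: `TRUE` for missense, nonsense, frameshift,
#'   splice-site and other non-silent effects; `FALSE` for silent.
#' @export
is_nonsilent <- function(effect) {
  bad <- setdiff(unique(effect), EFFECT_LEVELS)
  if (length(bad))
    stop_param("unknown effect class(es): ", paste(bad, collapse = ", "))
  effect %in% NONSILENT_EFFECTS
}

#' Consensus vote over per-caller variant sets
#'
#' Keeps variants reported by at least `min_callers` independent callers.
#' Voting is per sample: a variant's identity is
#' `(sample_id, chrom, pos, ref, alt)`, so support in one biopsy does not
#' carry over to another (the force-calling step propagates kept variants
#' patient-wide instead).
#'
#' @param calls_by_caller Named list, one data frame per caller, each with
#'   columns `sample_id, chrom, pos, ref, alt` (extra columns are carried
#'   along from the first caller listing the variant).
#' @param min_callers Minimum number of callers that must report a variant
#'   (default 2).
#' @return A data frame of the surviving variants with an added integer
#'   column `n_callers` and a `callers` column (semicolon-joined caller
#'   names). Lowering `min_callers` never removes variants.
#' @export
consensus_vote <- function(calls_by_caller, min_callers = 2L) {
  if (!is.list(calls_by_caller) || length(calls_by_caller) < 1L)
    stop_param("`calls_by_caller` must be a non-empty named list")
  if (is.null(names(calls_by_caller)) || any(!nzchar(names(calls_by_caller))))
    stop_param("`calls_by_caller` must be named by caller")
  if (!is.numeric(min_callers) || min_callers < 1L)
    stop_param("min_callers must be >= 1")
  key_cols <- c("sample_id", "chrom", "pos", "ref", "alt")
  pieces <- lapply(names(calls_by_caller), function(cl) {
    df <- calls_by_caller[[cl]]
    missing <- setdiff(key_cols, names(df))
    if (length(missing))
      stop_param("caller '", cl, "' table lacks column(s): ",
                 paste(missing, collapse = ", "))
    df$.caller <- cl
    df
  })
  all <- do.call(rbind, lapply(pieces, function(d)
    d[, union(key_cols, names(d)), drop = FALSE]))
  key <- do.call(paste, c(all[key_cols], sep = "\r"))
  first <- !duplicated(key)
  votes <- tapply(all$.caller, key, function(x) sort(unique(x)))
  out <- all[first, setdiff(names(all), ".caller"), drop = FALSE]
  k <- key[first]
  out$n_callers <- vapply(votes[k], length, integer(1))
  out$callers <- vapply(votes[k], paste, character(1), collapse = ";")
  out <- out[out$n_callers >= min_callers, , drop = FALSE]
  rownames(out) <- NULL
  log_info("consensus vote kept %d of %d distinct variants", nrow(out),
           sum(first))
  out
}

#' Build the force-called union count matrix for one patient
#'
#' Takes the union of consensus variants across a patient's biopsies and
#' fills a complete variant-by-sample grid of (alt, ref) read counts from a
#' force-calling lookup, so that a variant called in only one biopsy still
#' has an observed (possibly zero-alt) count in every other biopsy. No cell
#' may be missing.
#'
#' @param variants Data frame of consensus variants for the patient, with
#'   columns `chrom, pos, ref, alt` plus annotation columns (`gene`,
#'   `effect`, ...) that are constant per variant and carried along.
#' @param counts Data frame of force-called read counts with columns
#'   `sample_id, chrom, pos, ref, alt, alt_count, ref_count`; it must cover
#'   every (variant, sample) pair.
#' @param sample_ids Character vector of all of the patient's sample IDs
#'   (the matrix columns).
#' @return A long-format data frame of class `"force_call_matrix"` with one
#'   row per variant x sample: key columns, annotations, `alt_count`,
#'   `ref_count`. Row order is variants (first appearance) x `sample_ids`.
#' @export
build_force_call_matrix <- function(variants, counts, sample_ids) {
  key_cols <- c("chrom", "pos", "ref", "alt")
  if (!all(key_cols %in% names(variants)))
    stop_param("`variants` needs columns chrom, pos, ref, alt")
  if (!all(c("sample_id", key_cols, "alt_count", "ref_count") %in% names(counts)))
    stop_param("`counts` needs columns sample_id, chrom, pos, ref, alt, ",
               "alt_count, ref_count")
  if (length(sample_ids) < 1L) stop_param("`sample_ids` must be non-empty")
  vkey <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  uniq <- !duplicated(vkey)
  variants <- variants[uniq, , drop = FALSE]
  vkey <- vkey[uniq]
  anno_cols <- intersect(c("gene", "effect", "patient_id"), names(variants))
  grid <- data.frame(
    variant_id = rep(vkey, each = length(sample_ids)),
    sample_id = rep(sample_ids, times = length(vkey)),
    variants[rep(seq_along(vkey), each = length(sample_ids)),
             c(key_cols, anno_cols), drop = FALSE],
    row.names = NULL, check.names = FALSE)
  ckey <- paste(variant_key(counts$chrom, counts$pos, counts$ref, counts$alt),
                counts$sample_id, sep = "@")
  gkey <- paste(grid$variant_id, grid$sample_id, sep = "@")
  idx <- match(gkey, ckey)
  if (anyNA(idx)) {
    miss <- gkey[which(is.na(idx))[1L]]
    stop_param("force-call counts missing for (variant, sample) pair: ",
               sub("@", " in sample ", miss, fixed = TRUE))
  }
  grid$alt_count <- as.integer(counts$alt_count[idx])
  grid$ref_count <- as.integer(counts$ref_count[idx])
  class(grid) <- c("force_call_matrix", class(grid))
  log_info("force-call matrix: %d variants x %d samples", length(vkey),
           length(sample_ids))
  grid
}
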