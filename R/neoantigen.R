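# Neoantigen binder classification from percentile ranks, and gene-level
# neoantigen load.
#
# Percentile rank semantics: a peptide with rank r binds its HLA allele
# with higher affinity than r% of random natural peptides, so smaller is
# stronger. A mutant peptide is only a neoantigen candidate when the
# corresponding wild-type peptide is itself a non-binder (rank > wt_rank),
# otherwise tolerance is expected.

#' Classify mutant peptides as strong/weak binders
#'
#' @param mut_rank,wt_rank Percentile ranks in \[0, 100\] of the mutant and
#'   corresponding wild-type peptide (vectorised).
#' @param thresholds Named list with elements `strong` (default 0.5),
#'   `weak` (default 2) and `wt` (default 2): a mutant is a strong binder
#'   when `mut_rank < strong`, a weak binder when
#'   `strong <= mut_rank < weak`, and in either case only when
#'   `wt_rank > wt`.
#' @return Character vector over `{"strong", "weak", "none"}`.
#' @examples
#' classify_binder(c(0.3, 1.5, 1.5), c(5, 5, 1))
#' @export
classify_binder <- function(mut_rank, wt_rank,
                            thresholds = list(strong = 0.5, weak = 2, wt = 2)) {
  if (any(mut_rank < 0 | mut_rank > 100, na.rm = FALSE) || anyNA(mut_rank))
    stop_param("mut_rank must be a percentile in [0, 100]")
  if (any(wt_rank < 0 | wt_rank > 100) || anyNA(wt_rank))
    stop_param("wt_rank must be a percentile in [0, 100]")
  wt_ok <- wt_rank > thresholds$wt
  ifelse(wt_ok & mut_rank < thresholds$strong, "strong",
         ifelse(wt_ok & mut_rank < thresholds$weak, "weak", "none"))
}

#' Gene-level neoantigen load
#'
#' Counts the mutated genes predicted to give rise to at least one
#' neoantigen (a strong or weak binder peptide). Duplicate peptide rows do
#' not change the count.
#'
#' @param records Data frame with columns `gene, mut_rank, wt_rank` (one
#'   row per peptide x HLA allele), or with a precomputed `binder_class`
#'   column.
#' @param thresholds Passed to [classify_binder()] when `binder_class` is
#'   absent.
#' @return Integer: number of distinct genes with at least one binder.
#' @export
neoantigen_load <- function(records,
                            thresholds = list(strong = 0.5, weak = 2, wt = 2)) {
  if (NROW(records) == 0L) return(0L)
  cls <- records$binder_class %||%
    classify_binder(records$mut_rank, records$wt_rank, thresholds)
  length(unique(records$gene[cls %in% c("strong", "weak")]))
}
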