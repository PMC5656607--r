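# The longitudinal resistance-driver screen.
#
# A gene is reported for a patient when, over the patient's biopsy series:
#   (a) it carries at least `min_nonsilent` distinct non-silent variants
#       that are powered (detection power >= min_power) in every biopsy;
#   (b) each such variant is compatible with a dominant clone in at least
#       one progression biopsy (95% CI upper bound >= ccf_prog_min) and
#       compatible with absence in every baseline/regression biopsy
#       (95% CI lower bound <= ccf_reg_max);
#   (c) the gene is under LOH in every progression biopsy where one of
#       those variants is dominant.
# Dominance and absence are judged on the confidence interval rather than
# the point estimate so that a truly dominant clone near the threshold is
# not discarded by binomial read noise; the point estimates are reported.

#' Filter variants to those powered in every biopsy
#'
#' @param ccf Data frame of per-variant, per-sample CCF estimates with
#'   columns `variant_id, sample_id, power` (as produced by
#'   [estimate_ccf_matrix()]).
#' @param sample_ids Sample IDs that must all be covered; defaults to every
#'   sample present in `ccf`. A (variant, sample) pair with no power value
#'   is an error.
#' @param min_power Per-sample detection power threshold (default 0.9).
#' @return Character vector of `variant_id`s powered at `min_power` or
#'   better in all samples.
#' @export
power_filter <- function(ccf, sample_ids = unique(ccf$sample_id),
                         min_power = 0.9) {
  vids <- unique(ccf$variant_id)
  key <- paste(ccf$variant_id, ccf$sample_id, sep = "@")
  need <- expand.grid(variant_id = vids, sample_id = sample_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(paste(need$variant_id, need$sample_id, sep = "@"), key)
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1L]
    stop_param("no power value for variant ", need$variant_id[i],
               " in sample ", need$sample_id[i])
  }
  pw <- ccf$power[idx]
  if (anyNA(pw)) stop_param("power values contain NA")
  ok <- tapply(pw >= min_power, need$variant_id, all)
  kept <- names(ok)[ok]
  log_info("power filter (>= %.2f in all samples): %d of %d variants kept",
           min_power, length(kept), length(vids))
  # preserve first-appearance order
  vids[vids %in% kept]
}

#' Screen one patient's longitudinal CCF matrix for escape drivers
#'
#' Applies the resistance-screen criteria (see the package vignette) to a
#' complete variant x biopsy CCF matrix plus per-sample gene-level LOH
#' calls. The screen is longitudinal: the patient must have at least one
#' progression and at least one baseline/regression biopsy, otherwise an
#' inapplicable-screen error is raised.
#'
#' @param ccf Data frame with columns `variant_id, sample_id, gene, effect,
#'   ccf, ci_low, ci_high, power`, covering every variant in every biopsy
#'   (the force-called matrix passed through [estimate_ccf_matrix()]).
#' @param loh_calls Data frame of per-sample LOH calls (columns
#'   `sample_id, gene, loh`) covering at least the genes carrying candidate
#'   variants in every progression sample.
#' @param samples Data frame with columns `sample_id, disease_state` for
#'   the patient's biopsies.
#' @param config An [pipeline_config()] object; the thresholds used are
#'   `min_power`, `ccf_prog_min`, `ccf_reg_max`, `min_nonsilent`.
#' @return A data frame of class `"escape_screen_hits"`, one row per hit
#'   gene, sorted by `max_ccf_progression` descending, with columns
#'   `gene, n_nonsilent, loh_in_progression, max_ccf_progression,
#'   max_ccf_nonprogression, passing_variants` (semicolon-joined variant
#'   IDs). Zero rows when no gene satisfies all criteria. The per-gene
#'   evaluation of each criterion is attached as attribute `"audit"`.
#' @export
screen_patient <- function(ccf, loh_calls, samples,
                           config = pipeline_config()) {
  states <- samples$disease_state
  if (!any(states == "progression") || all(states == "progression"))
    stop(errorCondition(
      paste0("screen inapplicable: need at least one progression and one ",
             "baseline/regression biopsy (got states: ",
             paste(states, collapse = ", "), ")"),
      class = c("escapescreen_inapplicable", "escapescreen_error")))
  prog_ids <- samples$sample_id[states == "progression"]
  nonprog_ids <- samples$sample_id[states != "progression"]

  powered <- power_filter(ccf, samples$sample_id, config$min_power)
  cand <- ccf[ccf$variant_id %in% powered & is_nonsilent(ccf$effect), ,
              drop = FALSE]
  audit <- data.frame(gene = character(), n_nonsilent = integer(),
                      multiple_nonsilent = logical(), ccf_pattern = logical(),
                      loh_in_progression = logical())
  empty <- data.frame(gene = character(), n_nonsilent = integer(),
                      loh_in_progression = logical(),
                      max_ccf_progression = numeric(),
                      max_ccf_nonprogression = numeric(),
                      passing_variants = character())
  if (nrow(cand) == 0L) {
    attr(empty, "audit") <- audit
    class(empty) <- c("escape_screen_hits", class(empty))
    return(empty)
  }

  # per-variant CCF pattern: dominant somewhere in progression, compatible
  # with absence everywhere else
  per_variant <- lapply(split(cand, cand$variant_id), function(v) {
    prog <- v[v$sample_id %in% prog_ids, , drop = FALSE]
    nonp <- v[v$sample_id %in% nonprog_ids, , drop = FALSE]
    dom_samples <- prog$sample_id[prog$ci_high >= config$ccf_prog_min]
    list(gene = v$gene[1L],
         passes = length(dom_samples) > 0L &&
           (nrow(nonp) == 0L || all(nonp$ci_low <= config$ccf_reg_max)),
         dom_samples = dom_samples,
         max_prog = if (nrow(prog)) max(prog$ccf) else -Inf,
         max_nonprog = if (nrow(nonp)) max(nonp$ccf) else -Inf)
  })

  loh_key <- paste(loh_calls$sample_id, loh_calls$gene, sep = "@")
  gene_loh <- function(gene, sample_ids) {
    if (length(sample_ids) == 0L) return(TRUE)
    idx <- match(paste(sample_ids, gene, sep = "@"), loh_key)
    if (anyNA(idx))
      stop_param("no LOH call for gene ", gene, " in sample(s) ",
                 paste(sample_ids[is.na(idx)], collapse = ", "))
    all(loh_calls$loh[idx])
  }

  genes <- unique(cand$gene)
  rows <- list(); audits <- list()
  for (g in genes) {
    pv <- per_variant[vapply(per_variant, function(x)
      identical(x$gene, g), logical(1))]
    n_total <- length(pv)
    passing <- pv[vapply(pv, `[[`, logical(1), "passes")]
    multiple_ok <- length(passing) >= config$min_nonsilent
    dom_samples <- unique(unlist(lapply(passing, `[[`, "dom_samples")))
    loh_ok <- multiple_ok && gene_loh(g, dom_samples)
    audits[[g]] <- data.frame(gene = g, n_nonsilent = n_total,
                              multiple_nonsilent = multiple_ok,
                              ccf_pattern = length(passing) > 0L,
                              loh_in_progression = loh_ok)
    if (multiple_ok && loh_ok) {
      rows[[g]] <- data.frame(
        gene = g, n_nonsilent = length(passing), loh_in_progression = TRUE,
        max_ccf_progression = max(vapply(passing, `[[`, numeric(1), "max_prog")),
        max_ccf_nonprogression =
          max(-Inf, vapply(passing, `[[`, numeric(1), "max_nonprog")),
        passing_variants = paste(names(passing), collapse = ";"))
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty
  hits <- hits[order(-hits$max_ccf_progression), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "audit") <- do.call(rbind, c(list(audit), audits))
  class(hits) <- c("escape_screen_hits", class(hits))
  log_info("screen: %d hit gene(s) among %d candidate gene(s)", nrow(hits),
           length(genes))
  hits
}

#' @export
print.escape_screen_hits <- function(x, ...) {
  cat(sprintf("Escape screen: %d hit gene(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
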