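# Pipeline-wide configuration.

#' Pipeline configuration
#'
#' Bundles every tunable threshold of the screen and its supporting stages
#' into one validated list, so a whole analysis is reproducible from a
#' single object (or YAML file).
#'
#' @param min_power Minimum per-sample detection power a variant must reach
#'   in every biopsy of a patient to enter the screen (default 0.9).
#' @param ccf_prog_min Cancer-cell-fraction level a screened variant must be
#'   compatible with in at least one progression sample ("dominant";
#'   default 0.5).
#' @param ccf_reg_max Maximum CCF a screened variant may be compatible with
#'   in any baseline or regression sample (default 0.05).
#' @param min_nonsilent Minimum number of distinct non-silent variants a
#'   gene needs to be reported (default 2; set 1 to allow single-lesion
#'   evidence).
#' @param min_alt_count Optional artifact filter: drop called variants with
#'   fewer supporting reads than this in the sample where they were called
#'   (default 0 = off).
#' @param min_callers Consensus votes required to keep a called variant
#'   (default 2).
#' @param loh_covered_fraction Fraction of a gene's length that must fall
#'   inside minor-copy-zero segments to call gene-level LOH (default 1.0).
#' @param k_min Minimum supporting reads that define "detected" in the
#'   power model (default 3).
#' @param strong_rank,weak_rank,wt_rank Percentile-rank thresholds for
#'   neoantigen binder classification (defaults 0.5, 2, 2).
#' @param gene_panel Genes inspected for LOH at cohort level.
#' @param seed Default random seed for stochastic stages.
#' @return A validated list of class `"escape_config"`.
#' @export
pipeline_config <- function(min_power = 0.9,
                            ccf_prog_min = 0.5,
                            ccf_reg_max = 0.05,
                            min_nonsilent = 2L,
                            min_alt_count = 0L,
                            min_callers = 2L,
                            loh_covered_fraction = 1.0,
                            k_min = 3L,
                            strong_rank = 0.5,
                            weak_rank = 2,
                            wt_rank = 2,
                            gene_panel = DEFAULT_GENE_PANEL,
                            seed = 1L) {
  cfg <- list(min_power = min_power, ccf_prog_min = ccf_prog_min,
              ccf_reg_max = ccf_reg_max, min_nonsilent = as.integer(min_nonsilent),
              min_alt_count = as.integer(min_alt_count),
              min_callers = as.integer(min_callers),
              loh_covered_fraction = loh_covered_fraction,
              k_min = as.integer(k_min), strong_rank = strong_rank,
              weak_rank = weak_rank, wt_rank = wt_rank,
              gene_panel = gene_panel, seed = as.integer(seed))
  frac01 <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  if (!frac01(cfg$min_power)) stop_param("min_power must be in [0, 1]")
  if (!frac01(cfg$ccf_prog_min)) stop_param("ccf_prog_min must be in [0, 1]")
  if (!frac01(cfg$ccf_reg_max)) stop_param("ccf_reg_max must be in [0, 1]")
  if (!frac01(cfg$loh_covered_fraction))
    stop_param("loh_covered_fraction must be in [0, 1]")
  if (cfg$min_nonsilent < 1L) stop_param("min_nonsilent must be >= 1")
  if (cfg$min_callers < 1L) stop_param("min_callers must be >= 1")
  if (cfg$k_min < 1L) stop_param("k_min must be >= 1")
  if (cfg$min_alt_count < 0L) stop_param("min_alt_count must be >= 0")
  for (nm in c("strong_rank", "weak_rank", "wt_rank"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0 || cfg[[nm]] > 100)
      stop_param(nm, " must be a percentile in [0, 100]")
  class(cfg) <- "escape_config"
  cfg
}

#' @rdname pipeline_config
#' @param path Path to a YAML file whose top-level keys are
#'   `pipeline_config()` arguments (requires the `yaml` package).
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_param("reading YAML configuration requires the 'yaml' package")
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_format("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @export
print.escape_config <- function(x, ...) {
  cat("<escape_config>\n")
  for (nm in setdiff(names(x), "gene_panel"))
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  cat(sprintf("  %-22s %s\n", "gene_panel",
              paste(x$gene_panel, collapse = ", ")))
  invisible(x)
}
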