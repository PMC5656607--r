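# Cohort-level endpoints: exact one-sided Fisher enrichment of LOH in
# non-responders, Kaplan-Meier / log-rank survival split by LOH status,
# gene-set expression scores, and three closed-form assay formulas.

#' One-sided Fisher exact test for LOH enrichment in non-responders
#'
#' Exact hypergeometric tail probability for a 2x2 table laid out as
#' rows = LOH yes/no, columns = non-responders / responders (responders
#' pooled with long-term survivors). The alternative is enrichment of LOH
#' among non-responders, i.e. the upper tail at the observed `a` with all
#' margins fixed. Implemented directly from the hypergeometric pmf.
#'
#' @param a,b,c,d Cell counts: `a` = LOH & non-responder, `b` = LOH &
#'   responder, `c` = no-LOH & non-responder, `d` = no-LOH & responder.
#' @return The exact one-sided p-value. A degenerate table (an empty row
#'   or column margin) returns 1 with a warning.
#' @examples
#' fisher_one_sided(20, 4, 49, 32)  # ~0.03
#' @export
fisher_one_sided <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_param("cell counts must be non-negative integers")
  loh_total <- a + b; nr_total <- a + c; n <- a + b + c + d
  if (loh_total == 0 || loh_total == n || nr_total == 0 || nr_total == n) {
    warning("degenerate 2x2 margins; returning p = 1", call. = FALSE)
    return(1)
  }
  # X ~ Hypergeometric: draws of size nr_total from loh_total successes
  x_max <- min(loh_total, nr_total)
  sum(dhyper(a:x_max, loh_total, n - loh_total, nr_total))
}

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' Standard two-group log-rank test on right-censored survival, with ties
#' handled through the hypergeometric variance at each distinct event
#' time, and the p-value from the chi-square distribution with one degree
#' of freedom. Kaplan-Meier curves are fitted per group. Built on the
#' `survival` package.
#'
#' @param time Numeric vector of follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Two-level grouping vector (e.g. LOH carrier yes/no).
#' @return A list of class `"escape_survfit"`: `statistic` (chi-square),
#'   `p` (two-sided), `n` and `observed`/`expected` events per group, and
#'   `km`, a data frame of the stepwise survival curves (columns
#'   `group, time, surv, n_risk, n_event`).
#' @export
log_rank <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L)
    stop_param("log_rank() needs exactly two non-empty groups; got ",
               nlevels(group))
  if (any(table(group) == 0L)) stop_param("a group has zero subjects")
  if (!any(event == 1)) stop_param("no events observed in either group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- unname(sd$chisq)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(fit$strata) %||% levels(group)[1L],
                fit$strata %||% length(fit$time))
  km <- data.frame(group = sub("^group=", "", strata), time = fit$time,
                   surv = fit$surv, n_risk = fit$n.risk,
                   n_event = fit$n.event)
  out <- list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
              n = as.vector(sd$n), observed = sd$obs, expected = sd$exp,
              groups = levels(group), km = km)
  class(out) <- "escape_survfit"
  out
}

#' @export
print.escape_survfit <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.3f (1 df), p = %.4g\n",
              x$statistic, x$p))
  cat(sprintf("  %s: n = %d, observed = %d, expected = %.1f\n",
              x$groups, x$n, x$observed, x$expected), sep = "")
  invisible(x)
}

#' Cohort LOH enrichment and survival endpoint
#'
#' Joins patient-level LOH status onto a clinical table, builds the 2x2
#' contingency table with responders and long-term survivors pooled into
#' the non-case column, and computes the one-sided Fisher enrichment
#' p-value plus the log-rank survival comparison split by LOH status.
#'
#' @param clinical Data frame in the [read_clinical()] layout.
#' @param loh_status Named logical vector (names = patient IDs) or data
#'   frame with columns `patient_id, loh`; every clinical patient must be
#'   covered.
#' @return A list of class `"escape_endpoint"`: `table` (2x2 matrix),
#'   `fisher_p`, `survfit` (an [log_rank()] result, or `NULL` when a group
#'   is empty or no events occurred), and `loh_fraction` per response
#'   column.
#' @export
loh_enrichment_endpoint <- function(clinical, loh_status) {
  if (is.data.frame(loh_status))
    loh_status <- setNames(as.logical(loh_status$loh), loh_status$patient_id)
  idx <- match(clinical$patient_id, names(loh_status))
  if (anyNA(idx))
    stop_param("no LOH status for patient(s): ",
               paste(clinical$patient_id[is.na(idx)], collapse = ", "))
  loh <- unname(loh_status[idx])
  nonresp <- clinical$response_group == "nonresponder"
  tab <- matrix(c(sum(loh & nonresp), sum(loh & !nonresp),
                  sum(!loh & nonresp), sum(!loh & !nonresp)),
                nrow = 2, byrow = TRUE,
                dimnames = list(loh = c("yes", "no"),
                                group = c("nonresponder", "responder_lts")))
  p <- fisher_one_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  sf <- if (length(unique(loh)) == 2L && any(clinical$os_event == 1)) {
    log_rank(clinical$os_days, clinical$os_event,
             ifelse(loh, "LOH", "no_LOH"))
  } else NULL
  out <- list(table = tab, fisher_p = p, survfit = sf,
              loh_fraction = colSums(tab * c(1, 0)) / colSums(tab))
  class(out) <- "escape_endpoint"
  out
}

#' @export
print.escape_endpoint <- function(x, ...) {
  cat("LOH x response endpoint\n")
  print(x$table)
  cat(sprintf("LOH fraction: %.1f%% of non-responders vs %.1f%% of responders/LTS\n",
              100 * x$loh_fraction[1], 100 * x$loh_fraction[2]))
  cat(sprintf("One-sided Fisher exact p = %.4g\n", x$fisher_p))
  if (!is.null(x$survfit))
    cat(sprintf("Log-rank p = %.4g\n", x$survfit$p))
  invisible(x)
}

#' Gene-set expression score
#'
#' Geometric mean of `TPM + 1` over the genes of a set; the pseudocount
#' keeps zero-expression genes from annihilating the mean, and the score
#' is reported on that +1 scale.
#'
#' @param tpm Named numeric vector of TPM values (names = genes).
#' @param gene_set Character vector of genes; members missing from `tpm`
#'   are dropped with a warning, and an entirely missing set is an error.
#' @return The score (>= 1).
#' @examples
#' expression_score(c(CD8A = 3, GZMB = 8), c("CD8A", "GZMB"))  # 6
#' @export
expression_score <- function(tpm, gene_set) {
  if (length(gene_set) == 0L) stop_param("gene_set must be non-empty")
  found <- gene_set[gene_set %in% names(tpm)]
  missing <- setdiff(gene_set, found)
  if (length(missing))
    warning("gene(s) absent from expression table dropped from score: ",
            paste(missing, collapse = ", "), call. = FALSE)
  if (length(found) == 0L)
    stop_param("expression score undefined: no gene of the set was found")
  vals <- tpm[found]
  if (any(vals < 0)) stop_param("TPM values must be >= 0")
  exp(mean(log(vals + 1)))
}

#' Bin an IHC tumor-fraction percentage into expression levels
#'
#' Bins: minimal \[0, 10), low \[10, 50), intermediate \[50, 80),
#' high \[80, 100\].
#'
#' @param tumor_fraction_pct Percentage(s) in \[0, 100\].
#' @return Factor over `minimal < low < intermediate < high`.
#' @export
ihc_bin <- function(tumor_fraction_pct) {
  if (any(tumor_fraction_pct < 0 | tumor_fraction_pct > 100) ||
      anyNA(tumor_fraction_pct))
    stop_param("tumor_fraction_pct must be in [0, 100]")
  cut(tumor_fraction_pct, breaks = c(0, 10, 50, 80, 100),
      labels = c("minimal", "low", "intermediate", "high"),
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}

#' Droplet digital PCR fractional abundance
#'
#' `F.A.% = Nmut / (Nmut + Nwt) * 100` over droplet event counts.
#'
#' @param n_mut,n_wt Non-negative mutant and wild-type event counts; their
#'   sum must be positive.
#' @return Fractional abundance as a percentage.
#' @export
ddpcr_fractional_abundance <- function(n_mut, n_wt) {
  if (any(n_mut < 0) || any(n_wt < 0))
    stop_param("event counts must be >= 0")
  if (any(n_mut + n_wt == 0))
    stop_param("fractional abundance undefined: zero total events")
  n_mut / (n_mut + n_wt) * 100
}

#' In vivo competition score
#'
#' Percentage change from baseline of a knockout clone relative to the
#' wild-type clone in a mixed transplant:
#' `(1 - (ko_sample/ko_baseline) / (wt_sample/wt_baseline)) * 100`.
#' Positive values mean depletion of the knockout clone.
#'
#' @param ko_sample_pct,ko_baseline_pct Knockout-clone percentages at
#'   harvest and inoculation.
#' @param wt_sample_pct,wt_baseline_pct Wild-type-clone percentages at
#'   harvest and inoculation; baselines and `wt_sample_pct` must be
#'   positive.
#' @return Percentage change (vectorised); 100 when the knockout clone is
#'   fully depleted, 0 when both clones kept their baseline ratio.
#' @export
competition_score <- function(ko_sample_pct, ko_baseline_pct,
                              wt_sample_pct, wt_baseline_pct) {
  pts <- c(ko_sample_pct, ko_baseline_pct, wt_sample_pct, wt_baseline_pct)
  if (any(pts < 0 | pts > 100)) stop_param("percentages must be in [0, 100]")
  if (any(ko_baseline_pct <= 0) || any(wt_baseline_pct <= 0))
    stop_param("baseline percentages must be > 0")
  if (any(wt_sample_pct == 0))
    stop_param("competition score undefined: wild-type sample percentage is 0")
  (1 - (ko_sample_pct / ko_baseline_pct) /
     (wt_sample_pct / wt_baseline_pct)) * 100
}
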