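# Cancer cell fraction (CCF) estimation and detection power.
#
# Deterministic allelic model with normal contamination at copy number 2:
# a variant present at multiplicity m in a fraction ccf of cancer cells,
# in a biopsy of purity alpha whose locus has total tumor copy number cn_t,
# is expected at allele fraction
#
#     VAF = ccf * alpha * m / (alpha * cn_t + (1 - alpha) * 2).
#
# The map VAF <-> CCF is linear at fixed (alpha, cn_t, m), so exact binomial
# (Clopper-Pearson) confidence limits on the VAF transfer directly to CCF.
# Subclonal copy number is ignored; purity and local copy number are inputs.

#' Expected variant allele fraction under the allelic CCF model
#'
#' @param purity Tumor purity (fraction of cells that are cancer), in (0, 1].
#' @param cn_t Local total copy number in the cancer cells (> 0; may be
#'   non-integer for subclonal calls, though the model treats it as clonal).
#' @param m Mutation multiplicity: mutant allele copies per mutated cancer
#'   cell (integer >= 1).
#' @param ccf Cancer cell fraction carrying the variant, in \[0, 1\].
#' @return Expected VAF in \[0, 1\]. Vectorised over all arguments. A
#'   parameter combination implying VAF > 1 (multiplicity inconsistent with
#'   the local copy number) is an error.
#' @examples
#' expected_vaf(purity = 1, cn_t = 2, m = 1, ccf = 1)    # clonal het: 0.5
#' expected_vaf(purity = 0.5, cn_t = 2, m = 1, ccf = 1)  # 0.25
#' @export
expected_vaf <- function(purity, cn_t, m, ccf) {
  if (any(purity <= 0 | purity > 1)) stop_param("purity must be in (0, 1]")
  if (any(cn_t <= 0)) stop_param("cn_t must be > 0")
  if (any(m < 1)) stop_param("multiplicity m must be >= 1")
  if (any(ccf < 0 | ccf > 1)) stop_param("ccf must be in [0, 1]")
  vaf <- ccf * purity * m / (purity * cn_t + (1 - purity) * 2)
  if (any(vaf > 1 + 1e-12))
    stop_param("expected VAF exceeds 1: multiplicity m = ", max(m),
               " is inconsistent with local copy number cn_t = ", min(cn_t))
  pmin(vaf, 1)
}

#' Estimate mutation multiplicity from an observed VAF
#'
#' Inverts the allelic model at CCF = 1 and rounds to the nearest integer
#' copy count, clamped to \[1, max(1, round(cn_t))\].
#'
#' @inheritParams expected_vaf
#' @param vaf Observed variant allele fraction in \[0, 1\].
#' @return Integer multiplicity estimate (vectorised).
#' @export
estimate_multiplicity <- function(vaf, purity, cn_t) {
  if (any(vaf < 0 | vaf > 1)) stop_param("vaf must be in [0, 1]")
  if (any(purity <= 0 | purity > 1)) stop_param("purity must be in (0, 1]")
  if (any(cn_t <= 0)) stop_param("cn_t must be > 0")
  m <- round(vaf * (purity * cn_t + (1 - purity) * 2) / purity)
  cap <- pmax(1, round(cn_t))
  as.integer(pmin(pmax(m, 1), cap))
}

#' Estimate CCF with an exact 95% confidence interval
#'
#' Converts alt/ref read counts at a locus to a cancer cell fraction by
#' inverting [expected_vaf()], and maps the exact Clopper-Pearson 95%
#' binomial interval on the VAF through the same linear inverse. Both the
#' point estimate and the limits are clamped to \[0, 1\].
#'
#' @inheritParams expected_vaf
#' @param alt,ref Alt- and ref-supporting read counts (vectorised;
#'   `alt + ref` must be positive).
#' @param conf Confidence level of the interval (default 0.95).
#' @return A data frame with columns `vaf`, `m`, `ccf`, `ci_low`, `ci_high`.
#' @examples
#' estimate_ccf(alt = 25, ref = 75, purity = 0.5, cn_t = 2, m = 1)
#' @export
estimate_ccf <- function(alt, ref, purity, cn_t, m = 1L, conf = 0.95) {
  if (any(alt < 0 | ref < 0)) stop_param("read counts must be >= 0")
  n <- alt + ref
  if (any(n == 0))
    stop_param("undefined CCF estimate: alt + ref = 0 at some locus")
  if (any(m < 1)) stop_param("multiplicity m must be >= 1")
  vaf <- alt / n
  alpha2 <- (1 - conf) / 2
  # Clopper-Pearson limits; closed at the boundary counts
  lo <- ifelse(alt == 0, 0, qbeta(alpha2, alt, n - alt + 1))
  hi <- ifelse(alt == n, 1, qbeta(1 - alpha2, alt + 1, n - alt))
  denom <- purity * cn_t + (1 - purity) * 2
  inv <- denom / (purity * m)      # linear factor of the VAF -> CCF inverse
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  data.frame(vaf = vaf, m = as.integer(m + 0 * vaf),
             ccf = clamp01(vaf * inv),
             ci_low = clamp01(lo * inv), ci_high = clamp01(hi * inv))
}

#' Detection power for a clonal variant
#'
#' Probability of observing at least `k_min` supporting reads for a clonal
#' (CCF = 1) variant at the given depth, purity, local copy number and
#' multiplicity: the upper binomial tail at the expected clonal VAF.
#'
#' @inheritParams expected_vaf
#' @param depth Total read depth at the locus (>= 0; vectorised).
#' @param k_min Minimum supporting reads that count as detection (default 3).
#' @return Power in \[0, 1\], non-decreasing in depth, purity and m.
#' @examples
#' detection_power(depth = 150, purity = 0.5, cn_t = 2, m = 1)
#' @export
detection_power <- function(depth, purity, cn_t, m = 1L, k_min = 3L) {
  if (any(depth < 0)) stop_param("depth must be >= 0")
  if (k_min < 1) stop_param("k_min must be >= 1")
  p <- expected_vaf(purity, cn_t, m, ccf = 1)
  pbinom(k_min - 1, size = depth, prob = p, lower.tail = FALSE)
}
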