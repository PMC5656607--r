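# Shared fixtures, built in code.

# one row of a CCF-estimate matrix with symmetric half-width CIs
ccf_rows <- function(vid, sids, gene, effect, ccf, power = 0.99, half = 0.1) {
  data.frame(variant_id = vid, sample_id = sids, gene = gene, effect = effect,
             ccf = ccf, ci_low = pmax(0, ccf - half),
             ci_high = pmin(1, ccf + half), power = power)
}

four_biopsy_samples <- function() {
  data.frame(sample_id = c("pre", "reg", "prog1", "prog2"),
             disease_state = c("baseline", "regression", "progression",
                               "progression"))
}

# Worked-example fixture: two escape frameshifts, each dominant in its own
# progression biopsy (CCF 0.74 / 0.55) and near-absent (0.01) elsewhere;
# LOH over the escape gene in both progression biopsies; clonal and
# subclonal background mutations with state-independent CCFs.
escape_patient_fixture <- function() {
  sids <- four_biopsy_samples()$sample_id
  ccf <- rbind(
    ccf_rows("fs1", sids, "B2M", "frameshift", c(0.01, 0.01, 0.74, 0.01)),
    ccf_rows("fs2", sids, "B2M", "frameshift", c(0.01, 0.01, 0.01, 0.55)),
    ccf_rows("bg_clonal", sids, "BRAF", "missense", rep(0.95, 4)),
    ccf_rows("bg_sub", sids, "TTN", "missense", rep(0.30, 4)),
    ccf_rows("bg_silent", sids, "B2M", "silent", c(0.01, 0.01, 0.70, 0.70)))
  loh <- expand.grid(sample_id = sids, gene = c("B2M", "BRAF", "TTN"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  loh$loh <- loh$gene == "B2M" & loh$sample_id %in% c("prog1", "prog2")
  list(ccf = ccf, loh = loh, samples = four_biopsy_samples())
}

# write lines to a temp TSV
write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

variant_tsv_lines <- c(
  "patient_id\tsample_id\tchrom\tpos\tref\talt\tref_count\talt_count\tgene\teffect\tcallers",
  "P1\tS1\t15\t45003745\tTC\tT\t60\t40\tB2M\tframeshift\tstrelka;mutect",
  "P1\tS2\t7\t140453136\tA\tT\t80\t20\tBRAF\tmissense\tstrelka;mutect;vardict")

# independent brute-force evaluation of the screen criteria, written as
# plain nested loops over genes, variants and samples
brute_force_screen <- function(ccf, loh, samples, cfg) {
  prog <- samples$sample_id[samples$disease_state == "progression"]
  nonprog <- setdiff(samples$sample_id, prog)
  hits <- character()
  for (g in unique(ccf$gene)) {
    passing <- character(); dom_all <- character()
    for (v in unique(ccf$variant_id[ccf$gene == g])) {
      rows <- ccf[ccf$variant_id == v, ]
      if (any(rows$power < cfg$min_power)) next
      if (rows$effect[1] == "silent") next
      dom <- rows$sample_id[rows$sample_id %in% prog &
                              rows$ci_high >= cfg$ccf_prog_min]
      absent <- all(rows$ci_low[rows$sample_id %in% nonprog] <= cfg$ccf_reg_max)
      if (length(dom) > 0 && absent) {
        passing <- c(passing, v)
        dom_all <- union(dom_all, dom)
      }
    }
    if (length(passing) >= cfg$min_nonsilent) {
      loh_ok <- all(vapply(dom_all, function(s)
        loh$loh[loh$sample_id == s & loh$gene == g], logical(1)))
      if (loh_ok) hits <- c(hits, g)
    }
  }
  hits
}
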