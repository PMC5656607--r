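---
title: "Methods: screening longitudinal tumor exomes for immune-escape drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening longitudinal tumor exomes for immune-escape drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escapescreen)
```

## The problem

Checkpoint blockade (anti-CTLA4, anti-PD1) works by unleashing T cells
against tumor antigens presented on HLA class I. A tumor that loses the
ability to present antigen — most economically by losing B2M, the obligate
subunit of every HLA class I complex — escapes that pressure. The genetic
signature of such escape in serial biopsies is characteristic: a gene
accumulates several independent truncating mutations, each mutation sweeps
to a high fraction of cancer cells, the sweeps happen only in biopsies
taken during disease progression, and the wild-type allele is lost (LOH),
so a single hit per cell suffices. `escapescreen` operationalizes that
signature as a screen over a patient's longitudinal whole-exome data, and
adds the cohort-level endpoints (enrichment of LOH in non-responders,
survival split by LOH status) used to confirm a candidate driver in
cross-sectional cohorts.

The package deliberately consumes the *outputs* of the standard somatic
pipeline — per-caller variant sets, allele-specific copy-number segments,
purity/ploidy estimates, binding-rank tables, TPM matrices — rather than
re-running alignment, calling, or binding prediction. Those inputs are
tabular and portable; everything downstream of them is implemented here.

## The CCF model

The central quantity is the cancer cell fraction (CCF): the fraction of
cancer cells in a biopsy that carry a variant. A biopsy of purity
$\alpha$ whose locus has total tumor copy number $C_t$ (normal cells
contribute copy number 2), with the variant on $m$ allele copies in a
fraction $f$ of cancer cells, is expected to show variant allele fraction

$$\mathrm{VAF} = \frac{f\,\alpha\,m}{\alpha C_t + 2(1-\alpha)}.$$

`expected_vaf()` computes this; `estimate_ccf()` inverts it at fixed
$(\alpha, C_t, m)$, which is a linear map, so the exact Clopper–Pearson
95% binomial interval on the VAF transfers directly to the CCF scale.
Point estimates and limits are clamped to $[0, 1]$. The model treats copy
number as clonal and ignores subclonal copy-number mixtures: purity and
local copy number are inputs inferred upstream, and the model's job is a
transparent, deterministic VAF-to-CCF normalization, not a full
purity/ploidy posterior.

Multiplicity is estimated by rounding the model inverse at $f = 1$ and
clamping to $[1, \max(1, \mathrm{round}(C_t))]$ (`estimate_multiplicity()`).

Detection power for a clonal variant is the upper binomial tail
$P(X \ge k_{\min})$ with $X \sim \mathrm{Bin}(\text{depth}, \mathrm{VAF}_{f=1})$;
$k_{\min} = 3$ supporting reads defines "detected". Three reads is the
conventional minimum-evidence threshold in exome pipelines; it matters
only through the power filter, and power at the working depth of 150x is
well above 0.9 across the purity range, so the screen is insensitive to
$k_{\min}$ within reason.

## Consensus voting and force-calling

Somatic calls are taken as the per-sample majority vote over caller
outputs (`consensus_vote()`, default 2 of 3), with variant identity
`(sample, chrom, pos, ref, alt)`. Voting is per sample: support in one
biopsy never rescues a variant in another. Instead, the union of a
patient's consensus variants is *force-called*: read counts are collected
at every union locus in every biopsy (`build_force_call_matrix()`), so a
mutation private to one biopsy still has an observed — possibly zero-alt —
count everywhere, and "absent" is a measurement, not a missing value. The
matrix is complete by construction; a missing (variant, sample) pair is an
error, never a gap.

Artifact filtering specific to FFPE/oxidation chemistry is represented
only by an optional minimum alt-count filter (`min_alt_count`, default
off): the screen's inputs here are simulated or pre-filtered tables, and
artifact chemistry is out of scope.

## The screen

For one patient, `screen_patient()` reports a gene when:

1. **Multiple non-silent mutations.** At least `min_nonsilent` (default 2)
   distinct non-silent variants (missense, nonsense, frameshift,
   splice-site) survive the power filter, which requires detection power
   $\ge$ `min_power` (default 0.9) in **every** biopsy — so absence of a
   variant is always interpretable as true absence rather than shallow
   coverage.
2. **Progression-exclusive dominance.** Each such variant is compatible
   with a dominant clone (CCF threshold `ccf_prog_min`, default 0.5) in at
   least one progression biopsy, and compatible with absence (CCF
   threshold `ccf_reg_max`, default 0.05) in every baseline and regression
   biopsy. Compatibility is judged on the 95% confidence interval: the
   upper limit must reach `ccf_prog_min` for dominance, and the lower
   limit must reach down to `ccf_reg_max` for absence. Using the interval
   rather than the point estimate is a deliberate design choice: a truly
   dominant clone at CCF 0.55 read at depth 150 lands below a 0.5 point
   cutoff in a substantial fraction of replicates purely through binomial
   noise, while the interval rule keeps both error directions controlled
   (the reported false-positive rate under escape-free simulations is in
   the acceptance output). Point estimates are what the hit table reports.
3. **LOH where it matters.** The gene is under loss of heterozygosity in
   every progression biopsy in which one of those variants is dominant,
   so the mutant allele is plausibly the only allele.

The default thresholds are the smallest ones consistent with the
characteristic escape pattern the screen targets (per-variant sweeps at
CCF 0.55–0.74 in single progression biopsies, ~1% residual elsewhere);
both are configurable, and the per-gene evaluation of each criterion is
attached to the result as an audit table. Criterion evaluation is
per-variant, not pooled per gene, because independent escape mutations in
the same gene are typically dominant in *different* biopsies. The screen
demands at least one progression and one non-progression biopsy and
refuses to run otherwise — the criteria are longitudinal by construction.

Raising `ccf_prog_min` or `min_nonsilent`, or lowering `ccf_reg_max`,
never adds hits (tested property), and the implementation is checked
against a brute-force evaluator on small cohorts.

## LOH calling

A gene has LOH in a sample when at least `loh_covered_fraction` (default
1.0, i.e. the whole gene) of its interval lies in segments with minor
allele copy number zero (`call_gene_loh()`). The default demands full
coverage because escape-associated deletions are typically multi-megabase
while the gene is a few kilobases; how partial-gene deletions should count
is genuinely unclear, so the fraction is a logged, configurable parameter
rather than a hidden convention. Homozygous deletion (total copy number
zero over the locus) is flagged separately as `both_copies_lost`.
Intervals are 1-based inclusive as on disk; overlapping segments are
resolved first-wins in `(chrom, start)` order, which makes coverage
invariant to splitting a segment into adjacent identical-CN pieces. A
locus on an unsegmented chromosome yields `loh = FALSE` with a warning:
no evidence is not evidence of loss.

## Neoantigen classification

`classify_binder()` applies percentile-rank thresholds: a mutant peptide
is a *strong* binder at rank < 0.5 and a *weak* binder at 0.5 ≤ rank < 2,
in either case only when the corresponding wild-type peptide is a
non-binder (rank > 2) — if the wild-type binds, central tolerance makes
the mutant uninteresting. Boundaries are strict on the mutant side and
strict on the wild-type side; ties at the exact thresholds are resolved by
that convention and tested. `neoantigen_load()` counts *genes* with at
least one binder, not peptides, so duplicated peptide rows cannot inflate
the load.

## Cohort endpoints

The enrichment endpoint (`loh_enrichment_endpoint()`) pools responders
and long-term survivors into the non-case column and computes a one-sided
Fisher exact p-value for LOH enrichment among non-responders.
`fisher_one_sided()` is implemented directly from the hypergeometric pmf
and validated exhaustively against fixed-margin enumeration for every
table with total count up to 30; on the published validation-cohort
margins (20/69 vs 4/36) it gives $p = 0.0304$. The survival endpoint is
the standard two-group log-rank test with hypergeometric tie handling and
a chi-square(1) p-value, with Kaplan–Meier curves per group; these are
delegated to the `survival` package behind the package's interface, and
the test's size is verified on permuted null labels. No multiplicity
correction is applied across genes — per-gene endpoints are reported raw,
which mirrors common practice for small panels and is a documented
limitation.

Three closed-form assay formulas round out the module: IHC
tumor-fraction binning (half-open bins $[0,10), [10,50), [50,80)$ and a
closed top bin $[80,100]$ — the printed ranges share endpoints, so a total
function needs a convention), ddPCR fractional abundance
$N_{mut}/(N_{mut}+N_{wt}) \times 100$, and the in vivo competition score
$(1 - \frac{KO_{s}/KO_{b}}{WT_{s}/WT_{b}}) \times 100$.

Gene-set expression scores are geometric means of $\mathrm{TPM}+1$; the
pseudocount keeps a single zero from annihilating the mean, and scores
are reported on the +1 scale.

## The synthetic cohort generator

Real longitudinal checkpoint-blockade cohorts are access-controlled, so
the package ships a generator with the statistical structure the analysis
assumes, and every end-to-end claim in the test suite is made against its
planted truth.

`simulate_longitudinal_patient()` draws, per patient: biopsies laid out
as baseline, regression, then progression (default 4 biopsies); per-biopsy
purity uniform on [0.3, 0.9]; per-locus depth Poisson with mean 150
(the working minimum tumor depth of the pipelines this emulates);
~246 background mutations, two per background gene, with state-independent
CCFs (60% clonal, the rest uniform on [0.05, 1]) placed on the retained
allele; whole-chromosome background segments with a 10% per-sample chance
of whole-chromosome LOH (never on the escape chromosome). Under the
escape scenario, every progression biopsy carries a focal deletion
(minor copy 0) spanning the escape gene ±5 Mb, plus two frameshifts at
CCF 0.74 and 0.55 — each dominant in its *own* progression biopsy and at
CCF 0.01 elsewhere, matching the per-biopsy sweep pattern the screen
targets. Read counts are binomial at the model VAF; caller assignment
gives well-supported variants (alt ≥ 8) two or three callers and splits
callers only near the three-read detection margin, where real callers
genuinely disagree. Background CCF dispersion across biopsies is not an
empirical claim — it is a configuration knob with a documented default.

`simulate_validation_cohort()` draws a cross-sectional cohort of
69 non-responders, 26 responders and 10 long-term survivors; LOH status
is Bernoulli at prevalence 28.9% / 11.1% by group; survival is
exponential proportional hazards (baseline hazard 1/1000 per day, hazard
ratio 2 for LOH carriers — the simplest model consistent with a log-rank
endpoint; at these settings the realized median log-rank p is of order
0.01) with independent exponential censoring matched to a 40% target
censoring fraction.

Both generators are deterministic given (config, seed) and restore the
caller's RNG state.

**What the simulations do not capture:** trinucleotide mutation spectra,
sequencing error and FFPE artifact chemistry, subclonal copy number,
purity estimation error, caller-specific biases, and phylogenetic
structure beyond the two planted escape lineages. Passing tests therefore
demonstrate that the estimators and decision rules are correct under the
stated statistical model, not that the pipeline is robust to every
pathology of real exome data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 100 replicate patients
for recovery and 100 for specificity (~250 variants × 4 biopsies each),
2 000 simulated variants for interval coverage, 5 000 label permutations
for the log-rank size check, 1 000 replicate cohorts for p-value
uniformity under a unit hazard ratio, and exhaustive Fisher enumeration
to total count 30. These sizes give Monte-Carlo standard errors well
inside the asserted bands while keeping a full run in the low minutes on
one core.

Degenerate inputs are handled explicitly: zero-depth cells are an error
for CCF estimation (not silently CCF 0); degenerate 2×2 margins return
p = 1 with a warning; an LOH-free cohort skips the survival split; a
patient without both progression and non-progression biopsies is an
inapplicable-screen error, not an empty result.
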