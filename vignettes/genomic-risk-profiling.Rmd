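---
title: "Genomic risk profiling of DNA damage checkpoint and repair panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic risk profiling of DNA damage checkpoint and repair panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genorisk)
```

## The scientific problem

Chronic inflammation produces reactive oxygen and nitrogen species that
damage DNA. Whether a tissue or a disease keeps its genome stable depends on
two gene families: DNA damage **checkpoint** factors (DDCFs — sensors such as
PARP1 and the Ku subunits XRCC6/XRCC5, mediators such as BRCA1, transducers
such as ATM/ATR) that arrest the cell cycle when damage is detected, and DNA
damage **repair** factors (DDRFs) spanning direct reversal, base and
nucleotide excision repair, the three double-strand-break repair routes, and
mismatch repair. `genorisk` implements a database-mining style pipeline over
a curated panel of 26 DDCFs + 42 DDRFs = 68 genes:

1. **Tissue expression profiling** from expressed-sequence-tag (EST) counts:
   normalization to transcripts per million (TPM), high/low/absent calls,
   per-tissue H% and a three-tier "variety pyramid".
2. **Disease modulation calling** from case-vs-control fold-change tables
   (GEO2R-style exports) and a **genomic-risk index** with a three-group
   classification of diseases.
3. **Cross-disease overlap** of modulated gene sets (exclusive Venn
   regions, disease-specific factors).
4. **Methylation-regulation classification** of panel genes from their
   correlation with tissue SAM/SAH methylation indices.
5. A **seeded synthetic-data generator** that emulates all three input
   families with planted ground truth, so the full pipeline runs and is
   validated offline.

## Panel membership

Two published DDCF membership variants exist and both ship with the package.
The `table2` variant (default) is the membership used by every quantitative
table downstream; it includes IL1A and splits replication protein A into
RPA1/RPA2/RPA3. The `figure2` variant follows the signalling diagram: a
single RPA, the clamp-loader RFC1, and the CDC25A/CDC25C effectors instead
of IL1A. The two lists are never mixed, each satisfies |DDCF| = 26, and the
risk denominator is 68 either way. Legacy aliases (Ku70 → XRCC6,
XPB → ERCC3, CSA → ERCC8, ...) and mouse case convention (Parp1 → PARP1) are
resolved by `normalize_symbol()`; mouse homology is by symbol case only — no
orthology database is consulted.

## Expression profiling

TPM here means *transcripts per million ESTs*:
`tpm = count / library_total * 1e6`. Calls follow EST semantics strictly:

* **absent (−)** exactly when the count is zero — one observed tag means the
  gene is expressed, so no minimum-count floor is applied;
* **high (++)** when TPM is *strictly greater* than the threshold (ties go
  to low, a literal reading of "higher than the threshold");
* **low (+)** otherwise.

The original threshold derivation is not reproducible from published
material, so the default `"auto"` rule is a single global threshold: the
mean TPM over all nonzero panel-gene × tissue cells. It is configurable; all
downstream statistics record the threshold actually used. H% for a tissue is
the percentage of the chosen panel subset called high there, and tissues tier
into `high_variety` (H% > 19), `moderate_variety` (5 ≤ H% ≤ 19, both bounds
inclusive) and `low_variety` (H% < 5).

## Modulation calls and the genomic-risk index

A panel gene in one contrast is **up** when its fold change is ≥ 2 and
**down** when ≤ 0.5 (both inclusive), additionally requiring p ≤ 0.05 when a
p-value is available; a missing p-value leaves the fold-change criterion
deciding alone. These defaults reflect the screens the published summary
tables applied; no printed entry violates them. No multiple-testing
correction is applied by default (`p_adjust = "BH"` is available) because the
published screens report none. Genes absent from a table count as unchanged
and stay in the denominator.

The genomic-risk index of a disease is `100 * (n_up + n_down) / 68`.
Display values round to the nearest integer with ties away from zero — the
only rule consistent with every published pair (16/68 = 23.53 → 24,
12/68 = 17.65 → 18, 1/68 = 1.47 → 1). Risk groups are assigned on the
*unrounded* percentage: **high** ≥ 10, **medium** in [5, 10), **low** < 5.
The boundaries must act on the raw value: a 7-gene disease (10.29%) is high
while a 6-gene disease (8.82%) is medium. One published cohort fraction
(5/27 printed as 18.8%) does not follow from its own numbers; the package
computes 18.5% and does not silently adopt the printed value.

## Overlap analysis

`venn_regions()` assigns every gene in the union of the per-disease sets to
exactly one exclusive region — the signature of all sets containing it — so
region cardinalities always sum to the union size. Up- and down-regulated
sets are analyzed separately by default, mirroring how the directions behave
as distinct signatures. "Mostly disease-specific" is operationalized as a
strict majority (> 50%) of the union lying in singleton regions; the
published phrasing is qualitative, so the flag is reported alongside the
counts rather than replacing them. Beyond six sets an exhaustive region
table is unreadable and only pairwise intersections are reported.

## Methylation-regulation classification

SAH is a hypomethylation index, SAM and SAM/SAH hypermethylation indices.
For each gene, per-tissue expression is correlated (Pearson) with each
index; p-values come from the t transform `t = r * sqrt((n-2)/(1-r^2))` with
n − 2 degrees of freedom, two-sided. A gene is **hypo**methylation-regulated
when the SAH correlation is significant, **hyper** when SAM or SAM/SAH is
significant while SAH is not, and **non** otherwise. SAH takes precedence if
both would apply — the published grouping contains no overlapping case, so
the precedence is made explicit here rather than left undefined. Correlation
tiers split at r² > 0.7 ("high") for significant results. Pearson is the
only default (the published r²/p pairs are consistent with the Pearson-t
relation); Spearman is deliberately not a default anywhere. Expression may
be rescaled per gene (each gene to its own maximum) for plotting; r is
invariant to affine rescaling, so this is cosmetic only.

The per-tissue **DNA damage response potential** used when correlating
against candidate regulator genes (oxygen sensors, VEGF pathway, stem-cell
master regulators) is not defined operationally in published material; the
package defaults to the tissue's H% over the combined 68-gene panel, with
mean TPM selectable as an alternative.

## The synthetic-data generator

The generator exists so that every pipeline stage is testable without the
retired UniGene resource or GEO downloads. It emulates:

* **EST tables** — Poisson counts at planted high (200 TPM) / low (20 TPM)
  levels, library totals uniform in 1e5–1e6, 21 tissues. A planted-absent
  cell has rate zero. Ground truth labels a sampled-zero cell `absent`:
  under EST semantics an unobserved tag *is* an unexpressed gene, so the
  recoverable truth is the realized one.
* **Contrasts** — per gene, five case and five control replicates drawn
  log-normal (log2 noise sd 0.3) around a gene baseline, the case arm offset
  by the planted log2 fold change (|log2fc| = 1.5 by default, i.e. planted
  genes are truly modulated at the fc = 2 boundary with headroom). The
  reported fold change is the ratio of arithmetic arm means; the p-value a
  Welch t-test on log2 values. This is deliberately the simplest model
  consistent with microarray ratio data — the test is plumbing, not a
  contribution.
* **Methylation panels** — six tissues; SAM uniform in 20–80, SAH
  residualized against SAM and rescaled into a narrow positive band around
  4. This orthogonalization is an identifiability-by-design choice: with six
  iid draws the realized SAM and SAH vectors are frequently confounded by
  chance (|r| well above the n = 6 significance cut), and the SAM/SAH ratio
  would otherwise be dominated by whichever input has the wider relative
  spread, making planted hypo and hyper classes indistinguishable *in
  principle*. With SAH orthogonal to SAM and SAM driving the ratio, the
  three indices separate. Planted slopes have signal-to-noise 5 against unit
  expression noise; 5 hypo and 15 hyper genes are planted (the published
  group sizes), hyper genes alternating between the SAM and ratio indices.

Each artifact draws from its own RNG stream derived from (master seed,
artifact name), so adding a generator never perturbs existing fixtures, and
a fixed seed reproduces everything bit for bit.

The **published-study preset** (`simulate_study()`) regenerates the whole study
skeleton: the 21 × 68 EST table with the ten classic housekeeping factors
planted never-absent, the 39 disease contrasts whose planted modulated-gene
counts equal the published per-disease numbers, and the methylation panel.
The cancers' planted category/direction splits are apportioned (largest
remainder) so class-level totals equal the published 44/14 up/down DDCF and
32/13 DDRF changes. Preset contrasts use stronger planted effects
(|log2fc| = 2, noise 0.25) so that threshold calling recovers the planted
counts exactly and the regenerated risk table matches the planted manifest
at any seed — the preset's purpose is deterministic end-to-end validation,
not power analysis.

### What passing tests do and do not show

The generator plants clean two-level expression classes, symmetric
log-normal replicate noise, and exactly linear methylation relations. Real
EST libraries have composition biases, real microarray contrasts have
correlated probes and batch effects, and real SAM/SAH measurements carry
assay error on both axes. Recovery rates on synthetic data (≥ 95% EST
labels, ≥ 90% planted modulated genes, ≥ 80% methylation classes at the
default seeds) therefore validate the *logic and calibration* of the
pipeline, not its field performance on raw public data. The published
tissue-profile and correlation figures are not reproducible at desk scale —
the underlying UniGene tables and tissue SAM/SAH measurements are not
printed — and the package does not attempt them.

## Numerical and calibration notes

* Display rounding is half-away-from-zero everywhere (`round_half_away()`),
  both for integer percentages and one-decimal summaries.
* Null calibration of modulation calling: with no planted effects and log2
  noise around 1.5, the fraction of genes called modulated tracks the
  t-test's size (≈ 0.05), because the p ≤ α criterion is then the binding
  constraint. At the default noise of 0.3 the fold-change gate (fc ≥ 2)
  dominates and the null call rate is essentially zero — the procedure is
  conservative for well-measured data. Both regimes are asserted in the
  test suite.
* Correlation significance is exactly the Pearson-t test; on null data the
  significant fraction matches α within Monte-Carlo error (1000 replicates),
  and the hypo/hyper/non partition's residual error on synthetic panels is
  the expected family-wise false-positive rate of three α-level tests on
  n = 6 tissues.
* Degenerate inputs fail loudly: zero-variance vectors, fewer than three
  tissues, non-positive library totals or fold changes, and panels whose
  membership counts are wrong all raise typed errors.
* Test problem sizes (1000-replicate calibrations, 1000 random collections
  for the overlap oracle, 15 × 68 null genes) were chosen so the full suite
  completes in well under a minute while keeping Monte-Carlo error small
  relative to the asserted bands.

## Known limitations

* The EST threshold rule is a stated stand-in for an unpublished
  derivation; per-gene or per-tissue thresholds are not offered.
* Mouse homology by case convention fails for genes whose official mouse
  symbol is not the case-folded human one; the panel's `mouse_symbol`
  column is authoritative where it differs.
* Fold-change tables are consumed as given: the package does not estimate
  differential expression from raw arrays.
* Pathway annotation of overlap regions is out of scope; regions report
  gene symbols only.
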