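---
title: "Mapping somatic alterations to single cells: methods and design"
author: "scvarmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping somatic alterations to single cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`scvarmap` implements the computational core of a single-cell genotyping
workflow for solid tumors, with pancreatic ductal adenocarcinoma (PDAC)
and its transitional precursor populations (acinar-to-ductal metaplasia,
ADM; pancreatic intraepithelial neoplasia, PanIN) as the motivating
setting. The workflow answers a concrete question: *given somatic
variants called from bulk whole-exome data, do the variant-supporting
molecules in barcoded scRNA-seq preferentially come from neoplastic
cells?* Around that core sit the supporting procedures a study of this
kind needs: consensus filtering of multi-caller variant call sets,
per-cell UMI-aware allele counting, a difference-of-proportions
enrichment statistic, expression QC and subcluster program analysis, and
arm-level summarization of gene-level copy-number estimates.

Everything is exercised on a fully seeded synthetic cohort with known
ground truth; the package ships no patient data and requires none.

# The synthetic cohort: what it emulates

`sim_config()` fixes the study conditions; a single integer seed
determines every output byte-for-byte. The default cohort has five
compartments — tumor (1,000 cells), PanIN (600), ADM (400), normal duct
(600), acinar (400), roughly 3,000 cells across three spatial samples of
one case — with these planted effects:

* **Mutation mapping.** At each of 8 variant sites (the first four in
  KRAS, CDKN2A, SMAD4, TP53), each cell yields a variant-supporting
  molecule with probability `mapping_rate[group]`: 0.30 in tumor, 0.15
  in PanIN, 0.05 in ADM, 0.01 in the normal compartments. The normal
  rates model ambient/chimeric noise; the PanIN and ADM rates encode
  the biological claim that early driver alterations are present in
  transitional populations at intermediate frequency.
  Reference-supporting molecules arrive at a fixed Poisson rate
  (0.5/cell/site) so total coverage is never structurally zero.
* **UMI structure.** Each molecule is emitted as `1 + Geometric`
  duplicate reads sharing a (cell barcode, UMI) pair
  (`umi_dup_rate = 0.3`), and each duplicate read flips to another
  allele category with probability 0.01. This creates exactly the
  within-UMI conflicts the consensus rule must resolve.
* **Call sets.** Somatic records independently violate each consensus
  rule with probability 0.15 and record the intended pass/fail;
  deterministic boundary records pin every threshold exactly (tumor VAF
  0.05, normal VAF 0.02, depths 14/8, indel lengths 99/100, zero-depth
  samples, population frequency exactly 0.05%).
* **Expression.** Negative-binomial counts (`dispersion = 2`, ~2,500
  counts/cell) over a 500-gene panel. Each tumor subcluster carries a
  program of 50 genes at log2 fold change 2. Program genes have a low
  fixed baseline (mean 1 count/cell) outside their cluster — cluster
  markers are genes largely off elsewhere; a program planted on
  ubiquitously detected genes would be invisible to any
  detection-fraction prefilter, which is a property of marker
  detection, not a defect of it. Mitochondrial genes contribute ~5% of
  a normal cell's counts.
* **CNV.** A cells-by-genes matrix at 1.0 = neutral with Gaussian noise
  (sd 0.1), an arm gain of +0.5 on 8q and a loss of −0.3 on 18q in
  tumor cells, and deep focal events (AKT2 +1.5 in 30% of tumor cells,
  SMAD4 −1.2 in 20%).
* **Geography.** Samples at (0,0), (10,0), (12,0) mm; tumor subcluster
  C1 draws 98% of its cells from S1, planting one spatially distinct
  subcluster (S1 is ≥6 mm from both other samples) and one negative
  (S2/S3 are 2 mm apart).

What the generator does **not** emulate: transcriptome-wide coexpression
structure, doublets, barcode errors, batch effects, read-level sequence
content, or any realistic gene-length/GC structure. Tests passing on
this cohort therefore demonstrate the *procedures* are correct under
their stated models, not that the models capture everything in real
droplet data.

Because the panel holds 500 genes, the ">10,000 genes expressed" QC
violation cannot occur in generated data; the generator plants
violations of every attainable threshold and the max-genes branch is
exercised on a constructed sparse matrix in the unit tests.

# Consensus variant filtering

`filter_somatic()` passes a record iff **all** of: support by ≥2 callers
within the class's caller set (SNVs: Strelka/VarScan/MuTect; indels:
Strelka/VarScan/Pindel); tumor depth ≥14 and normal depth ≥8; tumor VAF
≥0.05; normal VAF ≤0.02; indel length <100 (strict); exonic; and not
(in dbSNP and absent from COSMIC). `filter_germline()` requires alt
depth ≥5 **and** alt fraction ≥0.20 in both tumor and normal, a coding
location, and population frequency <0.05%. Every boundary is implemented
with exactly the printed operator; the fail table lists all violated
rules per record.

Numerical conventions, each configurable:

* **VAF** is `alt/(ref+alt)` — the biallelic, bam-readcount-style
  convention; "depth" likewise means `ref+alt`, not total pileup depth.
* Zero depth in either sample makes the VAF undefined; the record fails
  with reason `no-depth` rather than crashing or dividing by zero.
* Hotspot genotyping (`hotspot_vafs()`) uses `count(alt)/(count(alt) +
  count(ref))` per alternate base, so two alternates at one locus each
  get their own denominator.
* dbSNP/COSMIC membership and exonic status are consumed as boolean
  annotations; database matching and region annotation are upstream
  concerns. Multi-allelic VCF rows are rejected; sites must be
  pre-split.

# Per-cell allele counting and labeling

`dedup_umis()` collapses reads sharing (cell, site, UMI) to one molecule
whose allele is the **strict majority** of its reads; exact ties and
`other`-majority UMIs are discarded but counted, so
`ref + alt + discarded` always equals the number of distinct UMIs — an
invariant the tests enforce. Majority-with-tie-discard is the
conservative choice where no consensus rule is prescribed; raw-read
counting is available (`collapse = FALSE`) since "reads supporting"
could also be read literally. Barcode equivalence is exact string match:
barcode error correction belongs to demultiplexing.

`classify_cells()` labels each covered (cell, site) pair `reference`,
`variant`, or `variant_reference` (both alleles seen); the
minimum-molecule threshold defaults to 1. `label_cells_hierarchical()`
reduces multiple alterations per cell to one display label: mutations
outrank copy-number events, and within a kind the hierarchy is
KRAS > CDKN2A > SMAD4 > TP53, with other genes after it alphabetically.
Gains order before losses on the same gene as a deterministic
tie-break.

# The mapping-enrichment statistic

With `X_T` variant-supporting and `N_T` total molecules pooled over a
test group's cells and sites, and `X_N`, `N_N` for the comparison group:

$$P_T = X_T/N_T,\quad P_N = X_N/N_N,\quad
P_{avg} = \frac{X_T+X_N}{N_T+N_N},\quad Q_{avg}=1-P_{avg}$$

$$Z = \frac{|P_T-P_N| - \tfrac12\!\left(\tfrac1{N_T}+\tfrac1{N_N}\right)}
{P_{avg}\,Q_{avg}\sqrt{\tfrac1{N_T}+\tfrac1{N_N}}}$$

and the one-sided p-value is the upper-tail standard-normal probability
of `Z`. The test is only performed when `P_T > P_N` is actually
observed; skipped contrasts carry a reason and are excluded from the
Benjamini–Hochberg adjustment, so the FDR is controlled over the tests
actually run. The classical heuristic `N·P_avg·Q_avg ≥ 5` is reported as
`normal_approx_ok` but does not suppress a result.

**A note on the denominator.** The default denominator places
`P_avg·Q_avg` *outside* the square root. The textbook pooled standard
error is `sqrt(P_avg·Q_avg·(1/N_T+1/N_N))`; since `P_avg·Q_avg ≤ 1/4`,
the default denominator understates the standard error by the factor
`sqrt(P_avg·Q_avg)` and inflates `Z` at least twofold. Simulated null
contrasts (equal rates, 10,000 draws) reject at roughly 0.15–0.35 at
α = 0.05 under the default form, versus ~0.04 under the pooled form —
the continuity correction and the one-sided skip rule make the *pooled*
test conservative, not the default one. The default is kept for
fidelity to the procedure as published;
`compute_mapping_z(..., variance_form = "pooled")` gives the
statistically calibrated alternative, and the acceptance suite measures
both so the difference is always visible. Where the default form is
used, its p-values should be read as strong orderings rather than
calibrated tail probabilities.

Pooling operates on UMI-collapsed molecules by default (raw reads via
the mapper's `collapse = FALSE`), mirroring the mapper. Tests failing
the normality heuristic are flagged, not dropped.

# Expression programs

* **QC** removes a cell iff any of: counts <300, genes <200, UMIs
  <1,000, genes >10,000, UMIs >10,000, mitochondrial fraction >0.10
  (strictly). Counts and UMIs are the same quantity in droplet data, so
  the effective lower floor is 1,000; both are applied independently as
  stated.
* **Normalization** scales each cell to the median depth and applies
  `log1p` — a deterministic stand-in for variance-stabilizing
  transforms, which are out of scope.
* **Markers** (`find_degs()`) are one-vs-rest two-sided Wilcoxon
  rank-sum tests on the normalized layer with a tie-corrected normal
  approximation and no continuity correction, after Seurat-style
  prefilters: `max(pct_in, pct_out) ≥ min.pct` (0.25 global profile /
  0.1 subcluster profile), `pct_in − pct_out ≥ 0.1` under the
  subcluster profile, positive fold change only. Fold change is the
  natural-log ratio of mean `expm1` expression (+1), the wrapper
  convention of the tool the procedure names. P-values are Bonferroni
  adjusted against the full panel by default (BH available), filtered
  at adjusted P <0.05 and sorted by fold change.
* **ORA** (`ora_hypergeometric()`) is the upper-tail hypergeometric
  probability of the observed overlap between a marker list and each
  gene set, both intersected with a stated universe (genes detected in
  the analyzed cells), BH-adjusted across sets.
* **Pathway scores** take, per pathway, the union over clusters of the
  *overlap genes* behind significant enrichments (adjusted P <0.05) —
  the narrower of the two readings of "genes shown as enriched"; whole
  sets are available via `whole_set = TRUE`. The score is the mean
  normalized expression of those genes per cluster, centered and scaled
  across clusters with the sample (n−1) standard deviation; constant
  rows score 0 and are flagged. Clusters under 0.1% of total cells are
  excluded first; pathways rank by how many clusters show them
  significant.
* **Spatially distinct clusters** require ≥95% of a cluster's cells
  from one sample that lies ≥6 mm from *every other* sample
  contributing cells to the case (the stricter of the two readings of
  "6 mm from another sample"); both boundaries inclusive.
* **FPKM-UQ** follows the GDC formula
  `count·10⁹/(length·UQ)` with UQ the 75th percentile (default quantile
  type) of positive counts over protein-coding genes, then
  `log2(x + 1)`. A zero upper quartile marks the sample unusable.

Clustering itself (neighbors/Louvain, PCA dimensions, resolutions) is
consumed as input labels throughout: results stay reproducible without
re-matching a third-party implementation's internals.

# Arm-level CNV

`map_genes_to_arms()` assigns `p`/`q` from the cytoband's first
character, or from gene start versus centromere position with
coordinate input; missing bands (e.g. mitochondrial genes) stay
unmapped and excluded from means. `arm_level_means()` is the unweighted
per-cell mean over an arm's mapped genes — deliberately literal, no
length weighting. `call_deep_events()` thresholds values on the
declared scale (1.0 = neutral; log-ratio input converted as `2^x`);
"more than one copy" on a continuous expression-derived scale is
inherently fuzzy, so the defaults (gain ≥2.0, loss ≤0.1) are
conservative and fully configurable. The copy-number inference itself
(inferCNV/CopyKAT-class tools) is consumed as input, never
re-implemented.

# Problem sizes and verification

The test suite runs the default ~3,000-cell cohort end-to-end, 100
seeded replicates of the two-group enrichment recovery (500 cells per
group at rates 0.30 vs 0.01), 50 seeded replicates of the pathway
pipeline at 100 cells per cluster, 10,000-record filter oracles and
10,000 null contrasts; the full suite completes in well under a minute
on one CPU. Oracles are independent of the paths they check: the Z
formula against an arbitrary-precision (mpmath, 50-digit) evaluation;
the rank-sum test against `stats::wilcox.test`; ORA against exhaustive
enumeration of all draws on small universes; the filters against a
literal record-by-record re-application of each rule; the mapper
against generator ground truth at zero error rate. P-values are
compared where they are representable as normal doubles (above
~2.2·10⁻³⁰⁸); beyond that the floating-point format, not the
implementation, quantizes the value.

# Known limitations

* The default Z denominator is as published and therefore
  anticonservative (see above); calibrated inference should use the
  pooled form.
* The generator's compartments are expression-independent of the
  mutation process: mapping rate depends only on the group label, so
  mapping/expression correlations beyond group structure are not
  modeled.
* Indels and SNVs share the simple biallelic observation model; no
  alignment artifacts around indels are simulated.
* `spatial_distinct_clusters` treats geography at sample resolution;
  within-sample spatial structure is out of scope.
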