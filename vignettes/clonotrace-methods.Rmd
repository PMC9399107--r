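---
title: "Methods behind clonotrace: repertoire and microenvironment statistics for paired scRNA + scTCR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind clonotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotrace)
library(dplyr)
```

clonotrace implements the statistics that tumor single-cell atlases with
matched TCR sequencing are built on. This vignette explains each method, its
assumptions, the tunable parameters, the numerical choices made where the
procedure is conventionally under-specified, and what the synthetic-data
tests do and do not establish about real data.

## Quality control and normalization

Cells are filtered on three per-cell statistics — total UMI count, number of
detected genes, and mitochondrial count fraction — with defaults of 400, 200
and 30% (20% is the common convention for T-cell compartments, passed via
`qc_config(max_mito_frac = 0.20)`). All thresholds are **strict** in the
stated direction: a cell with exactly 400 UMIs, 200 genes and a 30.0%
mitochondrial fraction is retained; one with 399 UMIs is not. Genes detected
in fewer than 3 cells are removed **after** the cell filter, so a gene seen
only in low-quality cells disappears with them. QC is idempotent on typical
data, though this is an empirical property, not an algebraic one: removing
rare genes can in principle push a borderline cell below a threshold on a
second pass.

Normalization is per-cell library scaling followed by `log2(1 + x)`:

$$\mathrm{lognorm}_{cg} = \log_2\!\left(1 + s\,\frac{n_{cg}}{\sum_g n_{cg}}\right)$$

The scale factor $s$ (default 10,000) is a display convention; it is exposed
because downstream magnitudes (e.g. CNV clipping) depend on it. An exact
consequence used as a test invariant: $\sum_g (2^{\mathrm{lognorm}_{cg}} - 1) = s$
for every cell.

## Gene-set and tumor scores

Two per-cell scores are provided. The **z-score mean**: each set gene is
standardized across cells and the score is the mean of the standardized
values (genes with zero variance contribute 0). It is invariant to adding a
constant to any gene and weights every set gene equally regardless of
expression level.

The **bin-matched control score** compares a set's mean expression with that
of expression-matched control genes: genes are ranked by mean expression and
cut into `n_bins = 24` equal-size bins; for each set gene, `n_ctrl = 100`
controls are drawn with replacement from its bin; the score is
mean(set) − mean(pooled control draws). The bin count, control count and
with-replacement sampling mirror the widely used module-scoring convention;
a single seed controls the draws, so scores are reproducible and two calls
with the same seed agree exactly. The **tumor score** is the difference
between the binned scores of a malignant and a non-malignant signature; the
package deliberately takes these as arbitrary gene sets (GMT input) rather
than hardcoding any published list.

## Differential expression

Per gene, a two-sided Wilcoxon rank-sum test on log-normalized values
(exact when samples are small and tie-free, tie-corrected normal
approximation otherwise), with Bonferroni correction over the genes
actually tested — not the genome. The fold change is reported as the
difference of group means in log space; this matches the space the test
operates in and avoids the instability of ratios of sparse means (the
alternative is a documented config choice, not a hidden one). DEG
intersection across single-cell and bulk experiments uses the standard
strict filters (bulk: adjusted p < 0.05, |log2FC| > 1; single-cell:
adjusted p < 1e−10, |log2FC| > 1, detection rate outside the focal
compartment < 5%). Multi-dataset co-expression uses Spearman correlations
(average ranks on ties) multiplied across datasets; an undefined
coefficient (constant vector) makes the combined value missing, never zero,
because "no evidence" must not masquerade as "no association".

## Copy-number profiles and CNV score

The CNV profile is a transparent reimplementation of the
expression-smoothing approach used by reference-based CNV callers:

1. order genes by (chromosome, start);
2. center each gene by its reference-cell mean (reference = cell ids the
   caller designates, conventionally immune + stromal cells);
3. clip residuals at ±`clip` (default 3) reference standard deviations, with
   the SD floored at 0.1 so that near-constant genes cannot blow up;
4. moving-average over `window = 101` genes within each chromosome. Windows
   truncate at chromosome edges (every average spans at least half a
   window) and never cross chromosome boundaries, since copy-number events
   are intra-chromosomal;
5. re-center each cell by its median (removes per-cell baseline shifts);
6. re-center each gene by its reference mean, so reference columns average
   to zero exactly.

`cnv_score` is the mean of squared profile values per cell — a burden
statistic that is zero iff the profile is flat and invariant to gene order.
The window trades resolution for noise: a 101-gene window suppresses
single-gene programs (which is the point — expression programs are the main
confounder) but smears segment boundaries by up to half a window, which is
why boundary recovery is asserted only to ±50 genes. On sparse droplet data
the per-gene residual noise (SD ≈ 1 in log space) leaves residual profile
fluctuation of order $1/\sqrt{101} \approx 0.1$ even for null cells; the
flat-profile test therefore uses a deep, low-dispersion fixture, while the
sparse-data null is covered by requiring query and reference score
distributions to overlap (median ratio within [0.8, 1.25]).

## Ro/e tissue enrichment

For a cluster × tissue count table, expected counts are the chi-square ones,
$E_{rc} = \text{(row total)}\,\text{(col total)}/n$, and Ro/e $= O_{rc}/E_{rc}$.
Entries with a zero margin are undefined and propagate as missing — 0/0 is
not evidence of depletion. Enrichment is strict: Ro/e > 1. Two exact
identities serve as tests: the expected-count-weighted mean of Ro/e along
any row is 1, and the table is invariant to uniform scaling.

## Clonotypes and repertoire statistics

**Identity.** A clonotype is the multiset of productive (chain, CDR3)
sequences of a cell; cells with identical multisets within one patient share
a clonotype, and identical sequences in different patients never merge.
Nucleotide CDR3s are the default key (the strictest common choice);
amino-acid keying is available. Cells without a productive TRB are excluded
from the T-cell analysis set, and cells with more than two TRA or more than
two TRB chains are flagged as doublets (cells with exactly two of either are
real, quantified populations and are kept).

**Expansion** is the fraction of a cluster's TCR-bearing cells in clonotypes
of size ≥ 2. The field has no single formula for "expansion score"; the
clonal-cell fraction is the simplest one consistent with the clonal/
non-clonal dichotomy and is documented as such.

**Migration** between blood and solid tissue uses the Morisita–Horn index on
clone-size distributions,
$MH = 2\sum_i T_i B_i \big/ \sum_i (T_i^2 + B_i^2)$ with $T_i, B_i$ the
within-compartment relative clone sizes. It is 1 for identical relative
compositions, 0 for disjoint repertoires, symmetric, and invariant to
scaling either compartment. "Solid" pools tumor + paratumor by default
(tumor-only is a switch). Clusters missing a compartment give a missing
index, not zero.

**Sharing matrix.** Entry (r, c) is the fraction of (by default clonal)
clonotypes with a cell in primary cluster r that also have a cell in
secondary cluster c. Rows are independent conditional fractions; the
diagonal is 1. Whether the published convention restricts to clonal
clonotypes is ambiguous, so both modes exist with `clonal_only = TRUE` as
default — singletons cannot span two clusters, so including them only
dilutes rows.

**Clonal aggregation.** Per clonotype, the statistic is the maximum over
clusters of the share of its cells in that cluster. The null vector
recomputes the statistic after shuffling cluster labels across all
compartment cells (preserving cluster sizes); real and null vectors are
compared with a two-sided rank-sum test. One permutation replicate is the
default (matching the convention of comparing n real vs n permuted
clonotypes); `n_perm > 1` pools replicates. Because real and permuted
vectors share the clone-size composition, the test is slightly conservative
when few clonotypes are available; calibration is within the expected band
once a few hundred clonotypes enter (the scale at which the statistic is
used in practice).

**VDJ usage.** Per cluster, the fraction of productive chains carrying each
V/D/J gene (TRA and TRB pooled); columns z-scored across clusters
(zero-variance columns dropped); PCA on the standardized matrix. Scores are
reported with explained-variance fractions. Clusters with near-exclusive
usage of one gene (the invariant-chain MAIT pattern) appear as embedding
outliers.

## Ligand–receptor permutation test

Analysis units are **sections** — (subtype, tissue) combinations with
Ro/e > 1 — so that inter-tissue context is preserved. Per patient, sections
with < 20 cells are excluded; a (pair, sender, receiver) record is tested
only when the ligand is detected in > 30% of sender cells and the receptor
in > 30% of receiver cells (ineligible records are reported as untested,
not as p = 1). The observed statistic is the mean of the ligand's mean
log-normalized expression in the sender and the receptor's in the receiver —
the statistic is not fully pinned down in common descriptions of the
approach, so this package states it explicitly. The null permutes section
labels jointly across all the patient's sectioned cells 1000 times
(section sizes preserved), and

$$p = \frac{1 + \#\{\text{permuted} \ge \text{observed}\}}{n_{\mathrm{perm}} + 1},$$

the add-one convention that keeps p strictly positive. Untrimmed means over
all section cells (zeros included) are used. Cross-patient aggregation
counts a (pair, direction) as a network interaction when significant
(p < 0.01) in at least one patient; edges carry the count and the fraction
of eligible patients significant; node weight is the count of incident
significant interactions. Direction matters: ligand-in-A→receptor-in-B and
the reverse are distinct records.

## The synthetic generator

`synthetic_config()` defines the study conditions the test-suite runs
under; all parameters are config fields, chosen once to be realistic at desk
scale, and `synthetic_null_config()` switches every planted effect off:

* **3 patients × 2000 cells × 1000 genes** on 5 autosomes plus a 10-gene
  chrM block targeted at a 5% mitochondrial fraction. 2000 cells/patient
  keeps ≥ 100 clonal clonotypes in each CD8 cluster, which is what
  repertoire fractions need for stable estimates.
* **Counts**: negative binomial, gene means log-normal (log-mean log 0.5,
  log-sd 1.2 — median ≈ 0.5 counts/gene, i.e. droplet-like sparsity),
  dispersion θ = 2, per-cell log-normal size factors (sd 0.3). NB is the
  standard droplet-count assumption.
* **Clusters**: tumor and normal epithelium, stroma, two CD4 and five CD8
  states with tissue preferences (tumor cells 90% in tumor tissue, blood
  effectors 70% in blood, and so on), each with a 30-gene program at
  log2FC 1.5.
* **CNV**: one 150-gene 2× amplification on chr2 in the Tumor cluster.
* **Clonotypes**: discrete power-law clone sizes, $P(k) \propto k^{-2.5}$
  up to 50 — mostly singletons, a heavy clonal tail, as TCR repertoires
  show. A sharing chain resident → Tc17 ↔ exhausted is planted at overlap
  0.4 against a 0.05 within-compartment background. The entry edge is
  directional so that the Tc17 hub's total outgoing spill probability stays
  within the spill budget of small clones (a clonotype of size s can seed at
  most s − 1 other clusters); when the budget binds, stronger planted edges
  claim it first. Designated clusters have clones forced to span
  blood + solid tissue with cluster-specific probabilities (high for blood
  effectors and MAIT, low for exhausted cells).
* **VDJ**: per-cluster categorical usage with mild preferences; the
  MAIT-like cluster uses one TRAV gene at 90%.
* **L–R**: 20 pairs with moderate baseline expression (so detection clears
  the 30% bar); two planted tumor-section interactions between Tumor and
  Stroma at a 6× mean boost.
* A small fraction of T cells (0.5%) receives a third TRB chain to exercise
  doublet flagging.

What passing recovery tests shows: the implementations detect exactly the
signals planted, at the planted location and direction, and stay calibrated
when nothing is planted. What it does not show: robustness to ambient RNA,
batch effects, misassigned clusters, transcriptome-wide covariance
structure, or non-NB noise — real-data properties the generator does not
emulate. The generator's purpose is correctness testing, not splatter-class
realism.

## Numerical choices and degenerate inputs

* Strict inequalities everywhere a published threshold reads "less
  than"/"greater than"; boundary cases are pinned by tests.
* Empirical p-values use the add-one pseudocount; permutation comparisons
  use ≥ (ties count as exceedances).
* Spearman ties get average ranks; rank-sum ties get the tie-corrected
  normal approximation.
* Undefined quantities (zero Ro/e margins, empty MH compartments, constant
  correlation vectors) are reported as missing, never as 0 or 1.
* Clonotype ids are deterministic given the input (dense rank of the sorted
  chain multiset within patient), so shuffling input rows cannot change the
  partition.
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state (`withr::with_seed`).

## Problem sizes used by the test-suite

Oracle equivalences run on exhaustive small grids (all clone-size vectors
over ≤ 4 clonotypes with sizes ≤ 3; all 70 label assignments of 8 cells).
Calibration checks use one patient at 200–1500 cells: 1000 null genes for
DE (expected false-positive rate 5%), 200 seeded repertoire simulations for
the aggregation test, and ≥ 500 tested pair-directions at 1000 permutations
for the L–R test. Recovery checks run the full default configuration above.
These sizes were chosen so the whole suite exercises every claim in minutes
on a single CPU while keeping Monte-Carlo error well inside the asserted
bands.

## Known limitations

* The CNV module is a smoothing estimator, not an HMM segmenter; it reports
  relative expression deviations, and absolute copy numbers are out of
  scope.
* The aggregation test's real and permuted vectors are dependent (same
  cells), which makes it conservative at small clonotype counts.
* The L–R statistic uses untrimmed means; a few extreme cells can drive a
  record (the permutation null accounts for this globally, not per cell).
* Clonotype identity ignores sequencing errors in CDR3s; two reads of one
  clone differing by one nucleotide are distinct clonotypes under the
  nucleotide key.
* The expansion score is one reasonable formalization of "clonal expansion";
  alternatives (e.g. normalized Shannon-entropy-based indices) are not
  provided.
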