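---
title: "Comparing global transcriptome properties across cell types"
author: "txglobals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing global transcriptome properties across cell types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txglobals)
```

# Scope and model

`txglobals` quantifies two global properties of a cell type's
transcriptome and the relationship between them:

1. the **proportion of highly expressed genes** — how the number of genes
   at or above an FPKM threshold changes as the threshold rises, with
   ≥ 20 FPKM as the landmark for "highly expressed"; and
2. the **number of alternatively spliced transcripts expressed per gene**,
   summarized as its reciprocal, the *genes-per-transcript ratio*: at a
   threshold *t*, the number of distinct genes with at least one passing
   transcript divided by the number of passing transcripts. The ratio
   lives in (0, 1]; it is exactly 1 when no gene has two passing isoforms,
   and it falls as more isoforms per locus are expressed.

Both statistics are computed per sample on a shared threshold grid, then
summarized per cell type as mean ± SEM over biological replicates (SEM
uses the *n − 1* standard deviation over √n; with the typical two
replicates this is half the absolute replicate difference). Cell types
can then be clustered on their count curves, tested for a two-group
difference, and interrogated for the association between splicing
activity and the proportion of highly expressed genes.

All threshold comparisons are **inclusive** (≥). Source material in this
area alternates freely between "above 1 FPKM" and "≥ 1 FPKM"; one
convention has to be picked and applied uniformly, and inclusive
comparison keeps the boundary gene inside the set it is normally
described as belonging to. The two DE expression filters that are
explicitly phrased as "above" a value (5 FPKM for the fold-change
histogram, 1 FPKM for the length comparison) use strict >.

# Input model and normalization

Expression tables enter as Cufflinks-style tracking files
(`tracking_id`, `gene_id`, `length`, `<sample>_FPKM` columns) or as the
package's bit-exact generic TSV dialect (`transcript_id`, `gene_id`,
`length`, one plain column per sample; values written with 17 significant
digits so write → read round-trips are exact). Rows with non-numeric
FPKM fields are rejected with their row numbers and counted — rows kept
plus rows rejected always equals rows read. Gene-level FPKM, when not
supplied directly, is the **sum of isoform FPKMs**, matching Cufflinks'
gene abundance semantics; the gene length is recorded as the maximum
isoform length.

Upper-quartile normalization rescales sample *s* by mean(UQ)/UQ(s),
where UQ(s) is the 75th percentile of the sample's **strictly positive**
values, with linear interpolation between order statistics
(`quantile(type = 7)`). Two decisions are deliberate:

- *positive values only*: including zeros would make the statistic depend
  on how many unexpressed annotation entries happen to be present, i.e. on
  annotation size rather than on the expressed transcriptome;
- *linear interpolation*: the exact quantile rule is rarely stated in
  published pipelines; type 7 is R's default and the choice is recorded
  here so results are reproducible to the last digit.

After one application all per-sample upper quartiles are equal, so the
operation is idempotent.

Replicate-correlation QC defaults to Pearson correlation of
log2(FPKM + 1)-transformed values. Raw-FPKM Pearson is dominated by a
handful of very highly expressed genes; whether published correlation
tables used raw or logged values is usually unstated, so both are
supported (`transform = "none"`), and the bundled 16-sample reference
correlation matrix is consumed as printed values, where the question does
not arise.

# Clustering: uncentered Pearson, centroid linkage

The similarity is uncentered Pearson,
$s(x, y) = \sum_i x_i y_i \big/ \sqrt{\sum_i x_i^2 \sum_i y_i^2}$ —
Pearson's formula without mean-centering, i.e. the cosine about the
origin. It is scale-free but origin-sensitive, which is what makes it
appropriate for non-negative expression profiles: two samples with
proportional profiles are maximally similar regardless of depth.

Agglomeration follows Gene Cluster 3.0's centroid linkage: merge the pair
of active clusters with maximal similarity; represent the merged cluster
by the **unweighted mean of its member leaves** (not a size-weighted
running mean); recompute similarities against that centroid. Distances
are 1 − similarity and merge heights are reported exactly as computed.
Centroid linkage can produce height inversions (a later merge lower than
an earlier one); the dendrogram records them — silencing inversions would
misrepresent the geometry. Ties on similarity are broken by the
lexicographically smallest pair of cluster creation indices, making the
merge sequence deterministic across platforms.

One property that might be expected does *not* hold and is worth stating:
although the similarity is scale-free, the full tree is **not** invariant
to rescaling a single item's profile, because the centroid of a merged
cluster shifts when one member is rescaled. The package's tests assert
what is true — pairwise similarities and the first merge are scale-free,
and rescaling the whole matrix leaves the tree unchanged.

Expression-profile clustering (samples as items) first filters to genes
at ≥ 1 FPKM in at least one sample and applies log2(FPKM + 1) by
default. Heat-map conventions in the literature (red/green about a
center) imply centering for *display*, not necessarily for clustering;
the log transform is used here because raw-FPKM cosine similarity is
dominated by the same few genes that dominate raw correlation, and the
choice is exposed (`transform = "none"` reproduces the raw behaviour).
Threshold-curve clustering (cell types as items) uses the per-cell-type
mean count curves directly; counts are all positive and on one scale, so
no transform is applied. A k = 2 cut of that tree is the segregation of
cell types into high and low proportion of highly expressed genes.

# Two-group inference on curves

The primary test is a permutation test in which the **cell type is the
exchangeable unit** — replicates of one cell type are not exchangeable
with another cell type's, and permuting samples would overstate the
evidence. The statistic is the mean over thresholds of the absolute
difference in group means of the per-cell-type mean curves; labels are
permuted `nPerm` times and p = (1 + #{null ≥ observed})/(1 + nPerm). The
seed is a required explicit argument, and both the permutation test and
the generator restore the caller's RNG state, so no hidden global state
is consumed.

A classical repeated-measures F is reported alongside for comparability
with conventional ANOVA summaries: cell types are subjects, thresholds
the repeated (within-subject) factor, and the group F is the
between-subjects stratum of the group × threshold `aov`, sphericity
assumed. The repeated-measures designs behind published F values of this
kind are usually ambiguous (what the subjects were, what the repeated
factor was), which is why the permutation test — whose null requires only
exchangeability of cell types — is the package's primary inference and
the F is explicitly secondary.

With 8 cell types in balanced groups of 4 there are only
$\binom{8}{4} = 70$ distinct labelings, and the statistic is symmetric
under label complement, so the achievable p-value grid has steps of
2/70 ≈ 0.029: the test is mildly conservative at α = 0.05 *by
construction*, and p can never fall below ≈ 0.029. Calibration
simulations therefore use 12 exchangeable cell types (6 + 6), where the
grid (924 labelings) is much finer than α; this is a granularity
requirement of permutation testing, not a tuning of the null. Power
simulations use the study-scale design itself (8 cell types, planted
fractions 0.10 vs 0.15) with `nPerm = 499`, comfortably above the
granularity floor.

# Differential-expression summaries

DE tables are consumed, not produced: the upstream DE caller's model
(dispersion, likelihood) is out of scope, and only its output columns
matter (condition FPKMs, log2 fold of condition b over a, q-value,
status). Filters follow the printed conventions of this analysis style,
each configurable:

- fold-change histogram: q < 0.05 (strict), expression > 5 FPKM in at
  least one condition (strict), fold ≥ 3; binned by 2^|log2 fold| and
  direction (up = enriched in the high-proportion group, fixed as
  condition b);
- enriched-count curves: fold ≥ 3, q ≤ 0.05 (inclusive, as this filter
  is conventionally printed), and — the substantive rule — a gene counts
  at threshold *t* for its enriched group only if its FPKM is ≥ *t* in
  **every** cell type of that group, with the cell-type FPKM being the
  mean over its replicates; the companion ratio is high count / low
  count, flagged where the low count is zero;
- length comparison: the not-DE set takes genes > 1 FPKM whose condition
  FPKMs lie within 1% of each other — resolved as relative to the
  **larger** of the two values — with q > 0.05; the DE set takes genes
  > 1 FPKM in at least one condition with fold ≥ 2 and q < 0.05. Each
  selected gene contributes its annotated transcripts' lengths and the
  sets are compared with a Welch t-test.

The strict-vs-inclusive q comparison genuinely differs between printed
variants of these filters (< 0.05 in one place, ≤ 0.05 in another); the
defaults follow each filter's conventional phrasing and both are
switchable. Fold changes reconstructed as 2^|log2 fold| can land a few
ulps below a nominal integer fold, so fold comparisons and bin edges
apply a 10⁻⁹ relative tolerance; infinite folds (one condition at zero)
are kept as signed infinities and fall in the last histogram bin.

# The synthetic-data generator

The generator emulates the study design every analysis here assumes:
eight cell types, two biological replicates, one shared annotation. It
is the package's test bed, and its defaults are the study conditions —
they are not adjusted per analysis.

**Expression.** Each cell type draws per-gene mean FPKMs from a mixture
of two log-normals: a low component (median 1.5 FPKM, log-SD 1.0) and a
high component (median 60 FPKM, log-SD 0.8). The mixing weight is
calibrated analytically so that the *expected fraction of genes at or
above the 20-FPKM cutoff equals the cell type's target* `pHigh`:
w = (pHigh − P_lo)/(P_hi − P_lo), with P the component tail masses above
the cutoff. Using the target directly as the raw weight would miss the
realized fraction by those tail masses (the high component leaves ~8% of
its mass below 20 FPKM). Realized fractions track targets to within
±0.02 at 5000 genes, verified per cell type in the tests.

**Lineage structure.** Cell types sharing a lineage draw a fraction
ρ = 0.6 of their highly expressed gene *identities* from a shared
lineage program, the rest privately. This produces the correlated
expression programs that real developmental lineages show, and it is
what expression-profile clustering recovers (the default design spreads
eight cell types over three lineages). An optional per-cell-type
`highScale` shifts a cell type's high component upward, which plants
*asymmetric enrichment* — its highly expressed genes sit further above
any fixed threshold — used by the DE-summary recovery tests with
lineages aligned to groups. With the default cross-group lineage layout
the high group's shared program is split across two lineages and the
enriched-count ratio curve is not monotone; this is a real property of
the design, not a failure of the statistic.

**Isoforms.** Each cell type expresses 1 + Poisson(isoformMean − 1)
isoforms per gene; the shared annotation carries, per gene, the maximum
isoform count over cell types, so realized mean isoforms per expressed
gene equals the target with no truncation bias (verified to ±0.1 at
5000 genes). Gene FPKM is split over the expressed isoforms by a
symmetric Dirichlet (α = 1); unexpressed annotation isoforms are exact
zeros. Coupling of `isoformMean` to `pHigh` is left to the
configuration (`twoGroupConfig(couple = TRUE)` sets
isoformMean = 1 + 6·pHigh), so the association between splicing activity
and the proportion of highly expressed genes is a *recoverable planted
effect*, never a generator artifact.

**Replicates and noise.** Replicates of a cell type share gene means and
isoform splits and differ only by per-gene multiplicative log-normal
noise (σ = 0.25 on the natural-log scale), applied to all isoforms of a
gene jointly. This puts within-cell-type replicate correlations on the
log scale in the 0.9–0.98 regime typical of well-filtered replicated
RNA-seq, while between-cell-type correlations stay visibly lower.

**Lengths.** Transcript lengths are log-normal (median 2 kb, log-SD
0.7), bounded to [200, 100000] bp — a reasonable span for mammalian
mRNAs — and independent of expression, so length-expression correlation
analyses have a true null to recover.

**DE tables.** Condition means are the true per-cell-type gene means
averaged within each group (condition a = low, b = high); a gene is DE
in truth when the true group-mean fold is ≥ 2. q-values are *planted* —
uniform on [0, 0.01] for DE genes, uniform on [0.05, 1] otherwise —
because the consumers only need calibrated filter behaviour, and
simulating a DE caller's statistics would import a model that is out of
scope. Using true rather than emitted means keeps the table's log2 fold
exactly consistent with its condition means.

One structural deviation from a per-cell-type gene count: the number of
genes is a property of the shared annotation, not of a cell type — a
cross-sample matrix requires one feature universe — so `nGenes` lives in
the generator config, and per-cell-type specs carry only `pHigh`,
`isoformMean`, `lineage`, `group` and `highScale`.

**Determinism.** Generation order is fixed; the same config and seed
give bit-identical tables, and the generator restores the caller's RNG
state.

# What the synthetic data does and does not show

The generator reproduces the *statistical structure* the analyses
assume: calibrated high-expression fractions, isoform-count targets,
replicate correlation in the realistic regime, lineage-correlated
programs, length-independent expression, and planted group effects. It
does **not** reproduce read-level artifacts (mapping bias, positional
coverage), annotation errors, correlated isoform usage across genes,
length–expression coupling, or any absolute-scale calibration (which
requires spike-in standards and is explicitly out of scope). Passing
tests therefore demonstrate that the statistics recover planted truths
under the assumed structure — not that any particular biological dataset
satisfies that structure.

# Numerical choices and degenerate inputs

- Thresholds and filters compare with ≥ everywhere (see above); the
  default grid is log-spaced {0.125, 0.25, 0.5, 1, 2, 5, 10, 20, 50,
  100} FPKM, covering the sub-1-FPKM noise regime, the 1-FPKM expression
  cutoff and the ≥ 20 FPKM landmark; the default length-correlation bins
  are (0, 0.125], (0.125, 0.5], (0.5, 1], (1, 5], (5, 20], (20, ∞).
  Published figures of this kind rarely print their grids; these are
  decisions, not recoveries, and both are configurable.
- For the ratio statistic, a gene counts as expressed at *t* when **any
  isoform** passes (not when the gene-level sum passes), keeping the
  numerator and denominator on the same transcript-passing event.
  Gene-count curves use gene-level FPKM.
- Undefined points are flagged `NA`, never fabricated: a ratio with no
  passing transcripts, a length mean with no passing transcripts, a
  correlation bin with fewer than 3 transcripts or zero variance, a
  group ratio with a zero denominator.
- Degenerate inputs error early and name the offender: samples with
  fewer than 4 positive values (upper-quartile undefined), zero-variance
  columns (correlation undefined), all-zero profiles (uncentered Pearson
  undefined), fewer than 2 cell types per group (no exchangeability).
- Simulation scale in tests and the acceptance script: 50 seeds for the
  recovery rates at 5000 genes, 400 null simulations at 1500 genes and
  100 power simulations at 5000 genes, 200 oracle-comparison instances.
  These sizes put Monte-Carlo error well inside the asserted margins
  while keeping the default test run short.

# Limitations

- FPKM is a within-sample relative unit; between-sample statements are
  relative too, and absolute transcriptome size differences are
  invisible without spike-ins.
- The permutation test cannot reach p < 2/70 with 8 cell types in
  balanced groups; studies needing smaller p-values need more cell
  types, not more permutations.
- Centroid linkage with uncentered Pearson is the only linkage
  implemented — the semantics this package commits to; other linkages
  would silently change what the dendrogram means.
- The DE consumer trusts the upstream caller's q-values; no multiple-
  testing correction is re-done here.
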