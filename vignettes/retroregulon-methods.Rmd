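---
title: "Methods: TE-centric multi-omic analysis with retroregulon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE-centric multi-omic analysis with retroregulon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroregulon)
```

## Scope and model overview

`retroregulon` implements a transposable-element (TE)-centric analysis of
bulk multi-omic cohorts, of the kind used to study CD4+ T cells from
people living with HIV-1 who control viremia without therapy (elite
controllers, EC) against healthy controls (HC), viremic progressors (VP)
and treated individuals (ART). The pipeline has five analytic stages, and
a synthetic-data generator that emulates the statistical structure those
stages assume:

1. **Quantification** (`em_quantify`, `tpm_normalize`,
   `aggregate_families`, `log_zscale`): expression of genes and
   individual TE loci from read equivalence classes, with EM resolution
   of multi-mapping ambiguity, TPM normalization, TE-family aggregation,
   and log2/z scaling.
2. **Differential expression** (`wilcoxon_de`, `cluster_markers`,
   `select_variable`): rank-based two-group tests and one-vs-rest
   cluster markers with Bonferroni or Benjamini-Hochberg control.
3. **Clustering** (`pca`, `knn_graph`, `community_clusters`,
   `cluster_composition`): the first five principal components of the
   scaled matrix, a k-nearest-neighbor graph in PC space, Louvain
   community detection, and composition summaries per cluster.
4. **Chromatin accessibility** (`rpkm_bins`, `zscore_track`,
   `peak_te_overlap`, `family_enrichment`, `metaprofile`,
   `family_accessibility_by_cluster`): normalized binned coverage,
   peak-TE overlap under a 50%-of-peak + summit rule, TE-family
   enrichment against a size-matched random null, and family
   metaprofiles.
5. **Integration** (`link_peaks_to_tss`, `diff_accessibility`,
   `call_cisreg_pairs`; `spearman_matrix`, `anticorrelation_screen`):
   putative cis-regulatory TE-gene pairs from concordant differential
   accessibility and expression within 10 kb of a TSS, and a
   KRAB-zinc-finger (KZNF) versus TE-family anticorrelation screen.

All interval arithmetic is 0-based half-open internally; GTF and
RepeatMasker input (1-based inclusive) is converted at the file boundary,
and the TSS of a minus-strand gene is the *last base* of its annotated
interval (a base, not a boundary). A single convention applied everywhere
prevents off-by-one drift between the expression, peak and annotation
layers.

## EM quantification of ambiguous read classes

Reads compatible with several features (typically TE loci of one family,
or a TE locus inside a gene) arrive as *equivalence classes*: a feature
set plus a read count. We model a read as drawn from feature $f$ with
probability $\theta_f$ (a point on the simplex) and landing uniformly on
its length $\ell_f$, so

$$P(\text{class } c) \;=\; \sum_{f \in c} \theta_f / \ell_f ,$$

up to the positional density constant. The E-step distributes each
class's count over its features proportionally to $\theta_f/\ell_f$; the
M-step sets $\theta$ to the normalized expected counts. This is the
classic RSEM-style EM for mixture weights, and the class log-likelihood
$\sum_c n_c \log \sum_{f\in c} \theta_f/\ell_f$ is asserted to be
non-decreasing at every iteration — a violation is treated as an internal
error, not a warning. Defaults: uniform initialization, tolerance
$10^{-8}$ on $\max|\Delta\theta|$, at most 1000 iterations. TPM follows
as $(\theta_f/\ell_f)/\sum_g (\theta_g/\ell_g) \times 10^6$.

Two known limitations are deliberate: effective length equals annotated
length (no fragment-length correction), and there is no bootstrap
uncertainty. Both are out of scope for a desk-scale model and documented
rather than approximated.

Family-level expression is the **arithmetic mean of member-locus values
in the input unit** (TPM by default): "averaging the transcript levels"
reads most plainly as an expression-scale mean. A log-space mean
(`method = "log2_mean"`) is provided because the alternative reading is
defensible; the output unit records which was used.

## Rank tests and multiple-testing control

Two-group comparisons use the two-sided Mann-Whitney test with mid-rank
ties: exact enumeration when $n_A + n_B \le 12$ and there are no ties,
otherwise the normal approximation with tie and continuity correction
(`stats::wilcox.test` supplies both regimes). Fold changes are
mean-based with a pseudocount of 1 TPM, which keeps `log2FC` finite at
zero expression; on signed inputs (z-scores) the mean difference is used
instead. Cluster markers are one-vs-rest Kruskal-Wallis tests — for two
groups this equals the squared standardized Wilcoxon statistic on 1 df —
with BH adjustment within each cluster's feature list; a marker requires
FDR < 0.05 *and* positive fold change versus the rest. The 0.05 default
mirrors the nominal "significant DEGs (p < 0.05)" convention used for
cluster characterization; it is exposed as an argument.

A deliberate non-goal: negative-binomial GLM differential expression
(DESeq2-style) is not reimplemented. The rank tests are the supported
statistics; where a study also ran an NB GLM through an external tool,
that tool should be used directly.

## Sample clustering

The scaled matrix (per-feature z-scores of log2(TPM+1)) is reduced by
SVD; the **first five PCs** feed a KNN graph (Euclidean distance in PC
space, `k = 20`), whose edges are weighted by the Jaccard overlap of the
endpoints' neighbor sets (shared-nearest-neighbor weighting). Louvain
modularity maximization partitions the graph; `resolution` is exposed so
that the number of clusters is a *result*, not a constraint. These
defaults (`k = 20`, resolution 1.0, Louvain) follow the dominant
single-cell convention that "graph-based KNN clustering" evokes; sign
indeterminacy of the SVD is fixed by making each component's
largest-magnitude loading positive, and the Louvain seed is an explicit
argument, so the whole path is deterministic for fixed inputs.

Because bulk cohorts are often assembled from multiple studies, the
package does not attempt model-based integration (no method being
specified for it); instead `cluster_composition` cross-tabulates
clusters against cohort, subtype or any metadata field and tests
independence by chi-square (Monte-Carlo p when expected cells < 5), as a
batch-confounding diagnostic. On synthetic cohorts with cohort assigned
orthogonally to planted clusters this test is non-significant in ≥ 90%
of seeds.

## Accessibility enrichment and the matched random null

Binned coverage is normalized as RPKM per bin
($\mathrm{count} / (\mathrm{bin\ kb} \times \mathrm{reads\ M})$),
optionally z-scored across bins. Peak-TE association applies a **50%
threshold interpreted as the fraction of the peak covered by the TE**,
plus the requirement that the peak summit lies inside the TE. The
Methods-style phrasing ("50% overlapping threshold between each peak and
TE locus", using summit files) does not fix the denominator; we adopt the
strictest reading consistent with both elements and make the summit
requirement toggleable (`require_summit = FALSE`).

Family enrichment replaces every peak with a uniformly placed interval
of identical width (and summit offset), re-applies the same overlap
rule, and repeats this `n_draws = 100` times: the observed per-family
peak count is compared to the null mean, as
$\log_2((\mathrm{obs}+\varepsilon)/(\mathrm{exp}+\varepsilon))$ with
$\varepsilon = 0.5$ to avoid infinities, and the significance is the
permutation p-value $(1 + \#\{draws \ge obs\})/(n_{draws}+1)$ — which is
exactly super-uniform under the null. We use this permutation p as the
family-wide significance throughout: the alternative of routing TE
families through a gene-set enrichment tool is not reproduced, because
no coherent mapping of families onto gene sets is specified anywhere we
could follow. An exclusion BED (e.g. unmappable regions) restricts the
random placement when provided; mappability itself is not modelled.

Metaprofiles average reads-per-million signal in ±5 kb windows of
100-bp bins anchored at each locus's **left boundary** (lower
coordinate, regardless of strand — matching how such profiles are
conventionally drawn), 101 bins in total; windows truncated by
chromosome ends contribute missing values that are excluded from means.

## Cis-regulatory TE-gene pairs

Candidates are TE-associated peaks paired with every gene whose TSS lies
within 10 kb of the *peak interval* (distance 0 when the TSS is inside
the peak; boundary inclusive). The summit-to-TSS signed distance is
reported for ranking but not used for the cutoff — "peaks within 10 kb"
names the peak, not the summit. A pair is called when

* the peak is differentially accessible (Wilcoxon on normalized
  per-peak signal, nominal p < 0.05 and |log2FC| ≥ 0.5 by default — no
  test or cutoff being canonical, we stay within the rank-test family
  used everywhere else),
* the gene is differentially expressed at the caller-supplied adjusted
  p < 0.05, and
* (by default) the two effects are concordant in direction, since the
  motivating examples are uniformly "more accessible and more
  expressed".

At the reference paired design of n = 4 vs 4, the exact two-sided
Wilcoxon p-value cannot go below $2/70 \approx 0.0286$, so any
correction across thousands of features is degenerate — nothing could
ever pass 0.05. The recommended (and tested) pipeline therefore supplies
`wilcoxon_de(..., correction = "none")` for this small-n contrast,
consistent with nominal DEG calling at p < 0.05; with larger cohorts,
BH-adjusted stats plug into the same `expr_padj` threshold unchanged.
Gating pairs on prior family-level enrichment is deliberately *not*
done; enrichment output is reported alongside so users can apply their
own gate.

## KZNF-TE anticorrelation screen

KZNFs repress specific TE subfamilies, so their transcript levels should
anticorrelate with their targets across individuals. For every (TE
family, KZNF) pair the screen computes Spearman's rho (mid-rank ties) on
log2(TPM+1) family means, a two-sided p from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$, and BH adjustment across the full
pair grid (the multiplicity handling not being specified, we correct
over everything that was tested). The screen keeps pairs with
$\rho \le -0.3$ and $q \le 0.05$ and reports recovery of a user-supplied
known-binding list (e.g. ChIP-exo-confirmed repressor-target pairs).
Spearman rather than Kendall matches the reported "rho" from
pairwise-ranked correlation. Pooled and per-cluster screens are both
sensible; the functions operate on whatever sample subset they are
given, so per-cluster analysis is a subsetting step, not a mode switch.

## The synthetic-data generator

The generator exists to give every stage a typed input with planted,
recoverable truth; it emulates the *statistical* structure of the real
data, not its sequence content.

* **Counts**: $c_{fs} \sim \mathrm{NB}(\mu = b_f \cdot \mathrm{lib}_s
  \cdot 2^{\mathrm{lfc}\,[s\ \mathrm{affected}]},\ \mathrm{disp})$ with
  per-feature baselines drawn log-uniform from 20-200 and dispersion 0.1
  by default — the standard bulk RNA-seq noise model, and the regime in
  which rank tests are well calibrated. Planted fold changes attach to a
  group (EC/HC/VP/ART) or to a planted cluster label.
* **KZNF-TE coupling**: a per-pair standard-normal latent factor enters
  the KZNF mean as $e^{\lambda z}$ and every locus mean of the target
  family as $e^{-\lambda z}$ — a monotone negative association valid for
  rank correlation, rather than a direct copula. $\lambda$ is solved
  from the target correlation against the NB noise floor, accounting for
  the variance reduction from family-mean aggregation over $n$ loci:
  $\rho^2(\lambda^2 + \alpha)(\lambda^2 + \alpha/n) = \lambda^4$. The
  mapping ignores the Poisson-level $1/\mu$ term and the slight
  Spearman-vs-Pearson shrinkage, so realized rho is typically within
  ~0.05-0.1 of target (e.g. ≈ −0.63 realized for −0.7 requested at
  n = 128), which is ample for screens whose thresholds sit at −0.3.
* **ATAC**: background peaks placed uniformly with log-normal widths
  (median 400 bp, a realistic ATAC peak scale), planted peaks centered
  on the design's accessible TE loci with the summit inside the TE;
  per-sample tracks are Poisson per 100-bp bin with a 4-fold rate
  elevation inside peaks and an additional $2^{\mathrm{lfc}}$ inside
  planted peaks for the affected group, scaled by a per-sample depth
  factor.
* **Read classes**: reads drawn from true proportions; each read reports
  an ambiguity class containing its source feature. When classes do not
  partition the features, optional per-class weights set how often a
  read lands in a shared class — that is how "20% ambiguous mass" is
  realized while keeping every generator a pure function of
  (inputs, seed).

What the generator does **not** emulate: mappability structure, GC and
fragment-length bias, sequence homology between subfamilies, correlated
feature-feature noise, or cohort batch effects. Recovery tests passing
on this generator therefore demonstrate that the *algorithms* do what
they claim under their stated noise model — not that real cohorts are
free of the artifacts the generator omits.

## Problem sizes and numerical choices

The recovery analyses run at the cohort sizes the design mirrors: 128
samples in 4 planted clusters of 32 (lfc = 2, dispersion 0.1, 300 genes
of which 15 per cluster are markers — a 5% marker fraction typical of
transcriptome-wide contrasts); 4 vs 4 samples for the paired ATAC/RNA
contrast with 50 planted TE-gene links among 2000 genes and 200
background peaks; 128 samples for the anticorrelation screen with 5
planted pairs in a 15 × 7 grid (100 null combinations); 100k reads and
10 features for EM recovery. Null calibrations use 1000 features (rank
test) and 3000 uniform peaks against a 1500-locus family (enrichment).

Degenerate inputs are handled explicitly rather than by accident:
constant features get z = 0 and p = 1; all-zero TPM columns warn and
stay zero; classes whose abundance vanishes split their reads uniformly;
empty TE families are an error naming the family; a cluster without ATAC
samples reports NA. Ties break deterministically (feature ID in variable
ranking, index order in KNN), and every stochastic step takes an
explicit seed whose RNG state is restored afterwards.
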