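---
title: "Semi-supervised deconvolution of bulk transcriptomes: model and methods"
author: "semicam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised deconvolution: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semicam)
```

## The deconvolution model

A bulk expression profile measured on a tissue is a mixture of the profiles
of the cell types it contains. With $m$ genes, $n$ samples and $K$ cell
types, the model is

$$ y_{ij} = \sum_{k=1}^{K} x_{ik}\, p_{kj} + e_{ij}, \qquad
   Y = XP + E, $$

where $X \ge 0$ ($m \times K$) holds cell-type-specific expression,
$P \ge 0$ ($K \times n$) holds mixing proportions with every column summing
to one, and $e_{ij}$ is measurement noise. The goal is to estimate $P$ (and
$X$) from $Y$ alone, plus whatever marker-gene information is available.

A *marker gene* is expressed in exactly one cell type. Its row of $Y$ is
then proportional to one row of $P$; after dividing each gene vector by its
row sum, marker genes of cell type $k$ all collapse onto a single point,
and every other (mixed) gene lies inside the convex hull of these $K$
points. Unsupervised convex analysis of mixtures (CAM) exploits this:
cluster the normalized gene vectors, and find the $K$ cluster centers whose
simplex most tightly encloses all the others — those are the marker
clusters. This package extends the idea to the *semi-supervised* setting
where markers are known for only $L \le K$ of the cell types.

## Stage I: anchored clustering and vertex search

Known markers enter the clustering as anchors. Each of the $L$ marker sets
is averaged and every one of its genes is replaced by that average, so
k-means cannot split a marker set; the $L$ averages seed the first $L$
cluster centers, and the remaining $C - L$ centers are drawn uniformly from
the non-marker genes. Lloyd iterations with Euclidean distance run to
convergence, with two deterministic policies that matter on degenerate
inputs:

* an emptied cluster is re-seeded at the point farthest from its nearest
  center and the iteration continues; if the data contain fewer distinct
  points than centers (which happens for exactly noiseless synthetic
  mixtures, where all non-marker genes normalize to the same point), the
  largest cluster is split by fiat and the partition is kept;
* distance ties resolve to the lowest cluster index, and the anchored
  clusters are indexed first, so markers can never drift to an unanchored
  duplicate center.

The non-anchored starting centers are redrawn over `kmeans_restarts`
restarts (default 10) and the solution with the lowest within-cluster sum
of squares that keeps all $L$ anchored clusters distinct wins. We
implemented this Lloyd loop directly because the re-seed-and-continue and
forced-split policies cannot be expressed through `stats::kmeans`; on
well-separated data the partition agrees with `stats::kmeans`, which the
test suite checks.

Given the $C$ cluster centers $g_1, \dots, g_C$, the margin-of-error of a
center $g_c$ with respect to a candidate vertex set
$\{g_{v_1}, \dots, g_{v_K}\}$ is its distance to their convex hull,

$$ \delta_c = \min_{\alpha \ge 0,\ \sum_k \alpha_k = 1}
   \Big\| g_c - \sum_k \alpha_k g_{v_k} \Big\|_2 . $$

The first $L$ vertices are fixed to the anchored centers; the remaining
$K - L$ are found by enumerating all $\binom{C-L}{K-L}$ subsets of the
other centers and choosing the subset minimizing $\sum_c \delta_c$ over the
non-vertex centers (ties resolve to the lexicographically smallest index
tuple). Every gene in a selected vertex cluster becomes a marker of the
corresponding cell type, so the known marker lists grow and the $K - L$
unanchored cell types acquire de-novo marker lists.

### Solving the simplex-constrained least squares

$\delta_c$ is a tiny quadratic program. Because $K$ rarely exceeds 6–8, we
solve it *exactly* by support enumeration: the optimizer's nonzero support
is one of the $2^K - 1$ subsets, and for each subset the
equality-constrained KKT system is linear. The solver works entirely in
inner products, so the vertex search precomputes one $C \times C$ Gram
matrix and each candidate subset only indexes into it, solving each KKT
system for all non-vertex centers simultaneously (implemented in compiled
code; affinely dependent vertex sets — common after row normalization,
which places all centers on an affine subspace — fall back to a
pseudo-inverse). We first tried the classical route of non-negative least
squares on a sum-to-one-augmented system, but on normalized centers the
augmented normal equations are nearly singular and the iterative fallback
dominated the runtime; support enumeration is both exact and roughly two
orders of magnitude faster here. A projected-gradient solver remains for
the (unused in practice) case $K > 10$. The test suite validates the
solver against a dense-grid brute force to $10^{-3}$.

## Stage II: marker-constrained NMF

With a marker catalog covering all $K$ cell types, proportions are
estimated by non-negative matrix factorization of $Y$ under the
generalized Kullback–Leibler divergence

$$ D(Y \,\|\, XP) = \sum_{ij} \Big[ y_{ij} \log \frac{y_{ij}}{\hat y_{ij}}
   - y_{ij} + \hat y_{ij} \Big], $$

subject to three constraints: $X, P \ge 0$; every marker gene's row of $X$
is zero outside its own cell type's column; and every column of $P$ sums
to one. A squared-Frobenius mode is kept for comparison; KL is the default
because it consistently gave better recovery in our simulations, matching
its role as the default divergence in marker-based NMF deconvolution.

The updates are the standard multiplicative (majorize–minimize) rules with
two wrinkles:

* **Marker zeros.** The masked entries of $X$ are set to zero at
  initialization; multiplicative updates preserve exact zeros, and the
  mask is re-applied after every update as a safety net. The invariant
  "every marker row has at most one nonzero" therefore holds at every
  iteration, not just at convergence.
* **Sum-to-one columns of $P$.** A per-sample column renormalization
  cannot be compensated by any rescaling of $X$ (X has one column per cell
  type, not per sample), so plain normalize-after-update would break the
  monotone-descent guarantee. Instead the constraint is pushed *into* the
  majorization: minimizing the MM surrogate subject to
  $\sum_k p_{kj} = 1$ gives
  $p_{kj} \leftarrow b_{kj} / (a_k + \lambda_j)$ with
  $b_{kj} = p_{kj} \sum_i x_{ik} y_{ij} / \hat y_{ij}$,
  $a_k = \sum_i x_{ik}$, and $\lambda_j$ the Lagrange multiplier solving
  $\sum_k b_{kj}/(a_k + \lambda_j) = 1$ — a scalar root of a convex
  decreasing function, solved by safeguarded Newton vectorized over
  samples. Each iteration is therefore monotone non-increasing in the
  objective *and* leaves every column of $P$ exactly on the simplex. The
  Euclidean mode gets the analogous treatment (a clamped linear equation
  in $\lambda_j$, solved by bisection).

Initialization seeds marker rows of $X$ at their observed mean expression
in their own column, draws the remaining entries uniformly at the scale of
$Y$, and draws $P$ columns uniformly on the simplex; all draws are
seeded. Convergence is declared when the relative objective change drops
below `tol` (default $10^{-6}$, `max_iter` 2000); an `epsilon` guard
($10^{-12}$) protects divisions and logarithms because simulated data may
contain exact zeros after noise clipping. Restarts (`n_restarts`) keep the
best final objective; in our experiments the fit is insensitive to the
starting point, so the default is 1.

## Preprocessing and marker selection

Before deconvolution the paper-style filters apply: drop the 50% of genes
with the lowest mean expression ("low expression" is deliberately the row
mean — the simplest scale-free statistic — configurable upstream), then
keep the 50% with the highest coefficient of variation (sd/mean; a gene
with zero mean gets CV 0). Both fractions are parameters.

Markers can also be called directly from pure-cell replicate profiles: per
gene, rank cell types by mean log2 expression; test the top two groups
with a two-sided pooled-variance t-test on log2 values; call the gene a
marker of the top type if $p < 0.05$, the log2 fold change exceeds 1.5,
and the second-highest type's maximum linear expression stays below a cap
(default $2^7 = 128$, exposed as a parameter because the right value is a
property of the data's intensity scale); keep the top 100 by p-value per
type, ties broken by larger fold change then gene id. A pooled variance of
exactly zero is treated as the limit $p \to 0$ (different means) or
$p = 1$ (equal means) to avoid NaNs on noiseless data. The log2 transform
adds 1 only when values below 1 are present, since MAS5-scale intensities
are far above 1 but synthetic data need the guard. No multiple-testing
correction enters the selection itself; a descriptive Benjamini–Hochberg
summary of the selected lists is available (`marker_fdr_report`), computed
per candidate cell type over all tested genes — one reasonable reading of
a "marker FDR", documented here because others exist.

## The simulator

`simulate_dataset()` emulates the benchmark structure used to validate
marker-based deconvolution: a signature whose baseline expression per gene
is log-uniform on $[2^4, 2^{12}]$ (a realistic span for linear-scale
microarray intensities) shared across cell types, with
`markers_per_type` genes per cell type boosted `fold`-fold (default 10) in
their own column only; mixing proportions drawn $U(0,1)$ per entry and
rescaled so each sample's proportions sum to one (defaults: $K = 4$,
$n = 10$); and heteroscedastic Gaussian noise with
$\sigma_{ij} = 2^{\alpha \log_2 s_{ij}} = s_{ij}^{\alpha}$ at signal
$s = (XP)_{ij}$, with $\alpha = 0.85$ (weak) and $0.9$ (strong) as the two
study settings. Note the direction: for $s > 1$, $\sigma = s^\alpha$
*increases* with $\alpha$, so $\alpha = 0.9$ is the noisier setting; the
noise-to-signal ratio is $s^{\alpha - 1}$, largest for weakly expressed
genes. Negative post-noise values are clipped to zero by default (the
downstream factorization requires non-negative data); proportions and
noise use independently derived sub-streams of one seed so either can be
varied alone.

What the generator does *not* emulate: cross-cell-type variation of
non-marker genes (real baseline genes differ between cell types; synthetic
ones are identical, making them pure nuisance for the factorization), and
markers being literally silent elsewhere (a boosted marker keeps its
baseline in other cell types, so the stage-II zero-constraint is mildly
misspecified — as it is on real data). Passing tests on this generator
demonstrates the machinery recovers the truth it defines, at the stated
noise; it does not certify accuracy on any particular real platform.

## Study sizes used by the test suite

The end-to-end simulation study in the tests uses 20 replicates of
$m = 1000$ genes, $K = 4$, $n = 10$, both $\alpha$ settings, known markers
for $L = 0 \dots 4$ cell types at 10/50/100% of the 20 true markers per
type, the 50%/50% filters, and $C = 15$ clusters. $C = 15$ keeps cluster
granularity proportionate to the ~250 genes that survive filtering (about
17 genes per cluster) while the largest search, $L = 0$, enumerates
$\binom{15}{4} = 1365$ subsets. Known-marker subsets are drawn from the
markers that survive filtering, rotating which cell types are anchored
across replicates, mirroring how real marker lists are data-derived and
therefore survive expression filters. Under these conditions the mean
pooled Pearson correlation of fully anchored semi-CAM (weak noise) is
above 0.9 and accuracy is non-decreasing in $L$ within one standard error
of the paired differences — the orderings the method is designed to
deliver. For reference, with the true signature known the same data admit
$r \approx 0.98$: the remaining gap is the price of estimating $X$ from
250 genes under $s^{0.85}$ noise.

## Numerical and design choices, in brief

* Row-sum normalization before stage-I geometry is on by default
  (`normalize = TRUE`); stage II always runs on the unnormalized filtered
  matrix.
* Cluster centers are recomputed from the marker-averaged clustering input,
  so anchored centers stay consistent with the co-clustering trick.
* The vertex-search budget (default $10^6$ candidate subsets) turns an
  accidental combinatorial explosion into an instructive error rather than
  a hang.
* Component matching for evaluation maximizes summed row-wise Pearson
  correlation via the Hungarian algorithm (checked against exhaustive
  permutation search); the pooled correlation over all $K \cdot n$ entries
  is the headline accuracy number, with per-type correlations and
  per-sample RMSE alongside.
* Multi-seed ensembles (`run_ensemble`) align every run's components to the
  first run's by the same matching before averaging, then renormalize
  columns. Alignment is defensive: component order is fixed by the marker
  catalog, so it is usually the identity.
* Determinism: every random step (center draws, restarts, NMF
  initialization, simulator) flows from explicit integer seeds, and
  repeated runs are bit-identical.

## Limitations

Confounding covariates cannot be adjusted within the factorization;
accuracy degrades when marker genes are not close to cell-type exclusive;
$K$ must be supplied (no model-order selection); and the exhaustive vertex
search limits $C$ for small $L$ — with no anchors at all and $K = 4$,
$C \lesssim 50$ is the practical ceiling.
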