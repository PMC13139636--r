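---
title: "Enterotype stratification and community ecology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enterotype stratification and community ecology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`enterostrat` is a pipeline for stratifying gut microbial communities into
enterotypes and characterising the ecology that separates them: diversity,
biomarkers, co-occurrence structure, assembly processes, niche breadth, and
associations with host traits. This vignette explains the models the package
implements, the parameters that matter, and the design decisions taken where
the methodology is genuinely open. Everything shown here is computed by the
package's own functions and tests; no external results are quoted.

## The analysis at a glance

```{r}
library(enterostrat)

spec <- enterotype_sim_spec(seed = 11)          # study-shaped synthetic data
d    <- simulate_enterotype_dataset(spec)
tree <- simulate_yule_tree(ncol(d$counts), seed = 12, ultrametric = TRUE,
                           tip_labels = colnames(d$counts))

cfg    <- pipeline_config(d$counts, d$taxonomy, d$metadata, tree, seed = 42)
report <- run_pipeline(cfg, outdir = "results")
print(report)
```

## Enterotyping: Jensen–Shannon + PAM + Calinski–Harabasz

Communities are collapsed to genus level and converted to relative
abundances. The distance between two samples is the square root of the
Jensen–Shannon divergence,
$\mathrm{JSD}(p,q) = H(m) - \tfrac12\{H(p) + H(q)\}$ with $m = (p+q)/2$ and
$H$ the Shannon entropy in nats. The square root (rather than raw JSD) is
used because it is a true metric on the simplex; both are available via
`take_sqrt`. Zero abundances contribute $0\log 0 = 0$, so no pseudocount is
needed and the distance is exact.

Clustering is partitioning around medoids, implemented from scratch as the
classical BUILD + SWAP algorithm with all ties broken toward the lowest
sample index, so a given distance matrix always yields the same partition.
Single-swap descent can stall in a local optimum (we measured ~8% of small
random instances, where the reference implementation stalls on the identical
cost), so on small instances (n ≤ 30) BUILD is restarted deterministically
from every sample and the best SWAP result kept; the test suite verifies the
result against exhaustive medoid enumeration. Large instances use the single
canonical BUILD, where multi-start would be costly and the extra optimality
is immaterial to cluster recovery.

The number of clusters is chosen by maximising a *distance-based*
Calinski–Harabasz index over `k_range` (default 2–6): within- and
between-cluster dispersion are obtained from the sum-of-squared-distances
identity $W = \sum_c \frac{1}{2n_c}\sum_{i,j \in c} d_{ij}^2$, which
coincides with the familiar centroid formula whenever the distances are
Euclidean but avoids projecting the JSD matrix onto a truncated coordinate
space first. The mean silhouette width is reported per `k` for corroboration
but never drives the choice. Ties in CH go to the smaller `k`.

## Diversity and group comparison

Alpha diversity reports observed richness, Shannon entropy (natural log by
default, `base` switches to bits), Chao1 and ACE (the classical singleton/
doubleton and rare-taxa (≤10 reads) estimators, computed by `vegan`), and
Faith's phylogenetic diversity (total branch length spanned by a sample's
taxa, root path included by convention; `include_root = FALSE` to exclude).
No rarefaction is applied by default; `rarefy_counts()` exists for users who
want it.

Beta diversity uses Bray–Curtis on relative abundances. PERMANOVA and
PERMDISP are delegated to `vegan` (`adonis2`, `betadisper` with spatial
centroids + `permutest`), wrapped behind seeded permutation streams with the
standard `+1` p-value correction; 999 permutations by default. Two-group
univariate comparisons use Welch's t or the tie-corrected normal-approximation
Mann–Whitney U test with Benjamini–Hochberg q-values across each variable
family.

## Biomarkers

`lefse_like()` follows the LEfSe recipe for the two-class case: a
Kruskal–Wallis gate at `alpha = 0.05` on relative abundances scaled to
$10^6$, then an effect size from a one-dimensional Fisher discriminant
refitted over 30 bootstrap rounds of 2/3 subsamples (pooled covariance
ridge-regularised by $10^{-6}\times$ its mean diagonal to keep it
invertible). The reported score is
$\mathrm{sign}(\bar x_1 - \bar x_2)\log_{10}(1 + \text{effect})$ and the
threshold is 2.5. The subclass/Wilcoxon stage of the original tool is
deliberately omitted — there is no subclass structure in this design — so
score parity with the reference implementation is not a goal; the contract
is the thresholds and sign behaviour.

`simper()` decomposes mean between-group Bray–Curtis dissimilarity into
per-taxon shares; the shares sum exactly to the mean dissimilarity before
normalisation, an identity the tests assert at $10^{-9}$.

`screen_classifiers()` is a harness around six standard families (k-NN,
random forest, Gaussian naive Bayes, logistic regression, CART, gradient
boosted trees) with fixed documented hyperparameters, a stratified seeded
70/30 split, AUC via the rank (Mann–Whitney) formulation, and permutation
importance (mean test-AUC drop over 20 seeded shuffles per feature) for the
best model. The contract is the harness, not tuned performance.

## Co-occurrence networks

Taxa are pre-filtered (mean relative abundance ≥ 0.01% and prevalence ≥ 30%,
the conventional cut), then all pairwise Spearman correlations are computed
on relative abundances with mid-ranked ties; p-values use the t
approximation and are BH-corrected across all pairs; edges require
|rho| > 0.6 and q < 0.05 (both strict). Topology comes from `igraph`:
closeness defaults to harmonic centrality (well-defined on disconnected
graphs; classical closeness behind a flag), eccentricity and path lengths
are per-component/over reachable pairs, local clustering counts degree-≤1
nodes as 0, and modularity uses deterministic greedy agglomeration rather
than Louvain so repeated runs agree exactly.

## Assembly processes

**Neutral model.** `fit_ncm()` fits Sloan's neutral expectation
$\hat F(p) = 1 - \mathrm{Beta}(d;\, Nmp,\; Nm(1-p))$ for occurrence
frequency as a function of mean relative abundance, with $N$ the mean reads
per sample and detection limit $d = 1/N$ (one read — the model is silent on
this; one read is the standard choice). $m$ is estimated by bounded 1-D
least squares on the untransformed frequency scale; $R^2 = 1 - SSE/SST$ can
be negative for gross misfit and is reported as-is. Taxa are partitioned
against a 95% Wilson binomial band around the prediction at the realised
sample count. Recovery is verified by simulation: Moran-type local
communities (serial death–replacement with immigration probability $m$,
implemented in C++, 200 generations of burn-in) return $\hat m$ within a few
percent of the truth for $m \in [0.05, 0.5]$ at 50 samples × 300 taxa.

**βMNTD/βNTI.** The abundance-weighted β-mean-nearest-taxon distance is
compared with a null that shuffles taxon labels across the tree tips (999
shuffles by default, one shared shuffle per replicate across all sample
pairs); βNTI is the resulting z-score, with |βNTI| ≥ 2 read as deterministic
assembly. Pairs whose null has zero variance (e.g. two identical
single-clade communities) yield `NA` with a warning rather than aborting the
analysis; only a tree with no usable distance variation is an error.

**Raup–Crick (Bray–Curtis).** Null communities preserve each sample's
richness (taxa drawn without replacement proportional to occurrence
frequency) and reads (one individual per drawn taxon, the remainder
multinomial in metacommunity relative abundance). As with the tip-shuffle
null, each replicate draws one null community per sample and scores every
pair on it. $RC = 2[\#(null<obs) + 0.5\#(null=obs)]/n_{null} - 1$.

**Classification.** Pairs are assigned to homogeneous selection
(βNTI < −2), heterogeneous selection (βNTI > 2), dispersal limitation
(|βNTI| < 2 and RC > 0.95), homogenising dispersal (|βNTI| < 2 and
RC < −0.95), and drift otherwise. The inequalities are strict, so exact
boundary values (βNTI = ±2, RC = ±0.95) fall to drift. The pipeline
classifies within-enterotype pairs, with the metacommunity formed from the
enterotype's samples; whether between-group pairs are informative is left to
the user (`beta_nti`/`raup_crick_bray` accept any sample set).

## Niche breadth

Levins breadth $B_j = 1/\sum_s p_{js}^2$, where $p_{js}$ is taxon $j$'s
share of its own total across samples, runs from 1 (single-sample
specialist) to the number of samples. The permutation null shuffles each
taxon's abundances across samples independently (totals preserved, 1000
iterations) and classifies the observed $B$ against the null 95% band:
above → generalist, below → specialist, else neutral.

One subtlety dictated the default scale: on raw counts, $B$ is invariant to
permuting the taxon's own vector, so that null would be degenerate. The
package therefore computes the classification on per-sample *relative*
abundances — sequencing depths differ between samples, so realigning a
taxon's counts against different depths genuinely changes its profile, and
the null calibrates correctly (the tests verify ~5% non-neutral calls under
the null). `levins_breadth()` itself evaluates whatever scale it is handed,
so the textbook count-based toy values still hold.

## Host-trait association

Candidate explanatory variables (α-diversity indices, body weight, body
length, tail length, BMI = weight/length² in g/cm²) first pass an iterative
collinearity filter: while any pair exceeds |Spearman| > 0.6, the member of
the worst pair with the larger mean absolute correlation is dropped (ties to
the later column) — a deterministic rendering of the usual "drop one of each
collinear pair" instruction. The retained variables plus the enterotype
label (dummy-coded) constrain an RDA on the Hellinger-transformed genus
table (the standard transform for species data; raw scale behind a flag).
Global and marginal significance use seeded permutation tests (999).

## The synthetic data generators

The package is developed and tested against seeded generators rather than a
sequencing run, so every claim the tests make is a claim about data with
known truth.

* `simulate_enterotype_dataset()` emulates a 97-sample, two-cluster (63/34)
  gut community survey: per sample, genus-backbone compositions are drawn
  from a Dirichlet around one of two cluster base compositions
  (concentration θ = 50), read depths are lognormal around 30k, body weight
  differs by cluster (230 g vs 270 g, sd 35 g — cluster 2 heavier, so BMI
  co-varies), body/tail length do not, and season/habitat frequencies differ
  by cluster. Cluster sub-streams are seeded from the cluster's own
  parameters, which makes swapping the two clusters' parameters swap the
  generated blocks exactly.
* `simulate_neutral_communities()` implements Moran-type neutral dynamics
  over a fixed metacommunity; it exists so the NCM fit can be validated by
  parameter recovery rather than by eyeballing $R^2$.
* `simulate_selection_communities()` produces deterministic-assembly data.
  Its default kernel is *lineage-proximity* filtering: habitat affinity is
  perfectly phylogenetically conserved, and a sample retains taxa with
  probability Gaussian in patristic distance to a focal lineage (width set
  directly or calibrated to a target richness). A Brownian-trait kernel
  (`filter = "trait"`, the textbook construction) is also provided, but our
  experiments show it yields only weak phylogenetic clustering at
  desk-scale taxon pools — a Brownian trait band cuts across clades, and
  shared dominant taxa contribute zeros to both observed and null βMNTD —
  so it cannot generate the strong homogeneous-selection regimes the
  classifier is meant to detect; it is retained for neutral-limit checks
  (τ → ∞ recovers neutral weighting).

What the generators deliberately do **not** model: chimeras and other
denoising artefacts, compositional correlation induced by copy-number
variation, overdispersed (non-multinomial) count noise, and genuine
taxonomy (labels are synthetic). Passing tests therefore demonstrate
correctness of the statistical machinery under known structure, not
robustness to every artefact of real amplicon data.

## Problem sizes and runtime

The default test-suite sizes are chosen so the whole suite runs comfortably
on one CPU: enterotype recovery at 100 samples × 500 genera over 20 seeds,
neutral recovery at 50 samples × 300 taxa × 10 seeds per migration rate,
βNTI at 30 samples × 200 taxa with 99 nulls, type-I calibration of PERMANOVA
and RDA at 200 simulations × 99 permutations, and the end-to-end pipeline at
the full 97 × 2000 fixture with 999-null assembly models (the C++ kernels
make this a sub-minute stage). Production analyses on larger tables scale
linearly in nulls and near-quadratically in samples for the pairwise stages.

## Known limitations

* PAM BUILD+SWAP is a local optimiser; the multi-start safeguard applies
  only to small instances, so optimality is only asserted there.
* The LEfSe-style score is a faithful two-class reduction, not a clone; do
  not compare absolute scores against other implementations, only
  threshold behaviour.
* Spearman networks inherit the usual compositionality caveats; no
  SparCC/SPIEC-EASI-style correction is attempted.
* βNTI assumes the tree's branch lengths are meaningful for trait
  conservatism; ultrametric trees are recommended.
* The niche null (within-taxon shuffle) conditions on observed sample
  depths; with perfectly even depths it loses power by construction.
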