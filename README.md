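# enterostrat

Gut microbial communities do not vary along a smooth continuum: they tend to
fall into a small number of recurrent compositional states — *enterotypes*.
Which enterotype an animal carries co-varies with diet, season, habitat and
host condition, and the two states typically differ in diversity, in their
dominant lineages (e.g. the Bacillota/Bacteroidota balance), in how their
member taxa co-occur, and in whether community assembly is governed by
selection or by stochastic drift and dispersal. `enterostrat` implements
this entire analysis as a tested, seeded, reusable R pipeline operating on
ASV count tables, for microbial ecologists who want the full enterotype
workflow — not a pile of one-off scripts — and who want every stage to be
verifiable against synthetic data with known truth.

## What it computes

* **Enterotyping** — genus-level Jensen–Shannon distance
  (`sqrt(H(m) − (H(p)+H(q))/2)`), partitioning around medoids (deterministic
  BUILD+SWAP), optimal cluster number by a distance-based Calinski–Harabasz
  index, silhouettes for corroboration, PCoA ordination.
* **Diversity** — observed/Shannon/Chao1/ACE/Faith PD; Bray–Curtis;
  PERMANOVA and PERMDISP; shared/unique ASV (UpSet) accounting;
  Mann–Whitney/t tests with BH correction.
* **Biomarkers** — LEfSe-style Kruskal–Wallis + LDA effect sizes
  (score > 2.5, p < 0.05), SIMPER decomposition of between-group
  dissimilarity, and a six-family classifier screen (k-NN, random forest,
  naive Bayes, logistic, CART, gradient boosting) with 70/30 split, rank-AUC
  and permutation importance.
* **Networks** — filtered (mean abundance ≥ 0.01%, prevalence ≥ 30%)
  Spearman co-occurrence graphs (|rho| > 0.6, FDR q < 0.05) with node- and
  network-level topology.
* **Assembly** — Sloan's neutral community model
  (`freq = 1 − Beta(1/N; Nmp, Nm(1−p))`), abundance-weighted βMNTD/βNTI
  against a tip-shuffle null, Raup–Crick on Bray–Curtis, and the five-way
  process classification (homogeneous/heterogeneous selection, dispersal
  limitation, homogenising dispersal, drift).
* **Niche breadth** — Levins `B = 1/Σp²` with a permutation null
  classifying taxa into generalists/specialists/neutral.
* **Host-trait association** — Spearman collinearity pre-filter
  (|r| > 0.6) and Hellinger RDA of the community on body-size parameters,
  α diversity and the enterotype label.
* **Synthetic data** — seeded generators for two-enterotype surveys,
  Moran-type neutral communities, and selection-structured communities on a
  phylogeny, so the whole pipeline is testable end to end.

Performance-critical null models (Moran dynamics, βMNTD tip shuffles,
Raup–Crick draws) are implemented in C++ (Rcpp) using R's RNG, so everything
is reproducible from a single seed.

## Worked example

```r
library(enterostrat)

spec <- enterotype_sim_spec(seed = 11)       # 97 samples, 2 latent clusters
d    <- simulate_enterotype_dataset(spec)
tree <- simulate_yule_tree(ncol(d$counts), seed = 12, ultrametric = TRUE,
                           tip_labels = colnames(d$counts))

cfg    <- pipeline_config(d$counts, d$taxonomy, d$metadata, tree, seed = 42)
report <- run_pipeline(cfg, outdir = "results")
print(report)
```

```
Pipeline report: 97 samples, 2000 taxa
  enterotypes: k = 2 ; sizes 63/34 
  E1: NCM m = 0.002 (R2 = 0.82); homogeneous selection 2.2%, drift 0.0%
  E2: NCM m = 0.001 (R2 = 0.74); homogeneous selection 0.9%, drift 0.0%
```

The run recovers the two planted enterotypes at their 63/34 sizes (the
chosen `k` maximises the CH index). The neutral-model fit explains 82%/74%
of the occurrence–abundance relationship within each enterotype with small
immigration estimates; the process partition for this particular generator
is dominated by dispersal limitation (Dirichlet sampling produces more
compositional turnover than the richness-constrained null expects), which is
a property of the fixture, not of the method. `results/report.json` holds
the full machine-readable report — α/β diversity tests, biomarker tables,
network topology, NCM parameters, process fractions, niche fractions and
the RDA — and is byte-identical across repeat runs with the same seed.

Individual stages are plain functions on matrices and work standalone, e.g.

```r
e  <- select_enterotypes(d$counts, d$taxonomy, k_range = 2:6)
bn <- beta_nti(filter_taxa(d$counts, 1e-4, 0), tree, n_null = 999, seed = 1)
```

## Layout

```
R/                core modules: io, synthetic data, enterotyping, diversity,
                  differential, network, assembly, niche, association, pipeline
src/kernels.cpp   Moran / betaMNTD-null / Raup-Crick C++ kernels
tests/testthat/   unit, property and acceptance suites
vignettes/        methods vignette (models, parameters, design decisions)
scripts/          acceptance.R
```
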