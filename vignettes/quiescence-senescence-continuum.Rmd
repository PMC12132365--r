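---
title: "Senotyping and the quiescence-senescence continuum: methods"
author: "senotyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Senotyping and the quiescence-senescence continuum: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

After a pulse of a DNA-damaging chemotherapy such as etoposide, a
population of epithelial cells fractures into fates that are hard to
tell apart molecularly: cells that keep cycling, cells that withdraw
reversibly (quiescence, G0), and cells that withdraw irreversibly
(senescence). `senotyper` implements a complete analysis of this system
from two kinds of data:

* **single-cell RNA-seq count matrices** across a dose series
  (untreated, 2.5, 10, 25 µM), analysed through QC, normalization,
  clustering, differential expression, enrichment, per-cell gene-module
  scoring, and pseudotime; and
* **live-cell reporter traces**: a CDK2 activity sensor whose
  cumulative time below an activity of 0.8 defines ground-truth
  cell-cycle withdrawal, a protein-stabilization reporter whose
  post-induction accumulation slope measures protein biosynthesis, and
  a DNA-content readout that flags mitotic-slip cells by their 4N
  genomes.

The scientific claims the pipeline operationalizes are that (i)
chemotherapy-induced arrest is a *continuum* - senescence-associated
expression programs rise gradually with depth of withdrawal rather than
switching on; (ii) there are at least two *paths* into senescence, a
dominant mitosis-to-G0 path and a rarer mitotic-slip path with 4N DNA
content and elevated SASP; and (iii) within one treated population there
are several transcriptomically distinct *senotypes*.

# Pipeline model and parameters

The analysis stages mirror standard single-cell practice; each is an
exported function so every step is testable in isolation.

**QC** (`qc_filter`). Cells with fewer than 3,500 detected genes or more
than 15% mitochondrial counts (gene names matching `^MT-`,
case-insensitive) are removed - strict inequalities on both sides, so a
cell at exactly 3,500 genes or exactly 15% is retained. Optional total-UMI
bounds exist but are disabled by default because no defensible universal
threshold exists. The first failing rule is recorded per removed cell.

**Normalization** (`log_normalize`). \(x_{gc} = \ln(1 + s\,c_{gc}/T_c)\)
with scale factor \(s = 10{,}000\); by construction
\(\sum_g e^{x_{gc}}-1 = s\) for every cell, which the tests assert to
\(10^{-6}\) relative tolerance.

**HVGs and PCA** (`select_hvg`, `scale_and_pca`). Genes are ranked by
standardized variance after a loess mean-variance trend on raw counts
(log10-log10 scale, degree 2), with standardized values clipped at
\(\sqrt{n}\); ties break lexicographically so selection is
deterministic. Selected genes are z-scored across cells, clipped at
±10 (a conventional guard against single-cell outliers), and the top 30
principal components are taken. Component signs are fixed so the
largest-magnitude loading is positive, making the decomposition
reproducible to the bit.

**Module scores** (`module_score`). A set's score in a cell is the mean
log-normalized expression of the set genes minus the mean over pooled
control genes, drawn per set gene (seeded, without replacement, 100 per
gene by default) from the same average-expression bin (24
equal-frequency bins). Controls never include the scored set itself;
`assign_phase` additionally excludes *both* phase lists from both
control pools, because S and G2/M genes share bins and would otherwise
contaminate each other's baseline.

**Phase calls** (`assign_phase`). S if the S score beats the G2/M score
and zero; G2/M if its score is at least the S score and positive;
everything else is G0/G1 - which therefore mixes cycling G1 cells with
all arrested cells, exactly the ambiguity the trajectory analysis
exploits.

**Clustering** (`cluster_snn`). Exact k-nearest neighbours (k = 20,
self included) in PC space, shared-nearest-neighbour weights as the
Jaccard overlap of neighbour sets pruned below 1/15, and Leiden
modularity optimization at resolution 0.8. Leiden was chosen over
Louvain for deterministic convergence at a fixed seed. Cluster ids are
relabeled by decreasing size. Arrested (G0/G1-majority) clusters whose
top-dose occupancy is at least 1.5x the population share are called
senescent-like (several can qualify - the senotypes); among the rest the
lowest-occupancy one is quiescent-like and the remainder transition.

**Differential expression** (`wilcoxon_dge`, `rank_sum_p`). Two-sided
Wilcoxon rank-sum tests on log-normalized expression. The p-value is
exact - even under ties - for combined group sizes up to 50, via a
dynamic program over the permutation distribution of the rank sum on
doubled midranks; larger groups use the normal approximation with tie
and continuity correction (verified against `wilcox.test` and, for
small samples, against exhaustive enumeration). Fold changes are
\(\log_2[(\mathrm{mean}_A(e^x-1)+1)/(\mathrm{mean}_B(e^x-1)+1)]\); the
pseudocount of 1 on the de-logged scale is stated prominently because it
materially affects small-expression fold changes. Both Bonferroni
(m = genes tested) and Benjamini-Hochberg adjustments are reported:
Bonferroni is the DGE correction, while the ranking score
\(\mathrm{avg\_log2FC} \times -\log_{10}(\mathrm{adj.\ p})\) uses the
BH-adjusted p by default (configurable), with the adjusted p floored at
\(10^{-300}\) so saturated significance stays finite. Pre-filters
(expressing fraction ≥ 0.1 in either group, |log2FC| ≥ 0.25) follow
ecosystem defaults and are set to ~0 in the synthetic study so the
ranked universe spans all genes.

**Enrichment** (`gsea_preranked`). A native preranked GSEA: hits
increment the running sum by \(|s|^p\) normalized over the set
(p = 1 by default), misses decrement by \(1/(N-N_{hit})\); the ES is
the maximum-magnitude deviation (earliest extremum on numerical ties).
Significance comes from a seeded gene-label permutation null (1,000
random same-size sets, shared across sets of equal size), one-sided
toward the observed sign; NES divides the ES by the mean |permuted ES|
of the same sign, a convention chosen for sign stability. The leading
edge is the set genes at or before the extremum (at or after, for
negative ES). Set-size bounds default to [10, 500]. A set covering the
whole universe has no misses; its ES is defined as 0 with a warning.

**Trajectory** (`learn_trajectory`). The principal graph is the
Euclidean minimum spanning tree over the cluster centroids of the
G0/G1-labelled, drug-treated subset in PC space; cells project onto the
nearest point of any tree edge and pseudotime is geodesic distance from
the root projection. The root is the centroid nearest the mean position
of the proliferating (S/G2M) cells. This is a deliberate simplification
of learned-principal-graph methods: what downstream analyses consume is
the *ordering* and the *branch structure*, both of which the MST
recovers on this geometry, and the construction is deterministic with
no tuning. The branch point is the node with degree > 2 nearest the
root; cells projecting beyond it split by subtree. Which subtree is
"trajectory 2" is decided by an observable marker when one is supplied -
mean DNA content, since the slip limb is 4N - and by size otherwise
(the slip path is the rarer one). Cells before the branch point are
`shared` and belong to both branch-wise fits.

**Score gradients** (`loess_fit`, `rescale_unit`,
`pathway_heatmap_matrix`). Per pathway group: module score, Loess fit
against pseudotime per branch (span 0.3, degree 1, 100-point grid;
backed by `stats::loess` with `surface = "direct"`, which at span 1
equals a global tricube-weighted least-squares fit - the tests verify
this against an independent solver), then 0-1 rescaling per row for a
shared colour scale. Constant rows rescale to all zeros with a
degeneracy flag, and the un-rescaled fits are kept as an attribute so
branch peak heights remain comparable.

**Derived gene sets** (`shared_sasp_genes`,
`derive_senescence_signature`). The shared SASP set takes, per
senescent cluster, the top 50 (by ranking score - the pipeline's own
prioritization metric) of the pooled SASP leading-edge list, and
intersects across clusters; cluster-specific and branch-specific SASP
genes fall out because they rank low (or negative) in the clusters that
lack them. The senescence signature unions the top 100 genes of the
pooled senescent-vs-rest DGE with the top 50 of the weakly-identified
senescent cluster (operationalized as the senescent cluster with the
fewest Bonferroni-significant up-genes), then removes genes "elevated in
untreated G0/G1 cells". That phrase needed a concrete rule: a gene is
removed when its mean normalized expression in untreated G0/G1 cells
exceeds 0.5x its mean in pooled senescent cells, computed on the
de-logged (`expm1`) scale - the same scale as the fold change - because
log-scale means compress ratios and would discard genuinely graded
markers. Every removal is recorded with both means in an audit trace.

**Live-cell analysis** (`cdk2_low_duration`, `classify_cycle`,
`entry_fraction_curve`, `reporter_slope`, `dna_saddle_split`).
Cumulative CDK2-low time is the count of frames strictly below the 0.8
activity threshold times the frame interval (12 min), with tracking
gaps masked out of both numerator and movie length, never imputed.
Category cutoffs are not printed anywhere authoritative, so the
defaults are explicit and reported with the output: fast-cycling at
≤ 12 h cumulative low time over a 96 h movie, predicted-senescent at
≥ 95% of the movie, slow-cycling between. Reporter traces are
normalized to their pre-induction mean and an OLS line over a
user-chosen post-induction window gives the accumulation slope
(normalized units/hour); the window is a required argument because it
is an experimental design choice. DNA content is split at the density
minimum between the two highest KDE modes (Gaussian kernel, Silverman
bandwidth); unimodal input is flagged rather than split.

# What the synthetic data emulate

`simulate_counts` plants the full study structure with ground truth:

* **Latent arrest depth** \(d \in [0,1]\) per cell; \(d < 0.15\) means
  actively cycling (the generator, not the analyst, fixes this cutoff).
  Per-dose cycling probabilities (0.85, 0.45, 0.25, 0.05) and Beta
  depth distributions shift deeper with dose, matching the dose series'
  role of titrating the senescent fraction.
* **Two branches**: arrested cells take the mitotic-slip path with
  dose-dependent probability (0, 0.05, 0.15, 0.25 - the slip path is
  rare and concentrated at high dose); slip cells arrest directly and
  deeply, carry a ~4N DNA-content proxy, and express a 20-gene
  branch-specific SASP program.
* **Three senotypes** of 60 genes each with depth-activation ranges:
  the two mitosis-to-G0 senotypes tile the deep continuum (activation
  splitting at depth 0.8) so they chain along the arrest axis, and the
  slip senotype rides the slip branch.
* **Graded programs**: 40 p21-like pan-senescence markers with effect
  proportional to depth; 30 universal SASP genes ramping on from depth
  0.3 and saturating by 0.8 (interferon-class SASP genes are strongly
  induced in every deeply arrested cell); a 60-gene biosynthesis program
  declining linearly with depth; graded repression of the 80 cell-cycle
  genes in arrested cells (cell-cycle genes are the canonical
  down-program of arrest). Phase genes peak in their own phase and are
  strongly repressed (~7-fold) outside it, mirroring cyclin-like
  dynamics in droplet data.
* **A weak quiescence-only module** (25 genes, ~2.2-fold, active at
  depths 0.15-0.5): shallow-arrest cells carry no strong unique
  program - their defining feature is attenuated senescence changes -
  but the faint module exercises the signature's background-removal
  rule.
* **Counts**: negative binomial with gene-specific dispersion
  (log-uniform on [0.1, 1]), log-normal library sizes (sdlog 0.3,
  ~5,000 counts/cell over 1,500 genes), 13 `MT-` genes at ~5%
  mitochondrial share, plus planted QC foils: ~3% of cells with 6x
  mitochondrial load and ~2% with collapsed (5%) libraries.

The default scale is 500 cells per dose x 1,500 genes - small enough
that the full pipeline runs in about a minute, large enough that every
recovery statistic is stable across seeds.

What the generator does **not** emulate - and hence what passing tests
do not show about real data: ambient RNA, doublets, batch effects,
zero-inflation beyond NB sampling, gene-gene correlation within
programs beyond shared activation, realistic transcriptome-wide
mean-variance structure, or any mechanistic kinetics of damage
signalling. Recovery statistics here certify that the *algorithms*
recover *planted* structure, not that the biological conclusions
transfer.

`simulate_traces` builds CDK2 activity traces (96 h at 12-min frames):
fast cyclers rise and reset every ~16 h spending ~1.4 h per cycle below
threshold; slow cyclers interleave 15-30 h sub-threshold plateaus with
cycles; senescent cells stay at 0.3 throughout. `simulate_reporter_traces`
holds a per-cell baseline before induction and rises linearly after it,
so a zero-noise trace returns its generating slope exactly.

# Numerical choices and degenerate inputs

* Exact Wilcoxon p-values use doubled midranks so tied data stay on an
  integer lattice; two-sided p is `min(1, 2 min(P≤, P≥))`.
* The ES extremum takes the earliest position among numerically tied
  deviations (tolerance 1e-12) so implementation and oracle agree
  deterministically.
* All seeded stages save and restore the caller's RNG state, so
  pipeline results never depend on call order.
* Zero-variance HVGs are excluded from scaling with a warning; a
  constant score vector rescales to zeros with a `degenerate` flag; a
  whole-universe gene set gets ES 0 with a warning; unimodal DNA
  content refuses to split.
* QC that removes every cell, empty trace sets, negative reporter
  slopes, overlapping DGE groups and sub-3-frame fit windows are
  errors, not silent results.

# Known limitations

* The MST-over-centroids trajectory can, in principle, mis-order
  clusters if a hub geometry forms; with the study's planted effect
  sizes the ordering is stable across seeds, but pathological cluster
  geometries would need a learned principal graph.
* The senescent/weak-cluster identification rules are heuristics
  standing in for the paper-style manual inspection of cluster
  composition; both are overridable by explicit arguments.
* Exact Wilcoxon enumeration is limited to combined n ≤ 50; beyond
  that the normal approximation is used (with tie/continuity
  correction), which is standard but approximate.
* The 2-D embedding is for visualization only; no downstream statistic
  reads it.
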