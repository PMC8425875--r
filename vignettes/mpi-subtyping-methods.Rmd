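---
title: "Methods: MPI networks, subtype discovery, and metabolite accumulation scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MPI networks, subtype discovery, and metabolite accumulation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpinet)
```

# The model

`mpinet` analyzes tumor cohorts through the lens of a directed bipartite
**metabolite-protein interaction (MPI) network**: nodes are metabolites and
proteins, and an edge states that a metabolite is a *substrate* (consumed by
the protein's reaction), a *product* (produced by it), or *both* when the
interaction is reversible. Such networks are assembled upstream from reaction
databases; this package consumes pre-extracted edge lists (TSV) and handles
integration, deduplication and direction merging. When two sources disagree
on direction, the pair is marked reversible — direction is then
indeterminate, and in the accumulation score below a reversible partner
cancels exactly, which is the conservative choice.

Three filters define the working network:

* **Common metabolites** (water, protons, ADP, ...) with more than 200
  distinct protein partners are removed — the threshold is a strict `>`.
* Proteins left without any partner are pruned.
* **Core MIPros** (metabolite-interacting proteins) are those retaining more
  than 4 partners (again strict). Their expression carries the metabolic
  signal used for subtyping.

# Subtype discovery

Tumor samples are projected onto the first two principal components of the
z-scored core-MIPro expression matrix, then consensus-clustered:
partitioning around medoids (PAM, Euclidean) on repeated 80% subsamples
(default 1000 repetitions), aggregated into a co-clustering frequency
matrix, with final labels from an average-linkage cut of one minus that
matrix at K = 2. These defaults mirror the ConsensusClusterPlus conventions
the original analysis relied on; K is a configuration value, not selected
automatically, and consensus matrices for a K scan are exposed for
inspection.

Raw principal-component signs are arbitrary, so a "PC1 < PC2" rule is not
portable across runs or cohorts. Labels are therefore oriented by **marker
genes**: the cluster with *lower* mean marker expression is called C1, the
poor-prognosis, metabolically down-regulated subtype. The PC1 − PC2
discriminant is reported as a consistency diagnostic (`discriminant_agreement`);
on well-separated cohorts it approaches 1, echoing the observation that the
two subtypes sit on either side of the PC1 = PC2 line.

Subtype-relevant genes are ranked by random-forest importance (mean Gini
impurity decrease). Because no random-forest package is available in the
target environment, the package ships its own compact, seeded implementation
(`rforest`, C++): bootstrap resampling, `sqrt(p)` feature subsampling per
node, probability averaging over leaves. Determinism under a fixed seed is a
tested contract. The top-30 genes feed **GL1**, an elastic-net logistic
classifier (glmnet; mixing parameter 0.5 by default, penalty chosen by
seeded cross-validation). GL1 stores its normalization recipe — targets are
row z-scored at prediction time — so it transfers across cohorts on the
relative-expression scale. **GL2** splits predicted-C1 samples into S1/S2
(trained on TME-derived sub-populations); `two_step_predict()` composes the
two so every sample receives exactly one of C2/S1/S2.

# The deltaM accumulation score

For each metabolite, its producers (**UpPs**, edges pointing to the
metabolite) and consumers (**DownPs**, edges leaving it) are read off the
directed network, and

$$\Delta M \;=\; \sum_{p \in \mathrm{UpPs}} \mathrm{log_2FC}(p)
  \;-\; \sum_{p \in \mathrm{DownPs}} \mathrm{log_2FC}(p)$$

with fold changes taken between the poor- and well-prognosis subtypes
(C1 vs C2). A positive score means C1 up-regulates producers relative to
consumers — the metabolite tends to *accumulate* in C1. Reversible partners
appear in both sums and cancel. Numerical choices: proteins without
expression are skipped (not imputed; `n_missing` reports them so sparse
metabolites can be filtered), summation runs in sorted-protein-id order for
bitwise reproducibility, no capping of extreme fold changes is applied, and
metabolites with fewer than 2 measured partner slots are flagged
`low_confidence` — a one-protein deltaM is just that protein's fold change.
Note that one reversible partner occupies two slots, so a metabolite whose
only partner is reversible is *not* flagged; its score is exactly 0 by
cancellation.

Metabolite sets (e.g. pathway compound lists) are then tested by GSEA on the
deltaM ranking; positive NES reads as pathway-level accumulation, negative
as consumption.

# Enrichment statistics

`gsea_es()` implements the weighted Kolmogorov–Smirnov running sum: hits
increment by $|s|^{w}$ (normalized over hits, default $w = 1$), misses
decrement by $1/(N - N_h)$; the enrichment score is the extremum of maximum
absolute deviation. On exactly symmetric profiles the positive and negative
extrema tie; the convention is to return the positive one, which makes the
statistic deterministic across floating-point accumulation orders.

The permutation null uses **set-size-matched random sets** rather than
phenotype permutation: the rankings this package tests (per-metabolite
deltaM, per-gene log2FC) carry no sample-level phenotype to permute. NES is
ES divided by the mean absolute null ES of matching sign; p is the empirical
matching-sign tail (floored at $1/(B+1)$); FDR follows the standard
NES-based procedure over the pooled normalized null.

Per-sample scoring (`sample_set_score`, used for the **ImmuP** immune score)
is an ssGSEA-style rank statistic — the cited methodology is a
gene-set-variation-analysis score, but kernel ECDF estimation is out of
scope, and the rank statistic preserves the two properties the analysis
uses: invariance to monotone within-sample transforms and monotonicity in
the set genes' expression. The ImmuP gene list itself is the intersection of
immune-pathway members with genes up-regulated in C1 at BH-FDR < 0.01 and
*linear* fold change > 1.5 (i.e. log2FC > log2 1.5).

# MPI link prediction

Candidate metabolite-protein pairs are described by six network-topology
features, computed with the candidate edge itself removed from the graph
(leakage control, a tested invariant): preferential attachment, the number
of length-3 paths, two cross-neighborhood Jaccard indices, inverse shortest
path length, and a resource-allocation index over length-3 paths. The
original work defines its six features only in an unavailable supplement;
this set is the package's own realization, kept behind a named-feature
interface so alternatives can be swapped in. Negative pairs are sampled
uniformly from non-edges at a 1:1 ratio (configurable). A seeded random
forest is trained under 5-fold stratified cross-validation; the reported
ROC/AUROC uses out-of-fold probabilities only, and high-confidence calls
require predicted probability strictly above 0.9. The threshold argument
accepts (0, 1]: a threshold of exactly 1 is legal and yields an empty call
set rather than an error.

# What the synthetic world does and does not establish

The generators (`synth_config()` and friends) produce every input with known
ground truth:

* **Network**: heavy-tailed metabolite degrees (log-normal), optional hubs
  above the 200-degree filter, protein partners drawn with log-normal
  weights. Defaults: 300 metabolites, 400 proteins, mean degree 6.
* **Cohort**: genes are standard normal on the z-score scale (the pipeline
  z-scores anyway, so an FPKM-level noise model would add nothing testable);
  50 informative genes drawn from the core MIPros receive a ±1 SD shift in
  C1 (half down — the down-shifted half doubles as the marker set).
  Survival is exponential with hazard ratio 3 for C1 and independent
  exponential censoring calibrated by root-finding to a 30% target.
  Structural choices (which genes carry signal) depend only on `seed`;
  `cohort_seed` varies the sampling noise so independent cohorts share one
  generative process — this is what the classifier-transfer property tests.
* **Accumulation scenario**: a pathway of metabolites is planted by setting
  their producer fold changes to +a and consumer fold changes to −b,
  greedily skipping metabolites that would assign conflicting values to a
  shared protein. Each planted deltaM is then *exactly*
  a·|up-only| + b·|down-only| (reversible partners cancel by construction,
  which is why the formula counts only directed partners); the target is
  the planted metabolite with the strictly largest truth score.
* **Link instance**: a planted block model with per-node log-normal
  activity. The activity term matters: with perfectly homogeneous degrees,
  preferential attachment carries no signal and the "true edges score
  higher on every feature" property cannot hold; heavy-tailed activity is
  also what real MPI networks show.

A green test on this world establishes that the statistics recover planted
structure at the stated effect sizes and that every deterministic
computation matches an independent oracle. It does not establish cohort
realism: no batch effects, no count noise, no correlated gene modules, no
informative censoring. The headline numbers of the motivating study (a
31,236-edge network, AUROC 0.97) depend on versioned external databases and
patient cohorts and are deliberately out of scope; the corresponding
properties are asserted at desk scale instead (e.g. AUROC ≥ 0.80 on the
planted blocks).

# Degenerate inputs and tie-breaks

* Wilcoxon tests switch from the exact distribution to the normal
  approximation with continuity correction at n > 25 or in the presence of
  ties; all-zero paired differences give p = 1.
* Cox screening uses Efron tie handling; genes with constant expression or
  non-converging fits are flagged, never fatal. Expression enters as a
  z-score (sign and p are unaffected by the scale; the coefficient is per
  SD).
* log2 fold change is the difference of group means of log2 values
  (mean-of-logs); inputs declared linear get a +1 pseudocount upstream.
* Ranking ties break by (score descending, id ascending) everywhere.
* Community detection (greedy modularity, igraph) inserts vertices in
  lexicographic order and never returns a partition with lower modularity
  than the connected-component partition (the greedy merge can otherwise
  leave a clique split at negative modularity).
* `consensus_cluster` requires the subsample to be at least as large as K
  and at least 50 repetitions.

# Known limitations

* GSVA-kernel per-sample scoring, phenotype-permutation GSEA, multivariate
  or penalized Cox models, stoichiometric/flux modelling, and any parsing of
  primary reaction databases are out of scope by design.
* The six link-prediction features are this package's realization, not the
  original study's (whose definitions are unavailable); conclusions about
  feature identity do not transfer.
* Consensus clustering and random-forest runtimes scale with `reps` and
  `n_trees`; the tests run with both scaled down (documented inline) — the
  defaults remain the stated analysis conditions.
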