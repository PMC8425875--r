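# mpinet

Metabolite-protein interaction (MPI) networks for tumor subtyping and
metabolite-accumulation scoring.

## The problem

Tumors rewire metabolism, but metabolite levels are rarely measured at
cohort scale. `mpinet` works around that by exploiting the *directed*
structure of metabolite-protein interactions: every metabolite is connected
to the proteins that produce it (its **UpPs**) and the proteins that consume
it (its **DownPs**). Given only transcriptomics, the package

1. **builds and filters** a directed bipartite MPI network from edge lists
   (integration across sources, removal of common metabolites with degree
   > 200, core metabolite-interacting proteins = degree > 4, both strict);
2. **discovers two prognosis-linked subtypes** (C1 poor, C2 well) by PCA of
   core-MIPro expression followed by consensus clustering (PAM over
   subsamples, K = 2), oriented by marker genes, and makes them
   **transferable** with an elastic-net classifier (GL1) on the top-30
   random-forest-ranked subtype-relevant genes; a second classifier (GL2)
   refines predicted-C1 samples into S1/S2 sub-populations;
3. **scores metabolite accumulation** with the network statistic

   deltaM = Σ log2FC(UpPs) − Σ log2FC(DownPs),

   where fold changes are C1 vs C2: positive deltaM means the
   poor-prognosis subtype tends to accumulate the metabolite. Metabolite
   sets are then tested by GSEA (weighted Kolmogorov–Smirnov running sum,
   set-permutation null) on the deltaM ranking;
4. **scores immune activity per sample** (ImmuP, ssGSEA-style) from immune
   genes up-regulated in C1 (FDR < 0.01, linear FC > 1.5);
5. **predicts novel MPIs** with a random forest over six network-topology
   features computed with the candidate edge excluded, reporting
   cross-validated AUROC and calls at probability > 0.9;
6. ships a fully **seeded synthetic-data generator** with exact ground
   truth for every stage, and an end-to-end pipeline
   (`run_full_pipeline()`) whose outputs are byte-reproducible.

It is aimed at computational biologists who have expression cohorts plus a
pre-extracted interaction edge list and want the full subtype → mechanism →
prediction workflow without any database downloads.

## Worked example (synthetic world)

```r
library(mpinet)

cfg <- synth_config(seed = 11, n_metabolites = 150, n_proteins = 250,
                    hub_fraction = 0.02, hub_degree = 220,
                    n_genes = 800, n_samples = 150, effect_size = 1.5)
gn  <- gen_mpi_network(cfg)
net <- prune_isolated_proteins(remove_common_metabolites(gn$network))
net
#> mpi_network: 855 unique MPIs covering 147 metabolites and 200 proteins
length(core_mipros(net))
#> [1] 62
```

Three hub metabolites (degree 220 > 200) and the proteins they orphaned are
gone; 62 proteins keep more than 4 partners and become the subtyping
features.

```r
co    <- gen_cohort(cfg, gn$network)
model <- fit_subtype_model(co$cohort, net, co$truth$markers,
                           reps = 200, seed = 1)
model
#> subtype_model: 150 samples; C1=66, C2=84 ; discriminant agreement 1
table(model = model$labels, truth = co$truth$labels[names(model$labels)])
#>      truth
#> model C1 C2
#>    C1 66  0
#>    C2  0 84
logrank_test(co$cohort, model$labels)$p
#> [1] 2.86e-08
```

Recovery of the planted subtypes is perfect at 1.5 SD effect size, every
sample falls on the correct side of the PC1 = PC2 line (agreement 1), and
the planted hazard ratio of 3 shows up in the log-rank test.

```r
acc <- gen_accumulation_scenario(cfg, gn$network)
tab <- delta_m(net, acc$log2fc)
head(accumulation_report(tab, top_k = 3), 3)
#>   metabolite_id deltaM   direction
#> 1         M0106      7 accumulated
#> 2         M0051      6 accumulated
#> 3         M0103      6 accumulated

res <- metabolite_gsea(tab, acc$sets, n_permutations = 1000, seed = 1)
head(res[, c("set", "size", "es", "nes", "p")], 2)
#>               set size        es      nes           p
#> 1 planted_pathway    9 0.9492754 2.112376 0.000999001
#> 2   background_08   10 0.6117769 1.455772 0.076142132
```

The planted target (its 4 producers set to +1, 3 consumers to −1, so its
true deltaM is exactly 7) tops the table, and the planted pathway is the
only significant set (p at the 1/(B+1) permutation floor; backgrounds stay
null).

## Command line

```sh
Rscript -e 'mpinet::mpinet_cli()' simulate  --seed 4 --out world/
Rscript -e 'mpinet::mpinet_cli()' build-net --edges kegg.tsv,brenda.tsv --out net.tsv
Rscript -e 'mpinet::mpinet_cli()' deltam    --net net.tsv --fc fc.tsv --sets compounds.gmt --out dm.tsv
Rscript -e 'mpinet::mpinet_cli()' run-all   --seed 7 --out run/
```

(An installable wrapper lives in `inst/exec/mpinet`.)

## Documentation

The methods vignette (`vignettes/mpi-subtyping-methods.Rmd`) describes the
model, every tunable with its default and rationale, what the synthetic
world does and does not establish, numerical conventions, and known
limitations.
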