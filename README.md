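# coexmod

Co-expression gene module detection for single-cell RNA-seq and spatial
transcriptomics count matrices.

Instead of selecting "highly variable" genes one at a time, `coexmod`
treats each gene as a point in cell space and looks for dense
neighborhoods of genes — groups with mutually similar expression profiles
across cells or spots. The output unit is the co-expression module: a set
of genes behaving as one transcriptional program. It is aimed at anyone
analyzing 10x-style count matrices who wants modules (programs, markers of
states or rare populations, spatially variable signatures) rather than a
flat list of variable genes.

## The algorithm

1. **DKNN selection.** From a gene–gene distance matrix (Pearson distance
   `d = 1 − r` by default) each gene is scored by the distance to its
   *K*-th nearest neighbor gene (DKNN). A permutation null — a probe
   gene's expression vector is shuffled across cells and its distances
   recomputed — gives the DKNN distribution with no co-regulation, and an
   empirical FDR
   `FDR(t) = F0(t)·n / #{DKNN ≤ t}` (capped at 1) sets the selection
   threshold at a chosen target (default `1e-4`).
2. **Neighborhood graph** over the selected genes: union of each gene's
   *S* nearest relations (`closest_neighborhood`, S < K) or mutual
   *K*-nearest neighbors (`reciprocal_neighborhood`).
3. **Markov clustering (MCL)**, implemented from scratch: alternating
   expansion (matrix power) and inflation (entrywise power `r` with column
   renormalization) on the column-stochastic flow matrix; modules are the
   attractor supports. Inflation is the resolution knob (1.2 for the
   benchmark design; 1.8–2.2 on sparse real data).
4. **Filters and scores:** module size, supporting cells (cells expressing
   a minimum fraction of the module), expression standard deviation; plus
   a rank-based per-cell module activity score in `[0, 1]` (AUCell-style
   recovery curve).

A Gamma–Poisson simulator with planted DE modules
(`simulate_dataset()` / `simulate_grid()`) and benchmark metrics (AUROC,
F1, median top-Jaccard module recovery) make the whole pipeline testable
end to end.

## Worked example

```r
library(coexmod)

design <- simulation_design(n_genes = 1200, n_cells = 400,
                            de_module_sizes = c(120, 80, 50), fc_max = 80,
                            seed = 1)
sim <- simulate_dataset(design)
sim$matrix
#> ExpressionMatrix: 1200 genes x 400 cells [layer: raw_counts, sparse]
sim$truth
#> SyntheticTruth: 400 cells in 5 clusters; 250 DE genes in 3 modules

ln  <- lognormalize(sim$matrix)
sel <- select_genes(ln, selection_params(k_neighbors = 15,
                                         fdr_target = 1e-3, seed = 1))
sel
#> DknnResult: 1195 genes scored, 1048 selected (threshold 0.8300, FDR 0.000953)

ms <- partition_genes(ln, sel,
                      graph_params(method = "closest_neighborhood",
                                   s_closest = 5, k_neighbors = 15),
                      mcl_params(inflation = 1.5))
ms <- filter_cluster_size(ms, 10)
ms <- filter_nb_supporting_cells(ms, sim$matrix, min_cells = 5, min_frac = 0.2)
ms
#> ModuleSet: 6 modules, 1034 genes
#>   sizes: M01=732 M02=117 M03=80 M04=49 M05=45 M06=11

jac <- jaccard_module_recovery(truth_modules(sim$truth), ms)
round(jac$top_jaccard, 3)
#> [1] 0.975 1.000 0.980
auroc(-sel$observed_dknn,
      sel$gene_ids %in% names(sim$truth$de_gene_module))
#> [1] 0.957
```

The three planted modules are recovered almost exactly (top Jaccard 0.975,
1.000, 0.980: M02–M04 match the 120-, 80- and 50-gene truth modules), and
ranking genes by negated DKNN separates planted from noise genes with
AUROC 0.957. The large M01 is the complementary background program: with
library sizes fixed, up-regulating the planted modules compresses every
other gene's share in the target clusters, so the remaining genes
genuinely co-vary — the method reports it as one module, and the
supporting-cells/size filters or a higher inflation can be used to
dissect or drop it. Module activity per cell comes from
`module_activity_scores(ms, ln)`; export with `write_modules_gmt()` or
`write_modules_tsv()`.

A thin command-line wrapper covers the same pipeline:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "coexmod.R", package = "coexmod"))') \
    run --simulate --seed 1 --out out/
```

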