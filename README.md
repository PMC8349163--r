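# baitclust

Candidate pathway gene prioritization by bait-enriched network clustering.

## The problem

Many biosynthetic pathways — the glucosinolate (GSL) pathway of
*Arabidopsis thaliana* being the motivating case — have a core of
experimentally verified ("bait" or "known") genes plus an unknown number of
missing members that sequence similarity cannot find. Guilt-by-association
on a gene co-expression network can: genes that sit in the same densely
interconnected network neighborhood as many baits are strong pathway
candidates. `baitclust` implements that idea as a reusable, tested pipeline
for anyone with (a) one or more co-expression edge lists and (b) a bait gene
list.

## The method

1. **Merge** the per-source edge lists (two-column TSV or SIF) into one
   undirected, unweighted network by set union of canonical edges.
2. **Cluster** the network with an overlapping density-based algorithm
   (DPClusO-style). A cluster *k* has density
   *d<sub>k</sub>* = |E<sub>k</sub>| / (|N<sub>k</sub>|(|N<sub>k</sub>|−1)/2),
   and an outside node *n* has cluster property
   *cp<sub>nk</sub>* = |E<sub>nk</sub>| / (*d<sub>k</sub>* · |N<sub>k</sub>|).
   Clusters are grown greedily from high-degree seeds and a candidate node
   joins only while the enlarged density stays ≥ *d*<sub>min</sub> and
   *cp<sub>nk</sub>* ≥ *cp*<sub>min</sub> (default 0.5). Clusters may
   overlap.
3. **Enrich**: each cluster is scored for bait enrichment with a one-sided
   Fisher's exact test on the 2×2 table (baits in/out of cluster ×
   genes in/out of cluster), with the network — not the genome — as the
   universe.
4. **Score**: every gene receives SScore = −log₁₀(min *p* over the clusters
   containing it); unclustered genes score 0.
5. **Select the density**: the SScore threshold sweep yields a ROC curve
   (baits as positives) per density in {0.5, 0.6, 0.7, 0.8, 0.9}; the
   density with the highest AUC wins (ties to the larger density).
6. **Extract candidates**: non-bait members of the significant clusters
   (raw *p* < 0.05) at the selected density, ranked by SScore.
7. Optionally, **pathway over-representation** of the candidates against a
   GMT file (upper-tail hypergeometric, Bonferroni), with Cohen's-kappa
   (≥ 0.5) grouping of significant pathways.

A planted-module synthetic generator (stochastic-block construction with
near-clique, bait-rich modules in a sparse background) makes every stage
testable end to end, including label-holdout recovery experiments.

## Worked example

```r
library(baitclust)

# a synthetic benchmark with 4 planted bait-rich modules
ds <- generate_synthetic(synthetic_spec(seed = 42))
ds
#> synthetic_dataset: 369 nodes, 3284 edges, 145 known (0.39), 15 planted candidates

scan <- scan_densities(ds$network, ds$known)
scan
#> density_scan:
#>   d_min 0.50: 218 clusters, AUC 0.6251
#>   d_min 0.60: 218 clusters, AUC 0.6653
#>   d_min 0.70: 218 clusters, AUC 0.8856
#>   d_min 0.80: 218 clusters, AUC 0.8856
#>   d_min 0.90: 225 clusters, AUC 0.9592  <- selected
```

The scan clusters the network at each density, tests every cluster for bait
enrichment, scores genes, and reports the ROC AUC of the SScore for
separating baits from non-baits; here density 0.9 separates best and is
selected. Candidates then come from the significant clusters at that
density:

```r
best <- scan$per_density[[5]]
rep <- candidate_report(best$enriched, ds$known, best$scores)
rep
#> candidate_report: 11 significant clusters (p < 0.05), 15 candidate genes
#>   top 6 clusters yield 8 candidates
head(rep$candidates, 3)
#>    gene   sscore best_cluster_id n_significant_clusters
#> 1 g0122 12.47680               3                      4
#> 2 g0148 12.47680               3                      4
#> 3 g0011 12.14871               1                      3
```

All 15 planted (truly-in-module but unlabeled) genes are recovered as
candidates; the SScore column is −log₁₀ of each gene's best cluster
enrichment p-value. The worked Fisher arithmetic itself is a one-liner —
a 51-gene cluster holding 47 of the 112 network baits in a 270-gene
network:

```r
fisher_greater(47, 4, 65, 154)
#> [1] 5.792078e-17
```

The same stages are available file-to-file through `run_pipeline()` /
`pipeline_config()`, which write TSV outputs per stage plus a JSON run
manifest.

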