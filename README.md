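# gomclust

Grade-of-membership (GoM) clustering for RNA-seq count data.

Hard clustering forces every sample — a tissue biopsy, a single cell — into
exactly one cluster. That is often the wrong model for expression data:
tissues share cell types and pathways, and single cells sit on continuous
trajectories between states. `gomclust` instead fits a mixed-membership
model, identical in form to topic models (latent Dirichlet allocation) and
to admixture models in population genetics: sample *n* draws a proportion
*q<sub>nk</sub>* of its reads from each of *K* clusters, and cluster *k* is
an expression profile *θ<sub>k·</sub>* over genes,

> (c<sub>n1</sub>, …, c<sub>nG</sub>) ~ Multinomial(c<sub>n+</sub>; p<sub>n1</sub>, …, p<sub>nG</sub>),  p<sub>ng</sub> = Σ<sub>k</sub> q<sub>nk</sub> θ<sub>kg</sub>.

The package provides, for audiences working with bulk or single-cell count
matrices:

* **Fitting** — EM-based MAP estimation with symmetric Dirichlet priors and
  multi-restart selection by log-likelihood (`fit_gom()`), with broom-style
  `tidy()`/`glance()` accessors and TSV+JSON serialization.
* **Annotation** — per-cluster "driving gene" scores
  D<sub>g</sub>[k] = min<sub>l≠k</sub> KL(Poisson(θ<sub>kg</sub>) ‖ Poisson(θ<sub>lg</sub>)),
  ranking the genes that most distinguish a cluster from its closest
  neighbour (`distinctiveness()`, `top_driving_genes()`).
* **Visualization** — Structure plots (stacked membership bar charts,
  grouped and gradient-ordered) via `plot_structure()` / `autoplot()`.
* **Thinning** — binomial downsampling of counts,
  t<sub>ng</sub> ~ Bin(c<sub>ng</sub>, p<sub>thin</sub>), to emulate
  shallower sequencing (`thin_counts()`).
* **Benchmarking** — the pairwise two-group separation protocol comparing a
  K = 2 GoM fit cut at the steepest membership fall against hierarchical
  clustering of log-CPM profiles (`pairwise_separation_matrix()`).
* **Simulation** — a generative sampler with known ground truth spanning
  bulk (~10⁷ reads) to single-cell (~10³–10⁴) depths (`simulate_gom_counts()`).
* **I/O** — dense TSV/CSV and Matrix Market triplet count matrices with
  id sidecars, label TSVs, and a command-line wrapper
  (`inst/cli/gomclust.R`) with subcommands `simulate`, `fit`, `annotate`,
  `thin`, `plot-structure`, `evaluate-pairs`, each writing a reproducibility
  manifest.

## Worked example

```r
library(gomclust)

# 120 samples, 300 genes, 3 latent profiles; 70% of samples near-pure,
# the rest admixed; single-cell-like libraries of 5,000 reads.
sim <- simulate_gom_counts(N = 120, G = 300, K = 3, library_sizes = 5000,
                           regime = "mixed", pure_fraction = 0.7,
                           delta = 1.5, seed = 1)
fit <- fit_gom(sim$counts, K = 3, seed = 1)
fit
#> gom_fit: 120 samples, 300 genes, K = 3 clusters
#>   log-likelihood -1796123.3515; NOT converged after 1000 iterations (restart 2, seed 2)

# How close are the fitted memberships to the simulation truth?
aligned_membership_error(sim$q, fit$q)
#> [1] 0.01200362

# Which genes drive cluster 1?
top_driving_genes(distinctiveness(fit), k = 1, n = 3)
#> # A tibble: 3 × 4
#>   cluster gene_id   score  rank
#>     <int> <chr>     <dbl> <int>
#> 1       1 gene_291 0.0798      1
#> 2       1 gene_226 0.0537      2
#> 3       1 gene_246 0.0525      3

# Structure plot, samples grouped by their dominant true cluster
labels <- tibble::tibble(sample_id = rownames(sim$q),
                         label = paste0("group", apply(sim$q, 1, which.max)))
autoplot(fit, labels)
```

The membership error of 0.012 means the average entry of the fitted
120 × 3 membership matrix is within about one percentage point of the truth
after optimal cluster relabelling ("NOT converged" reports that the
log-posterior was still improving by more than the 1e-4 tolerance at the
iteration cap — the fit itself is accurate, as the error shows). The
driving-gene table says reads of `gene_291` are the strongest single-gene
evidence separating cluster 1 from its closest other cluster.

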