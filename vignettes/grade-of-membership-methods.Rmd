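---
title: "Grade-of-membership models for RNA-seq counts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grade-of-membership models for RNA-seq counts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gomclust)
```

## The model

`gomclust` treats an RNA-seq experiment as a samples-by-genes table of read
counts $C_{N \times G} = (c_{ng})$ and models each sample's counts as a
multinomial draw:

$$(c_{n1}, \dots, c_{nG}) \sim \mathrm{Multinomial}(c_{n+},\; p_{n1}, \dots, p_{nG}),
\qquad p_{ng} = \sum_{k=1}^{K} q_{nk}\,\theta_{kg}.$$

Each sample $n$ has a *grade of membership* $q_{nk}$ in each of $K$ clusters
(its rows sum to 1), and each cluster $k$ carries an expression profile
$\theta_{k\cdot}$, a probability vector over genes. This is the structure of
topic models (latent Dirichlet allocation) in document analysis and of
admixture models in population genetics: samples are not forced into a single
cluster but may draw reads from several. For bulk tissue panels this captures
shared function and cellular composition across tissues; for single-cell data
it captures continuous variation between cell states that hard clustering
misrepresents.

Assumptions worth keeping in mind: conditional on $p_{n\cdot}$ the reads are
independent draws, so the model captures no overdispersion beyond what
mixed membership itself induces; the library size $c_{n+}$ is ancillary
(memberships are invariant to sequencing depth in expectation); and $K$ is
chosen by the analyst, not inferred.

## MAP fitting by EM

The fit maximizes the posterior under independent symmetric Dirichlet priors
on the rows of $q$ (concentration `alpha_q`) and of $\theta$
(`alpha_theta`). The EM iteration uses responsibilities
$r_{ngk} = q_{nk}\theta_{kg}/p_{ng}$ over nonzero counts and the closed-form
M-step

$$q_{nk} \propto \sum_g c_{ng} r_{ngk} + (\alpha_q - 1), \qquad
\theta_{kg} \propto \sum_n c_{ng} r_{ngk} + (\alpha_\theta - 1).$$

Internally both sums are computed in one dense multiplicative pass
($A = q \circ (X\theta^\top)$, $B = \theta \circ (q^\top X)$ with
$X = C/P$ masked to nonzero counts), which is algebraically identical to the
responsibility sums and lets BLAS do the work; zero counts contribute
nothing, so sparsity is respected where it matters.

Tunable parameters, defaults, and reasoning:

* `alpha_theta = 1.1` — keeps every $\theta_{kg}$ strictly positive. The
  driving-gene score below is a KL divergence between Poisson rates and is
  undefined at zero rates, so positivity is a modelling requirement, not a
  numerical fudge. Genes with zero total count keep prior-only mass and are
  listed in a warning rather than silently dropped.
* `alpha_q = 1` — a flat prior; memberships are maximum-likelihood. Values
  below 1 would break the closed-form M-step (negative pseudo-counts).
* `tol = 1e-4` (absolute change in log-posterior), `max_iter = 1000` — plain
  EM on these problems gains well under `tol` per iteration near a mode.
* `n_restarts = 3` — EM finds local modes; three independent seeded starts
  are run and the one with the highest *data log-likelihood* is kept
  (the prior term is excluded from selection; with fixed hyperparameters it
  offsets all restarts by a parameter-dependent but practically negligible
  amount, and recording the rule keeps selection reproducible).
* Initialization: membership rows drawn from a flat Dirichlet; profile rows
  are the global gene frequencies blended (9:1) with Dirichlet noise. The
  data-informed profile start converges much faster than a fully random one,
  and the noise differentiates restarts.

The log-posterior used for convergence and monotonicity checks is the kernel
(likelihood plus Dirichlet kernels); the Dirichlet normalizing constants are
parameter-free and omitted. Monotonicity of EM holds for the kernel exactly,
and the suite asserts it to a relative `1e-8` at every iteration. We chose
plain EM over quasi-Newton acceleration deliberately: the monotonicity
guarantee is a checkable contract, and correctness is easier to establish.

Degenerate inputs: a row of pseudo-counts that underflows to zero mass is
reset to uniform with a warning; samples with zero total reads are rejected
at fit time (the multinomial is undefined for an empty library); `K` larger
than the gene count draws a warning.

## Driving genes

To interpret a cluster we score every gene by how far its rate in cluster
$k$ is from the *closest* other cluster, using the KL divergence between
Poisson distributions:

$$\mathrm{KL}_g[k,l] = \theta_{kg}\log\frac{\theta_{kg}}{\theta_{lg}}
  + \theta_{lg} - \theta_{kg}, \qquad
  D_g[k] = \min_{l \ne k} \mathrm{KL}_g[k,l].$$

A gene scores high only if it separates cluster $k$ from *every* other
cluster, which is what makes the top-ranked genes good candidates for
annotation. Scores are computed on $\theta$ as fitted; the divergence is
applied to the probability-scale rates directly. Ties in rankings break by
ascending gene id so reports are deterministic; exact zeros in $\theta$
(possible only if `alpha_theta` is forced to 1) are floored at `1e-12` with
a warning. Downstream gene-set enrichment is out of scope — the exporter
writes plain id lists consumable by external enrichment tools.

## Thinning

`thin_counts()` simulates shallower sequencing: $t_{ng} \sim
\mathrm{Bin}(c_{ng}, p_\mathrm{thin})$ independently per entry. The
reproducibility contract is part of the function's definition: one seed, one
random stream, entries consumed in row-major order, and zero entries do not
consume draws. That last convention makes the draw sequence independent of
how many zeros a sparse matrix stores, at the cost of coupling an entry's
draw to the pattern of preceding nonzeros — a trade we accept for stable,
testable behaviour.

## The two-group separation benchmark

To compare mixed-membership fitting against the field's default, the
benchmark repeatedly asks: given samples from two labelled groups, does a
method split them back into those groups?

* **GoM route**: fit $K = 2$ on *raw counts*, sort samples by their cluster-1
  membership, and cut at the *steepest fall* — the largest drop between
  consecutive sorted values. Ties in the maximal gap break at the first
  (highest-ranked) position; an all-equal vector yields a degenerate
  $1$ vs $n-1$ split plus a warning. The cut is invariant to shifting and
  positive rescaling of the membership vector.
* **Hierarchical route**: log-CPM transform
  ($\log_2(1 + 10^6 c_{ng}/c_{n+})$, pseudo-count inside the log so zero
  counts map to 0), Euclidean distances, agglomerative clustering with
  complete linkage (average linkage available), dendrogram cut at $K = 2$.
  Raw-count and per-gene standardized inputs are available as options.

A trial succeeds only if the partition equals the label groups exactly, in
either orientation. Up to `n_sample` (default 50) samples are pooled from
the two groups without enforcing balance; only fully degenerate subsamples
(fewer than 2 of either label) are redrawn, up to 20 times.
`pairwise_separation_matrix()` runs one trial per label pair per method with
per-pair derived seeds and reports per-method success fractions.

## The simulator

`simulate_gom_counts()` draws data from the generative model itself, with
ground truth returned for scoring:

* **Profiles**: a base gene-frequency vector from a symmetric Dirichlet with
  concentration 0.05 — heavy-tailed, so a few genes absorb most reads, as in
  real RNA-seq — perturbed per cluster by $\theta_k \propto
  \mathrm{base} \times e^{\delta z}$, $z \sim N(0,1)$. The separation knob
  $\delta$ is 0 for identical profiles; divergence grows monotonically with
  it. In this package's tests and acceptance runs $\delta = 1.5$ is used as
  "strong separation" (rate ratios of $e^{\pm 3}$ are routine there, far
  beyond the transition region, which sits near $\delta \approx 0.1$ at
  library size $10^4$).
* **Memberships**: `pure` (one-hot, round-robin), `dirichlet`,
  `admixed` (a linear gradient between consecutive clusters, emulating
  developmental trajectories), and `mixed` — 70% one-hot plus 30% flat
  Dirichlet by default, the regime used for recovery benchmarks.
* **Library sizes**: presets `bulk` ($10^7$) and `sc` ($10^4$), or explicit
  per-sample values.

What the simulator does *not* emulate: overdispersion beyond the mixture,
batch effects, zero inflation, gene–gene correlation beyond profiles, or
allele-specific signal. Tests passing on these data show the estimator
recovers the model's own structure at realistic depths; they do not certify
behaviour under real-data artefacts the model excludes.

Problem sizes in the test and acceptance suites (50–200 samples, 100–500
genes, libraries $10^2$–$10^4$) were chosen as the smallest sizes at which
the statistical claims are comfortably testable; recovery at bulk depth is
strictly easier than the single-cell-scale settings exercised.

## Structure plots

The Structure plot draws one horizontal stacked bar per sample, segment
lengths equal to memberships, grouped so samples sharing a label are
contiguous. The within-group order is, deliberately, by the group's dominant
cluster (highest mean membership), descending with stable ties: the
published convention "sorted by proportional representation" admits several
readings, and this one produces the familiar within-group gradient. The
built-in palette has 20 qualitative colors; larger $K$ requires a custom
palette because such plots stop being readable anyway.

## Known limitations

* No automatic choice of $K$, and no variational or collapsed-Gibbs
  inference; plain EM MAP only.
* Restart selection by likelihood can, in principle, prefer a mode the prior
  would down-weight; with the default near-flat priors this is immaterial.
* The benchmark's success criterion is exact partition recovery, which is
  strict: a single misplaced sample counts as failure.
* `aligned_membership_error()` enumerates all $K!$ relabellings; fine for
  the $K \le 5$ regime it serves, factorial beyond that.
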