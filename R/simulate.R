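#' Simulate cluster expression profiles
#'
#' Draws a shared base gene-frequency vector from a heavy-tailed symmetric
#' Dirichlet (small concentration mimics the skewed expression distribution
#' of RNA-seq, where a few genes absorb most reads), then perturbs it per
#' cluster on the log scale with strength `delta`:
#' `theta_k propto base * exp(delta * z_kg)`, `z_kg ~ N(0,1)`.
#' `delta = 0` yields K identical rows; larger `delta` pushes the rows apart
#' in Poisson Kullback-Leibler divergence.
#'
#' @param K number of clusters.
#' @param G number of genes.
#' @param delta non-negative separation strength.
#' @param profile_shape Dirichlet concentration of the base draw (default
#'   0.05, heavy-tailed).
#' @param seed integer seed.
#' @return a K x G matrix, rows summing to 1, rownames `cluster_k`.
#' @export
simulate_profiles <- function(K, G, delta = 1, profile_shape = 0.05, seed = 1) {
  stopifnot(K >= 1, G >= 1, delta >= 0, profile_shape > 0)
  set.seed(seed)
  base <- as.vector(rdirichlet(1, profile_shape, len = G))
  base <- base + 1e-12            # keep strictly positive
  base <- base / sum(base)
  theta <- matrix(NA_real_, K, G,
                  dimnames = list(paste0("cluster_", seq_len(K)),
                                  paste0("gene_", seq_len(G))))
  for (k in seq_len(K)) {
    z <- stats::rnorm(G)
    row <- base * exp(delta * z)
    theta[k, ] <- row / sum(row)
  }
  theta
}

#' Simulate membership proportions
#'
#' @param N number of samples.
#' @param K number of clusters.
#' @param regime `"pure"` (one-hot rows, clusters assigned round-robin),
#'   `"dirichlet"` (rows drawn from a symmetric Dirichlet with concentration
#'   `alpha`), `"admixed"` (a blockwise gradient: samples interpolate linearly
#'   between consecutive cluster pairs, producing the ordered-gradient
#'   memberships characteristic of developmental series), or `"mixed"`
#'   (fraction `pure_fraction` one-hot, remainder Dirichlet).
#' @param alpha Dirichlet concentration for the admixed draws.
#' @param pure_fraction fraction of one-hot samples under `"mixed"`.
#' @return an N x K membership matrix, rows summing to 1.
#' @keywords internal
simulate_memberships <- function(N, K, regime = c("mixed", "pure", "dirichlet", "admixed"),
                                 alpha = 1, pure_fraction = 0.7) {
  regime <- match.arg(regime)
  q <- matrix(0, N, K)
  assign_k <- rep_len(seq_len(K), N)
  if (regime == "pure") {
    q[cbind(seq_len(N), assign_k)] <- 1
  } else if (regime == "dirichlet") {
    q <- rdirichlet(N, alpha, len = K)
  } else if (regime == "admixed") {
    # gradient between consecutive clusters: sample i sits at position t in [0, K-1]
    t <- seq(0, K - 1, length.out = N)
    lo <- pmin(floor(t) + 1, K - 1)
    w <- t - (lo - 1)
    q[cbind(seq_len(N), lo)] <- 1 - w
    q[cbind(seq_len(N), lo + 1)] <- q[cbind(seq_len(N), lo + 1)] + w
  } else { # mixed
    n_pure <- round(pure_fraction * N)
    if (n_pure > 0) q[cbind(seq_len(n_pure), assign_k[seq_len(n_pure)])] <- 1
    if (n_pure < N) q[(n_pure + 1):N, ] <- rdirichlet(N - n_pure, alpha, len = K)
  }
  q
}

#' Simulate counts from the grade-of-membership generative model
#'
#' Draws memberships `q` per the chosen regime, computes per-sample
#' multinomial probabilities `p = q %*% theta`, and draws each sample's
#' counts as `Multinomial(library_size_n, p_n.)`. Returns the counts
#' together with the ground-truth `q` and `theta`, so inference can be
#' scored against the truth.
#'
#' @param N,G,K samples, genes, clusters.
#' @param library_sizes length-N positive integers, or a single value
#'   recycled. Presets: `"bulk"` = 1e7, `"sc"` = 1e4.
#' @param regime,alpha,pure_fraction membership regime (see
#'   [simulate_memberships]).
#' @param delta,profile_shape profile separation and base concentration
#'   (see [simulate_profiles()]).
#' @param theta optional K x G profile matrix overriding the simulated one.
#' @param seed integer seed; the whole draw is reproducible from it.
#' @return a list with `counts` (a [count_matrix()]), `q` (N x K truth),
#'   `theta` (K x G truth).
#' @examples
#' sim <- simulate_gom_counts(N = 20, G = 50, K = 2, library_sizes = 1000, seed = 1)
#' sim$counts
#' @export
simulate_gom_counts <- function(N, G, K, library_sizes = 1e4,
                                regime = "mixed", alpha = 1, pure_fraction = 0.7,
                                delta = 1, profile_shape = 0.05,
                                theta = NULL, seed = 1) {
  stopifnot(N >= 1, G >= 1, K >= 1)
  if (is.character(library_sizes)) {
    library_sizes <- switch(match.arg(library_sizes, c("bulk", "sc")),
                            bulk = 1e7, sc = 1e4)
  }
  library_sizes <- rep_len(library_sizes, N)
  stopifnot(all(library_sizes >= 1))
  if (is.null(theta)) {
    theta <- simulate_profiles(K, G, delta = delta, profile_shape = profile_shape,
                               seed = seed)
  } else {
    stopifnot(nrow(theta) == K, ncol(theta) == G)
  }
  set.seed(seed + 1L)
  q <- simulate_memberships(N, K, regime = regime, alpha = alpha,
                            pure_fraction = pure_fraction)
  p <- q %*% theta
  counts <- matrix(0, N, G,
                   dimnames = list(paste0("sample_", seq_len(N)), colnames(theta)))
  for (n in seq_len(N)) {
    counts[n, ] <- as.vector(rmultinom(1, size = library_sizes[n], prob = p[n, ]))
  }
  rownames(q) <- rownames(counts)
  colnames(q) <- rownames(theta)
  list(counts = count_matrix(counts), q = q, theta = theta)
}

#' Build a two-group fixture for the separation benchmark
#'
#' Two groups of pure samples drawn from two profiles at separation `delta`,
#' with attached group labels. `delta = 0` makes the groups statistically
#' indistinguishable.
#'
#' @param delta profile separation.
#' @param n_per_group samples per group (>= 2).
#' @param library_size reads per sample.
#' @param G number of genes.
#' @param seed integer seed.
#' @param profile_shape base Dirichlet concentration.
#' @return list with `counts` (a [count_matrix()]) and `labels` (tibble
#'   `sample_id`, `label` with values `"groupA"`/`"groupB"`).
#' @export
make_pair_fixture <- function(delta, n_per_group = 25, library_size = 1e4,
                              G = 200, seed = 1, profile_shape = 0.05) {
  stopifnot(n_per_group >= 2)
  theta <- simulate_profiles(2, G, delta = delta, profile_shape = profile_shape,
                             seed = seed)
  N <- 2L * n_per_group
  q <- matrix(0, N, 2)
  q[seq_len(n_per_group), 1] <- 1
  q[(n_per_group + 1):N, 2] <- 1
  p <- q %*% theta
  set.seed(seed + 1L)
  counts <- matrix(0, N, G, dimnames = list(paste0("sample_", seq_len(N)), colnames(theta)))
  for (n in seq_len(N)) {
    counts[n, ] <- as.vector(rmultinom(1, size = library_size, prob = p[n, ]))
  }
  labels <- tibble::tibble(
    sample_id = rownames(counts),
    label = rep(c("groupA", "groupB"), each = n_per_group))
  list(counts = count_matrix(counts), labels = labels)
}
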