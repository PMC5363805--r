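# Shared fixtures and independent oracles used across the suite.

# Random small count matrix with no empty samples.
random_counts <- function(N, G, seed, lambda = 5) {
  set.seed(seed)
  x <- matrix(rpois(N * G, lambda), N, G)
  empty <- rowSums(x) == 0
  x[empty, 1] <- x[empty, 1] + 1L
  count_matrix(x)
}

# Scalar triple-loop oracle for the distinctiveness score: literal
# evaluation of min over l != k of the Poisson KL at every (k, g).
distinctiveness_oracle <- function(theta) {
  K <- nrow(theta); G <- ncol(theta)
  D <- matrix(NA_real_, K, G)
  for (k in seq_len(K)) {
    for (g in seq_len(G)) {
      best <- Inf
      for (l in seq_len(K)) {
        if (l == k) next
        kl <- theta[k, g] * log(theta[k, g] / theta[l, g]) + theta[l, g] - theta[k, g]
        if (kl < best) best <- kl
      }
      D[k, g] <- best
    }
  }
  D
}

# Scalar-loop oracle for one MAP-EM update: explicit responsibilities
# r_ngk = q_nk theta_kg / p_ng summed into pseudo-counts entry by entry.
em_update_oracle <- function(C, q, theta, alpha_q, alpha_theta) {
  N <- nrow(C); G <- ncol(C); K <- ncol(q)
  A <- matrix(alpha_q - 1, N, K)
  B <- matrix(alpha_theta - 1, K, G)
  for (n in seq_len(N)) {
    for (g in seq_len(G)) {
      if (C[n, g] == 0) next
      p_ng <- sum(q[n, ] * theta[, g])
      for (k in seq_len(K)) {
        r <- q[n, k] * theta[k, g] / p_ng
        A[n, k] <- A[n, k] + C[n, g] * r
        B[k, g] <- B[k, g] + C[n, g] * r
      }
    }
  }
  list(q = A / rowSums(A), theta = B / rowSums(B))
}

# Independent permutation enumerator (head-recursive, different code path
# from the package's insertion-based one) for the alignment oracle.
perms_oracle <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perms_oracle(k - 1)
  out <- NULL
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

aligned_error_oracle <- function(q_true, q_est) {
  P <- perms_oracle(ncol(q_true))
  min(apply(P, 1, function(p) mean(abs(q_true - q_est[, p, drop = FALSE]))))
}

# Drop-in random fit state for em_step tests.
random_fit_state <- function(N, G, K, seed) {
  set.seed(seed)
  q <- matrix(rgamma(N * K, 1), N, K); q <- q / rowSums(q)
  theta <- matrix(rgamma(K * G, 1), K, G); theta <- theta / rowSums(theta)
  structure(list(q = q, theta = theta, log_posterior_trace = numeric(),
                 log_likelihood = NA_real_, n_iter = 0L),
            class = "gom_fit")
}

expect_rows_sum_to_one <- function(x, tol = 1e-8) {
  expect_lt(max(abs(rowSums(x) - 1)), tol)
}
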