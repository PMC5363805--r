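#' Fit configuration for the grade-of-membership model
#'
#' Bundles the hyperparameters of EM-based MAP estimation. Symmetric
#' Dirichlet priors with concentration >= 1 keep the M-step closed-form;
#' `alpha_theta = 1.1` keeps every profile entry strictly positive (the
#' Poisson KL driving-gene score needs positive rates) while
#' `alpha_q = 1` leaves memberships at their maximum-likelihood values.
#'
#' @param K number of clusters (>= 1).
#' @param tol convergence threshold on the absolute change of the
#'   log-posterior between EM iterations.
#' @param max_iter maximum EM iterations per restart.
#' @param n_restarts independent EM runs; the one with the highest data
#'   log-likelihood is kept.
#' @param seed integer seed; restart r uses `seed + r - 1`.
#' @param alpha_theta,alpha_q symmetric Dirichlet concentrations (>= 1) on
#'   profile rows and membership rows.
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(K, tol = 1e-4, max_iter = 1000, n_restarts = 3,
                       seed = 1, alpha_theta = 1.1, alpha_q = 1) {
  if (K < 1) abort("K must be >= 1")
  stopifnot(tol > 0, max_iter >= 1, n_restarts >= 1,
            alpha_theta >= 1, alpha_q >= 1)
  structure(list(K = as.integer(K), tol = tol, max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 alpha_theta = alpha_theta, alpha_q = alpha_q),
            class = "fit_config")
}

# Data log-likelihood sum_{ng} c_ng log p_ng over nonzero counts.
multinomial_loglik <- function(C, p) {
  nz <- C > 0
  if (any(p[nz] == 0)) {
    warn("p_ng = 0 where c_ng > 0; log-likelihood is -Inf")
    return(-Inf)
  }
  sum(C[nz] * log(p[nz]))
}

# Log-posterior kernel: likelihood + Dirichlet prior kernels (normalizing
# constants are parameter-free and omitted; monotonicity is unaffected).
log_posterior_kernel <- function(C, q, theta, alpha_q, alpha_theta) {
  lp <- multinomial_loglik(C, q %*% theta)
  if (alpha_q > 1) lp <- lp + (alpha_q - 1) * sum(log(q))
  if (alpha_theta > 1) lp <- lp + (alpha_theta - 1) * sum(log(theta))
  lp
}

# One full E+M update. Dense multiplicative form of the standard MAP-EM:
# with X = C / (q theta) masked to nonzero counts, the expected counts are
#   A_nk = q_nk * (X theta^T)_nk   (membership pseudo-counts)
#   B_kg = theta_kg * (q^T X)_kg   (profile pseudo-counts)
# which equal the triplet sums sum_g c_ng r_ngk and sum_n c_ng r_ngk with
# responsibilities r_ngk = q_nk theta_kg / p_ng.
em_update <- function(C, q, theta, alpha_q, alpha_theta) {
  p <- q %*% theta
  X <- matrix(0, nrow(C), ncol(C))
  nz <- C > 0
  X[nz] <- C[nz] / p[nz]
  A <- q * (X %*% t(theta)) + (alpha_q - 1)
  B <- theta * (crossprod(q, X)) + (alpha_theta - 1)
  list(q = row_normalize(A), theta = row_normalize(B))
}

#' One EM iteration on a fitted state
#'
#' Applies a single E+M update to the parameters of a [gom_fit] object and
#' returns the updated fit with the log-posterior trace extended. The
#' log-posterior never decreases beyond `1e-8 * |value|`.
#'
#' @param m a [count_matrix()].
#' @param fit a `gom_fit` (possibly mid-optimization).
#' @param cfg a [fit_config()] supplying the priors.
#' @return the updated `gom_fit`.
#' @export
em_step <- function(m, fit, cfg) {
  stopifnot(is_count_matrix(m), inherits(fit, "gom_fit"))
  C <- as_plain_matrix(m)
  upd <- em_update(C, fit$q, fit$theta, cfg$alpha_q, cfg$alpha_theta)
  lp <- log_posterior_kernel(C, upd$q, upd$theta, cfg$alpha_q, cfg$alpha_theta)
  fit$q <- upd$q
  fit$theta <- upd$theta
  fit$log_posterior_trace <- c(fit$log_posterior_trace, lp)
  fit$log_likelihood <- multinomial_loglik(C, upd$q %*% upd$theta)
  fit$n_iter <- fit$n_iter + 1L
  fit
}

# Seeded initialization: q rows from a flat Dirichlet; theta rows are the
# global gene frequencies blended with Dirichlet noise (data-informed start,
# randomness across restarts explores modes).
init_params <- function(C, K, seed) {
  set.seed(seed)
  N <- nrow(C); G <- ncol(C)
  q <- rdirichlet(N, 1, len = K)
  f <- colSums(C) + 0.1
  f <- f / sum(f)
  noise <- rdirichlet(K, 1, len = G)
  theta <- row_normalize(0.9 * matrix(f, K, G, byrow = TRUE) + 0.1 * noise)
  list(q = q, theta = theta)
}

run_em <- function(C, cfg, seed, init = NULL) {
  if (is.null(init)) init <- init_params(C, cfg$K, seed)
  q <- init$q; theta <- init$theta
  trace <- log_posterior_kernel(C, q, theta, cfg$alpha_q, cfg$alpha_theta)
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    upd <- em_update(C, q, theta, cfg$alpha_q, cfg$alpha_theta)
    q <- upd$q; theta <- upd$theta
    lp <- log_posterior_kernel(C, q, theta, cfg$alpha_q, cfg$alpha_theta)
    iter <- iter + 1L
    delta <- lp - trace[length(trace)]
    trace <- c(trace, lp)
    if (is.finite(delta) && abs(delta) < cfg$tol) { converged <- TRUE; break }
  }
  list(q = q, theta = theta, trace = trace, converged = converged, n_iter = iter,
       log_likelihood = multinomial_loglik(C, q %*% theta))
}

#' Fit the grade-of-membership model by EM MAP estimation
#'
#' Models each sample's counts as Multinomial with probabilities
#' `p_ng = sum_k q_nk theta_kg`: `q` holds per-sample membership proportions
#' over K clusters and `theta` per-cluster expression profiles over genes.
#' Runs `n_restarts` independent EM runs from seeded random initializations
#' and keeps the run with the highest data log-likelihood.
#'
#' @param m a [count_matrix()].
#' @param K number of clusters; remaining arguments as in [fit_config()].
#' @inheritParams fit_config
#' @param init optional list with `q` (N x K) and `theta` (K x G) to start
#'   from (single run; intended for diagnostics).
#' @return an object of class `gom_fit`: `q` (N x K), `theta` (K x G),
#'   `log_likelihood`, `log_posterior_trace`, `converged`, `n_iter`,
#'   `restart_index`, `seed_used`, `config`.
#' @examples
#' sim <- simulate_gom_counts(N = 30, G = 60, K = 2, library_sizes = 500, seed = 1)
#' fit <- fit_gom(sim$counts, K = 2, seed = 1)
#' glance(fit)
#' @export
fit_gom <- function(m, K, tol = 1e-4, max_iter = 1000, n_restarts = 3,
                    seed = 1, alpha_theta = 1.1, alpha_q = 1, init = NULL) {
  stopifnot(is_count_matrix(m))
  cfg <- fit_config(K, tol, max_iter, n_restarts, seed, alpha_theta, alpha_q)
  C <- as_plain_matrix(m)
  if (any(rowSums(C) == 0)) {
    abort("cannot fit: sample(s) with zero total reads present; drop them first")
  }
  if (ncol(C) < cfg$K) {
    warn(sprintf("K = %d exceeds the number of genes (%d)", cfg$K, ncol(C)))
  }
  zero_genes <- colnames(C)[colSums(C) == 0]
  if (length(zero_genes)) {
    warn(paste0("gene(s) with zero total count retain prior-only profile mass: ",
                paste(head(zero_genes, 5), collapse = ", "),
                if (length(zero_genes) > 5) sprintf(" (+%d more)", length(zero_genes) - 5) else ""))
  }
  runs <- vector("list", cfg$n_restarts)
  n_run <- if (is.null(init)) cfg$n_restarts else 1L
  for (r in seq_len(n_run)) {
    res <- tryCatch(run_em(C, cfg, seed = cfg$seed + r - 1L, init = init),
                    error = function(e) NULL)
    runs[[r]] <- res
  }
  lls <- vapply(runs[seq_len(n_run)], function(x) if (is.null(x)) -Inf else x$log_likelihood, 0)
  if (all(!is.finite(lls))) abort("all restarts failed numerically")
  best <- which.max(lls)
  res <- runs[[best]]
  dimnames(res$q) <- list(rownames(C), paste0("cluster_", seq_len(cfg$K)))
  dimnames(res$theta) <- list(paste0("cluster_", seq_len(cfg$K)), colnames(C))
  structure(list(q = res$q, theta = res$theta,
                 log_likelihood = res$log_likelihood,
                 log_posterior_trace = res$trace,
                 converged = res$converged, n_iter = res$n_iter,
                 restart_index = best, seed_used = cfg$seed + best - 1L,
                 restart_log_likelihoods = lls[seq_len(n_run)],
                 config = unclass(cfg)),
            class = "gom_fit")
}

#' Predicted per-sample multinomial probabilities
#'
#' The implied probability of a read from sample n mapping to gene g,
#' `p_ng = sum_k q_nk theta_kg`; each row is a probability vector.
#'
#' @param fit a `gom_fit` (or any list with conformable `q` and `theta`).
#' @return an N x G matrix with rows summing to 1.
#' @export
compute_p <- function(fit) {
  if (ncol(fit$q) != nrow(fit$theta)) abort("q and theta are not conformable")
  fit$q %*% fit$theta
}

#' Multinomial data log-likelihood of a fit
#'
#' `sum_n sum_g c_ng log(p_ng)` over nonzero counts; with
#' `include_multinomial_coefficient = TRUE` the parameter-free multinomial
#' log-coefficient `sum_n [log(c_n+!) - sum_g log(c_ng!)]` is added.
#' If some `p_ng = 0` where `c_ng > 0`, returns `-Inf` with a warning.
#'
#' @param m a [count_matrix()].
#' @param fit a `gom_fit`.
#' @param include_multinomial_coefficient add the multinomial coefficient?
#' @return a single numeric value.
#' @export
gom_log_likelihood <- function(m, fit, include_multinomial_coefficient = FALSE) {
  stopifnot(is_count_matrix(m))
  C <- as_plain_matrix(m)
  p <- compute_p(fit)
  if (!all(dim(C) == dim(p))) abort("count matrix and fit dimensions differ")
  ll <- multinomial_loglik(C, p)
  if (include_multinomial_coefficient) {
    ll <- ll + sum(lgamma(rowSums(C) + 1)) - sum(lgamma(C + 1))
  }
  ll
}

#' @export
logLik.gom_fit <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$q) + length(object$theta), class = "logLik")
}

#' @method print gom_fit
#' @export
print.gom_fit <- function(x, ...) {
  cat(sprintf("gom_fit: %d samples, %d genes, K = %d clusters\n",
              nrow(x$q), ncol(x$theta), ncol(x$q)))
  cat(sprintf("  log-likelihood %.4f; %s after %d iterations (restart %d, seed %d)\n",
              x$log_likelihood,
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$restart_index, x$seed_used))
  invisible(x)
}

#' Tidy a grade-of-membership fit into a long tibble
#'
#' @param x a `gom_fit`.
#' @param matrix `"q"` for sample memberships (columns `sample_id`,
#'   `cluster`, `membership`) or `"theta"` for cluster profiles (columns
#'   `cluster`, `gene_id`, `probability`).
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.gom_fit <- function(x, matrix = c("q", "theta"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "q") {
    tibble::as_tibble(x$q, rownames = "sample_id") |>
      tidyr::pivot_longer(-"sample_id", names_to = "cluster",
                          values_to = "membership") |>
      dplyr::mutate(cluster = as.integer(sub("^cluster_", "", .data$cluster)))
  } else {
    tibble::as_tibble(x$theta, rownames = "cluster") |>
      tidyr::pivot_longer(-"cluster", names_to = "gene_id",
                          values_to = "probability") |>
      dplyr::mutate(cluster = as.integer(sub("^cluster_", "", .data$cluster)))
  }
}

#' One-row fit summary
#' @param x a `gom_fit`.
#' @param ... unused.
#' @return a one-row tibble with dimensions, likelihood and convergence info.
#' @export
glance.gom_fit <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$q), n_genes = ncol(x$theta),
                 K = ncol(x$q), log_likelihood = x$log_likelihood,
                 converged = x$converged, n_iter = x$n_iter,
                 restart_index = x$restart_index, seed_used = x$seed_used)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
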