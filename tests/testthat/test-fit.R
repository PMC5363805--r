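test_that("predicted probabilities reduce correctly for one-hot and symmetric mixtures", {
  theta <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  onehot <- list(q = rbind(c(1, 0), c(0, 1)), theta = theta)
  p <- compute_p(onehot)
  expect_equal(p[1, ], theta[1, ])
  expect_equal(p[2, ], theta[2, ])
  half <- list(q = matrix(c(0.5, 0.5), 1), theta = theta)
  expect_equal(as.vector(compute_p(half)), c(0.5, 0.5))
  expect_error(compute_p(list(q = matrix(1, 1, 3), theta = theta)), "conformable")
})

test_that("predicted probabilities match the scalar-loop mixture sum", {
  set.seed(11)
  q <- matrix(rgamma(6, 1), 3, 2); q <- q / rowSums(q)
  theta <- matrix(rgamma(8, 1), 2, 4); theta <- theta / rowSums(theta)
  p <- compute_p(list(q = q, theta = theta))
  for (n in 1:3) for (g in 1:4) {
    expect_equal(p[n, g], sum(q[n, ] * theta[, g]), tolerance = 1e-14)
  }
  expect_rows_sum_to_one(p, tol = 1e-12)
})

test_that("log-likelihood matches direct evaluation with and without the coefficient", {
  m <- count_matrix(matrix(c(2, 2), 1, 2))
  fit <- list(q = matrix(1, 1, 1), theta = matrix(c(0.5, 0.5), 1, 2))
  class(fit) <- "gom_fit"
  expect_equal(gom_log_likelihood(m, fit), 4 * log(0.5), tolerance = 1e-12)
  expect_equal(gom_log_likelihood(m, fit, include_multinomial_coefficient = TRUE),
               4 * log(0.5) + log(6), tolerance = 1e-12)
  # zero probability under positive count warns and returns -Inf
  bad <- fit; bad$theta <- matrix(c(1, 0), 1, 2)
  expect_warning(ll <- gom_log_likelihood(m, bad), "-Inf")
  expect_identical(ll, -Inf)
})

test_that("empirical proportions maximize the multinomial likelihood locally", {
  m <- count_matrix(matrix(c(3, 5, 2), 1, 3))
  p_hat <- c(3, 5, 2) / 10
  fit_at <- function(p) {
    f <- list(q = matrix(1, 1, 1), theta = matrix(p, 1, 3)); class(f) <- "gom_fit"; f
  }
  ll_hat <- gom_log_likelihood(m, fit_at(p_hat))
  set.seed(5)
  for (i in 1:25) {
    eps <- rnorm(3, sd = 0.02)
    p_pert <- p_hat + eps - mean(eps)     # stay on the simplex
    if (any(p_pert <= 0)) next
    expect_lt(gom_log_likelihood(m, fit_at(p_pert)), ll_hat)
  }
})

test_that("one EM update matches the scalar responsibility oracle", {
  for (seed in 1:5) {
    m <- random_counts(6, 8, seed = seed)
    st <- random_fit_state(6, 8, K = 3, seed = seed + 100)
    cfg <- fit_config(K = 3, alpha_theta = 1.1, alpha_q = 1.2)
    upd <- em_step(m, st, cfg)
    oracle <- em_update_oracle(unclass(m), st$q, st$theta, 1.2, 1.1)
    expect_equal(unname(upd$q), oracle$q, tolerance = 1e-12)
    expect_equal(unname(upd$theta), oracle$theta, tolerance = 1e-12)
  }
  # the minimal hand-checkable case: one sample, two genes, two clusters
  m <- count_matrix(matrix(c(3, 1), 1, 2))
  st <- structure(list(q = matrix(c(0.6, 0.4), 1),
                       theta = rbind(c(0.7, 0.3), c(0.2, 0.8)),
                       log_posterior_trace = numeric(), n_iter = 0L),
                  class = "gom_fit")
  cfg <- fit_config(K = 2, alpha_theta = 1, alpha_q = 1)
  p <- c(0.6 * 0.7 + 0.4 * 0.2, 0.6 * 0.3 + 0.4 * 0.8)
  r1 <- 0.6 * c(0.7, 0.3) / p               # responsibilities for cluster 1
  q1_new <- (3 * r1[1] + 1 * r1[2]) / 4
  upd <- em_step(m, st, cfg)
  expect_equal(upd$q[1, 1], q1_new, tolerance = 1e-14)
})

test_that("EM iterations never decrease the log-posterior and keep rows normalized", {
  set.seed(99)
  for (trial in 1:10) {
    m <- random_counts(8, 12, seed = trial + 200)
    K <- sample(2:3, 1)
    st <- random_fit_state(8, 12, K, seed = trial + 300)
    cfg <- fit_config(K = K)
    prev <- -Inf
    for (i in 1:25) {
      st <- em_step(m, st, cfg)
      lp <- st$log_posterior_trace[length(st$log_posterior_trace)]
      expect_gte(lp, prev - 1e-8 * abs(lp))
      expect_rows_sum_to_one(st$q)
      expect_rows_sum_to_one(st$theta)
      prev <- lp
    }
  }
})

test_that("a stationary K=1 state is a fixed point of the EM update", {
  m <- count_matrix(rbind(c(3, 1), c(1, 3)))
  alpha <- 1.1
  theta_star <- (colSums(unclass(m)) + alpha - 1) /
    (sum(unclass(m)) + 2 * (alpha - 1))
  st <- structure(list(q = matrix(1, 2, 1), theta = matrix(theta_star, 1),
                       log_posterior_trace = numeric(), n_iter = 0L),
                  class = "gom_fit")
  upd <- em_step(m, st, fit_config(K = 1, alpha_theta = alpha))
  expect_equal(as.vector(upd$theta), unname(theta_star), tolerance = 1e-12)
  expect_equal(as.vector(upd$q), c(1, 1), tolerance = 1e-12)
})

test_that("K=1 fits land on the closed-form MAP profile", {
  fit <- fit_gom(count_matrix(rbind(c(3, 1), c(1, 3))), K = 1, alpha_theta = 1.1,
                 seed = 1)
  expect_equal(as.vector(fit$theta), c(4.1 / 8.2, 4.1 / 8.2), tolerance = 1e-10)
  expect_equal(as.vector(fit$q), c(1, 1))
  for (seed in 1:5) {
    m <- random_counts(7, 11, seed = seed + 400)
    fit <- fit_gom(m, K = 1, alpha_theta = 1.3, seed = seed)
    x <- unclass(m)
    closed <- (colSums(x) + 0.3) / (sum(x) + ncol(x) * 0.3)
    expect_equal(unname(as.vector(fit$theta)), unname(closed), tolerance = 1e-10)
  }
})

test_that("disjoint-support groups are recovered by majority membership", {
  theta <- rbind(c(rep(0.1, 10), rep(0, 10)), c(rep(0, 10), rep(0.1, 10)))
  sim <- simulate_gom_counts(N = 40, G = 20, K = 2, library_sizes = 1000,
                             regime = "pure", theta = theta, seed = 8)
  fit <- suppressWarnings(fit_gom(sim$counts, K = 2, seed = 8))
  est_group <- apply(fit$q, 1, which.max)
  true_group <- apply(sim$q, 1, which.max)
  # identical up to cluster relabelling
  agreement <- max(mean(est_group == true_group), mean(est_group != true_group))
  expect_equal(agreement, 1)
})

test_that("fits are reproducible and the kept restart dominates the others", {
  m <- random_counts(20, 30, seed = 77)
  f1 <- fit_gom(m, K = 2, seed = 5)
  f2 <- fit_gom(m, K = 2, seed = 5)
  expect_identical(f1$q, f2$q)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$log_posterior_trace, f2$log_posterior_trace)
  expect_true(all(f1$log_likelihood >= f1$restart_log_likelihoods))
  expect_equal(f1$seed_used, 5 + f1$restart_index - 1)
})

test_that("permuting the initialization labels permutes the fitted clusters", {
  m <- random_counts(15, 20, seed = 13)
  set.seed(21)
  q0 <- matrix(rgamma(45, 1), 15, 3); q0 <- q0 / rowSums(q0)
  th0 <- matrix(rgamma(60, 1), 3, 20); th0 <- th0 / rowSums(th0)
  perm <- c(3, 1, 2)
  f <- fit_gom(m, K = 3, init = list(q = q0, theta = th0), seed = 1, max_iter = 50)
  fp <- fit_gom(m, K = 3, init = list(q = q0[, perm], theta = th0[perm, ]),
                seed = 1, max_iter = 50)
  expect_equal(unname(fp$q), unname(f$q[, perm]), tolerance = 1e-10)
  expect_equal(unname(fp$theta), unname(f$theta[perm, ]), tolerance = 1e-10)
})

test_that("fit accessors expose tidy, glance, and serialization round trips", {
  m <- random_counts(10, 8, seed = 31)
  fit <- fit_gom(m, K = 2, seed = 3, max_iter = 100)
  td <- tidy(fit)
  expect_identical(names(td), c("sample_id", "cluster", "membership"))
  expect_identical(nrow(td), 20L)
  th <- tidy(fit, "theta")
  expect_identical(nrow(th), 16L)
  gl <- glance(fit)
  expect_identical(gl$K, 2L)
  expect_identical(gl$n_samples, 10L)
  dir <- withr::local_tempdir()
  write_gom_fit(fit, dir)
  back <- read_gom_fit(dir)
  expect_equal(back$q, fit$q, tolerance = 1e-12)
  expect_equal(back$theta, fit$theta, tolerance = 1e-12)
  expect_equal(back$log_likelihood, fit$log_likelihood)
  expect_equal(back$config$K, 2L)
})

test_that("degenerate configurations are rejected or warned about", {
  m <- random_counts(4, 3, seed = 51)
  expect_error(fit_gom(m, K = 0), "K must be")
  expect_warning(fit_gom(m, K = 4, seed = 1, max_iter = 20), "exceeds the number of genes")
  mz <- count_matrix(rbind(c(0, 0), c(1, 2)), allow_zero_rows = TRUE)
  expect_error(fit_gom(mz, K = 1), "zero total reads")
})
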