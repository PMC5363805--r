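test_that("steepest-fall split lands on the largest membership gap", {
  p <- steepest_fall_partition(c(0.95, 0.90, 0.15, 0.05))
  expect_setequal(p$block1, c(1, 2))
  expect_setequal(p$block2, c(3, 4))
  p2 <- steepest_fall_partition(c(1, 1, 0, 0))
  expect_setequal(p2$block1, c(1, 2))
  expect_warning(p3 <- steepest_fall_partition(rep(0.5, 4)), "degenerate")
  expect_length(p3$block1, 1)
  expect_length(p3$block2, 3)
  expect_error(steepest_fall_partition(0.5), "at least 2")
})

test_that("steepest-fall split is exhaustive-scan correct and affine invariant", {
  set.seed(12)
  for (i in 1:20) {
    v <- runif(15)
    p <- steepest_fall_partition(v)
    # oracle: scan every cut of the sorted sequence
    s <- sort(v, decreasing = TRUE)
    gaps <- s[-15] - s[-1]
    expect_identical(length(p$block1), as.integer(which.max(gaps)))
    expect_true(min(v[p$block1]) > max(v[p$block2]))
    # invariance to shift and positive rescale
    p_aff <- steepest_fall_partition(3 * v + 2)
    expect_identical(p_aff, p)
  }
})

test_that("alignment error is permutation-invariant and matches enumeration", {
  set.seed(3)
  q <- matrix(rgamma(30, 1), 10, 3); q <- q / rowSums(q)
  expect_equal(aligned_membership_error(q, q), 0)
  expect_equal(aligned_membership_error(q, q[, c(3, 1, 2)]), 0)
  q_true <- matrix(rep(c(1, 0), each = 5), 5, 2)
  q_est <- matrix(rep(c(0.9, 0.1), each = 5), 5, 2)
  expect_equal(aligned_membership_error(q_true, q_est), 0.1, tolerance = 1e-12)
  for (K in 2:5) {
    qa <- matrix(rgamma(8 * K, 1), 8, K); qa <- qa / rowSums(qa)
    qb <- matrix(rgamma(8 * K, 1), 8, K); qb <- qb / rowSums(qb)
    expect_equal(aligned_membership_error(qa, qb), aligned_error_oracle(qa, qb),
                 tolerance = 1e-14)
  }
  expect_error(aligned_membership_error(q, q[, 1:2]), "shape")
})

test_that("both methods separate well-separated groups and are seed-stable", {
  fx <- make_pair_fixture(delta = 1.5, n_per_group = 12, library_size = 5000,
                          G = 120, seed = 2)
  g1 <- suppressWarnings(
    gom_pair_separation(fx$counts, fx$labels, c("groupA", "groupB"),
                        n_sample = 20, seed = 11))
  expect_true(g1$success)
  expect_identical(g1$n_sampled, 20L)
  g2 <- suppressWarnings(
    gom_pair_separation(fx$counts, fx$labels, c("groupA", "groupB"),
                        n_sample = 20, seed = 11))
  expect_identical(g1$partition[[1]], g2$partition[[1]])
  h1 <- hclust_pair_separation(fx$counts, fx$labels, c("groupA", "groupB"),
                               n_sample = 20, seed = 11)
  expect_true(h1$success)
  h_avg <- hclust_pair_separation(fx$counts, fx$labels, c("groupA", "groupB"),
                                  n_sample = 20, seed = 11, linkage = "average")
  expect_identical(h_avg$method, "hclust_average")
  # partition covers the sampled ids exactly once
  part <- g1$partition[[1]]
  expect_identical(sort(part$sample_id), sort(part$sample_id[!duplicated(part$sample_id)]))
  expect_true(all(part$block %in% 1:2))
})

test_that("success is orientation-invariant in the label pair", {
  fx <- make_pair_fixture(delta = 1.5, n_per_group = 10, library_size = 5000,
                          G = 100, seed = 6)
  a <- suppressWarnings(gom_pair_separation(fx$counts, fx$labels,
                                            c("groupA", "groupB"), seed = 4))
  b <- suppressWarnings(gom_pair_separation(fx$counts, fx$labels,
                                            c("groupB", "groupA"), seed = 4))
  expect_identical(a$success, b$success)
})

test_that("identical-profile groups separate at roughly chance rates", {
  fx <- make_pair_fixture(delta = 0, n_per_group = 10, library_size = 1000,
                          G = 60, seed = 1)
  succ <- vapply(1:20, function(s) {
    suppressWarnings(
      gom_pair_separation(fx$counts, fx$labels, c("groupA", "groupB"),
                          n_sample = 16, seed = s, n_restarts = 1,
                          max_iter = 100))$success
  }, TRUE)
  expect_lt(mean(succ), 0.25)
})

test_that("the pairwise benchmark covers all pairs and summarizes per method", {
  # three mutually well-separated groups
  theta <- simulate_profiles(3, 120, delta = 1.5, seed = 5)
  parts <- lapply(1:3, function(k) {
    sim <- simulate_gom_counts(N = 12, G = 120, K = 1, library_sizes = 5000,
                               regime = "pure",
                               theta = theta[k, , drop = FALSE], seed = 40 + k)
    unclass(sim$counts)
  })
  x <- do.call(rbind, parts)
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  m <- count_matrix(x)
  labels <- tibble::tibble(sample_id = rownames(x),
                           label = rep(c("t1", "t2", "t3"), each = 12))
  bench <- suppressWarnings(
    pairwise_separation_matrix(m, labels, n_sample = 18, seed = 9,
                               n_restarts = 2, max_iter = 150))
  expect_identical(nrow(bench$results), 6L)         # 3 pairs x 2 methods
  gom_row <- bench$summary[bench$summary$method == "gom", ]
  expect_identical(gom_row$n_pairs, 3L)
  expect_equal(gom_row$success_fraction, 1.0)
  expect_error(pairwise_separation_matrix(m, labels[labels$label == "t1", ]),
               "at least 2")
  dir <- withr::local_tempdir()
  write_separation_results(bench, file.path(dir, "sep.tsv"),
                           file.path(dir, "sep.json"))
  back <- read.table(file.path(dir, "sep.tsv"), header = TRUE, sep = "\t")
  expect_identical(names(back), c("pair_a", "pair_b", "method", "success", "seed"))
  js <- jsonlite::read_json(file.path(dir, "sep.json"), simplifyVector = TRUE)
  expect_true("success_fraction" %in% names(js))
})
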