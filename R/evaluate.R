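#' Partition samples at the steepest fall of a membership vector
#'
#' Sorts the values descending and splits at the position with the largest
#' drop between consecutive sorted values — the rule for turning a K = 2
#' grade-of-membership fit into a hard two-group partition. Ties among
#' maximal gaps break at the first (highest-ranked) position; an all-equal
#' input yields a degenerate 1 vs n-1 split with a warning. The split is
#' invariant to adding a constant to all values and to positive rescaling.
#'
#' @param memberships numeric vector (length >= 2), e.g. cluster-1
#'   memberships of a K = 2 fit.
#' @return a list with integer index vectors `block1` (samples ranked above
#'   the gap, in descending membership order) and `block2` (the rest).
#' @examples
#' steepest_fall_partition(c(0.95, 0.90, 0.15, 0.05))
#' @export
steepest_fall_partition <- function(memberships) {
  n <- length(memberships)
  if (n < 2) abort("need at least 2 samples to partition")
  ord <- order(memberships, decreasing = TRUE)
  sorted <- memberships[ord]
  gaps <- sorted[-n] - sorted[-1]
  if (max(gaps) == 0) warn("all memberships equal; degenerate 1 vs n-1 split")
  cut <- which.max(gaps)                 # first maximal gap
  list(block1 = ord[seq_len(cut)], block2 = ord[(cut + 1):n])
}

# Draw a subsample of the pooled pair, redrawing (up to 20 times) any draw
# with < 2 samples from either label.
draw_pair_subsample <- function(labels, pair, n_sample, seed) {
  pool <- labels$sample_id[labels$label %in% pair]
  lab <- labels$label[match(pool, labels$sample_id)]
  if (length(unique(lab)) < 2 || any(table(lab) < 2)) {
    abort("need >= 2 samples per label in the pooled pair")
  }
  if (n_sample >= length(pool)) return(pool)
  set.seed(seed)
  for (attempt in 1:20) {
    ids <- sample(pool, n_sample)
    if (all(table(labels$label[match(ids, labels$sample_id)]) >= 2) &&
        length(unique(labels$label[match(ids, labels$sample_id)])) == 2) {
      return(ids)
    }
  }
  abort("could not draw a subsample with >= 2 samples per label in 20 attempts")
}

separation_result <- function(pair, method, ids, blocks, labels, seed) {
  lab <- labels$label[match(ids, labels$sample_id)]
  b1 <- ids[blocks$block1]
  groupA <- ids[lab == pair[1]]
  success <- setequal(b1, groupA) || setequal(b1, setdiff(ids, groupA))
  tibble::tibble(
    group_a = pair[1], group_b = pair[2], method = method,
    n_sampled = length(ids), success = success, seed = seed,
    partition = list(tibble::tibble(
      sample_id = ids,
      block = ifelse(ids %in% b1, 1L, 2L))))
}

#' Two-group separation trial with the grade-of-membership model
#'
#' Subsamples up to `n_sample` samples from the two labelled groups, fits a
#' K = 2 model on the raw counts, and splits the samples at the steepest
#' fall of their cluster-1 memberships. The trial succeeds iff the split
#' reproduces the two label groups exactly (either orientation).
#'
#' @param m a [count_matrix()].
#' @param labels tibble with `sample_id`, `label` covering the two groups.
#' @param pair character vector of the two labels to compare.
#' @param n_sample subsample size (all pooled samples if fewer).
#' @param seed integer seed (drives subsampling and the fit).
#' @param n_restarts,max_iter,tol passed to [fit_gom()].
#' @return a one-row tibble: `group_a`, `group_b`, `method`, `n_sampled`,
#'   `success`, `seed`, and a list-column `partition` of block assignments.
#' @export
gom_pair_separation <- function(m, labels, pair, n_sample = 50, seed = 1,
                                n_restarts = 3, max_iter = 200, tol = 1e-4) {
  stopifnot(is_count_matrix(m), length(pair) == 2)
  labels <- align_labels(labels, m)
  ids <- draw_pair_subsample(labels, pair, n_sample, seed)
  sub <- count_matrix(as_plain_matrix(m)[ids, , drop = FALSE])
  fit <- fit_gom(sub, K = 2, seed = seed, n_restarts = n_restarts,
                 max_iter = max_iter, tol = tol)
  blocks <- steepest_fall_partition(fit$q[, 1])
  separation_result(pair, "gom", ids, blocks, labels, seed)
}

#' Two-group separation trial with hierarchical clustering
#'
#' Same subsampling protocol as [gom_pair_separation()], but clusters the
#' samples by agglomerative hierarchical clustering on Euclidean distances
#' and cuts the dendrogram into two clusters. The default input is log-CPM
#' expression; raw counts and per-gene standardized log-CPM are available
#' as alternatives.
#'
#' @inheritParams gom_pair_separation
#' @param linkage `"complete"` (default) or `"average"`.
#' @param input `"log_cpm"` (default), `"raw"`, or `"standardized"`
#'   (log-CPM with per-gene zero mean / unit variance; constant genes
#'   dropped).
#' @return a one-row tibble as in [gom_pair_separation()].
#' @export
hclust_pair_separation <- function(m, labels, pair, n_sample = 50, seed = 1,
                                   linkage = c("complete", "average"),
                                   input = c("log_cpm", "raw", "standardized")) {
  stopifnot(is_count_matrix(m), length(pair) == 2)
  linkage <- match.arg(linkage)
  input <- match.arg(input)
  labels <- align_labels(labels, m)
  ids <- draw_pair_subsample(labels, pair, n_sample, seed)
  sub <- count_matrix(as_plain_matrix(m)[ids, , drop = FALSE])
  x <- switch(input,
              log_cpm = log_cpm(sub),
              raw = as_plain_matrix(sub) + 0,
              standardized = {
                lc <- log_cpm(sub)
                lc <- lc[, apply(lc, 2, stats::sd) > 0, drop = FALSE]
                scale(lc)
              })
  cl <- cutree(hclust(dist(x, method = "euclidean"), method = linkage), k = 2)
  blocks <- list(block1 = which(cl == 1L), block2 = which(cl == 2L))
  separation_result(pair, paste0("hclust_", linkage), ids, blocks, labels, seed)
}

#' Run the separation benchmark over all label pairs
#'
#' One trial per unordered label pair per method, each with a seed derived
#' deterministically from the global seed, plus per-method success
#' fractions. Pairs whose trial errors are recorded with `success = NA`,
#' excluded from the denominator, and flagged with a warning.
#'
#' @param m a [count_matrix()].
#' @param labels tibble with `sample_id`, `label` (>= 2 distinct labels).
#' @param methods subset of `c("gom", "hclust")`.
#' @param n_sample subsample size per trial.
#' @param seed global seed; pair i uses `seed + i`.
#' @param linkage,input passed to [hclust_pair_separation()].
#' @param ... passed to [gom_pair_separation()] (restart/iteration control).
#' @return a list with `results` (long tibble, one row per pair x method)
#'   and `summary` (tibble `method`, `n_pairs`, `n_success`,
#'   `success_fraction`).
#' @export
pairwise_separation_matrix <- function(m, labels, methods = c("gom", "hclust"),
                                       n_sample = 50, seed = 1,
                                       linkage = "complete", input = "log_cpm", ...) {
  methods <- match.arg(methods, c("gom", "hclust"), several.ok = TRUE)
  labs <- sort(unique(labels$label))
  if (length(labs) < 2) abort("need at least 2 distinct labels")
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  rows <- list()
  for (i in seq_along(pairs)) {
    pair <- pairs[[i]]
    pair_seed <- seed + i
    for (method in methods) {
      res <- tryCatch({
        if (method == "gom") {
          gom_pair_separation(m, labels, pair, n_sample = n_sample,
                              seed = pair_seed, ...)
        } else {
          hclust_pair_separation(m, labels, pair, n_sample = n_sample,
                                 seed = pair_seed, linkage = linkage, input = input)
        }
      }, error = function(e) {
        warn(sprintf("pair (%s, %s) failed for %s: %s",
                     pair[1], pair[2], method, conditionMessage(e)))
        tibble::tibble(group_a = pair[1], group_b = pair[2], method = method,
                       n_sampled = NA_integer_, success = NA, seed = pair_seed,
                       partition = list(NULL))
      })
      res$method <- method       # summarize gom vs hclust regardless of linkage tag
      rows[[length(rows) + 1L]] <- res
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(n_pairs = sum(!is.na(.data$success)),
                     n_success = sum(.data$success, na.rm = TRUE),
                     success_fraction = .data$n_success / .data$n_pairs,
                     .groups = "drop")
  list(results = results, summary = summary)
}

#' Write benchmark results to disk
#'
#' Long TSV `pair_a<TAB>pair_b<TAB>method<TAB>success<TAB>seed` plus a JSON
#' summary of per-method success fractions.
#'
#' @param bench output of [pairwise_separation_matrix()].
#' @param tsv_path,json_path output paths.
#' @export
write_separation_results <- function(bench, tsv_path, json_path = NULL) {
  tab <- bench$results |>
    dplyr::transmute(pair_a = .data$group_a, pair_b = .data$group_b,
                     method = .data$method, success = .data$success,
                     seed = .data$seed)
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(bench$summary, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}

#' Membership error after optimal cluster matching
#'
#' Mean absolute difference between two membership matrices, minimized over
#' all K! column permutations — cluster labels are arbitrary, so recovery
#' is scored up to relabelling.
#'
#' @param q_true,q_est N x K matrices of identical shape.
#' @return a non-negative scalar.
#' @export
aligned_membership_error <- function(q_true, q_est) {
  if (!all(dim(q_true) == dim(q_est))) abort("membership matrices differ in shape")
  K <- ncol(q_true)
  best <- Inf
  for (perm in all_permutations(K)) {
    err <- mean(abs(q_true - q_est[, perm, drop = FALSE]))
    if (err < best) best <- err
  }
  best
}
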