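#' Poisson Kullback-Leibler divergence between two rates
#'
#' KL divergence from Poisson(`a`) to Poisson(`b`):
#' `a * log(a / b) + b - a`. Non-negative, zero iff `a == b`, and
#' asymmetric in its arguments. Vectorized.
#'
#' @param a,b positive rates.
#' @return non-negative numeric.
#' @examples
#' poisson_kl(0.2, 0.1)
#' @export
poisson_kl <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) abort("poisson_kl requires strictly positive rates")
  a * log(a / b) + b - a
}

#' Score genes by how distinctively each cluster expresses them
#'
#' For every cluster k and gene g, the distinctiveness score is the minimum
#' over all other clusters l of the Poisson KL divergence between the
#' gene's rates `theta_kg` and `theta_lg`: a gene scores high for cluster k
#' only if its expression there differs substantially from the *closest*
#' other cluster. High-scoring genes are the "driving genes" of a cluster.
#'
#' Profile entries of exactly 0 are floored at `1e-12` with a warning (only
#' possible when the profile prior is user-forced to `alpha_theta = 1`);
#' the KL score is undefined at zero rates.
#'
#' @param theta a K x G profile matrix (rows sum to 1), or a `gom_fit`.
#' @return a tibble of class `driving_genes` with columns `cluster` (int),
#'   `gene_id`, `score`, and `rank` (1 = most distinctive; ties broken by
#'   ascending gene id), K x G rows.
#' @examples
#' th <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.6, 0.3), c(0.4, 0.4, 0.2))
#' colnames(th) <- paste0("gene", 1:3)
#' distinctiveness(th)
#' @export
distinctiveness <- function(theta) {
  if (inherits(theta, "gom_fit")) theta <- theta$theta
  K <- nrow(theta); G <- ncol(theta)
  if (K < 2) abort("distinctiveness undefined for a single cluster (K = 1)")
  if (any(theta == 0)) {
    warn("theta contains exact zeros; flooring at 1e-12 before KL scoring")
    theta[theta == 0] <- 1e-12
  }
  gene_ids <- colnames(theta) %||% paste0("gene_", seq_len(G))
  scores <- matrix(Inf, K, G)
  for (l in seq_len(K)) {
    # KL of every row against row l, vectorized over the K x G grid
    kl_l <- theta * log(theta / matrix(theta[l, ], K, G, byrow = TRUE)) +
      matrix(theta[l, ], K, G, byrow = TRUE) - theta
    kl_l[l, ] <- Inf                      # exclude l = k from the minimum
    scores <- pmin(scores, kl_l)
  }
  out <- tibble::tibble(
    cluster = rep(seq_len(K), each = G),
    gene_id = rep(gene_ids, times = K),
    score = as.vector(t(scores))) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene_id, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  class(out) <- c("driving_genes", class(out))
  out
}

#' Top driving genes of one cluster
#'
#' @param table a `driving_genes` tibble from [distinctiveness()].
#' @param k cluster index.
#' @param n how many genes (1..G).
#' @return a tibble with the first `n` rows of cluster k's ranking.
#' @export
top_driving_genes <- function(table, k, n = 100) {
  ks <- unique(table$cluster)
  if (!k %in% ks) abort(sprintf("cluster index %s out of range (1..%d)", k, max(ks)))
  G <- sum(table$cluster == k)
  stopifnot(n >= 1, n <= G)
  table |>
    dplyr::filter(.data$cluster == k, .data$rank <= n) |>
    dplyr::arrange(.data$rank)
}

#' Export driving-gene rankings
#'
#' Writes a long TSV `cluster<TAB>rank<TAB>gene_id<TAB>score` and, when
#' `top_n` is given, one plain-text id list per cluster
#' (`cluster<k>_top<n>.txt`) for pasting into external enrichment tools.
#'
#' @param table a `driving_genes` tibble.
#' @param path output TSV path.
#' @param top_n optional truncation for the per-cluster id lists.
#' @return `path`, invisibly.
#' @export
write_driving_genes <- function(table, path, top_n = NULL) {
  utils::write.table(table[, c("cluster", "rank", "gene_id", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(top_n)) {
    dir <- dirname(path)
    for (k in unique(table$cluster)) {
      ids <- top_driving_genes(table, k, min(top_n, sum(table$cluster == k)))$gene_id
      writeLines(ids, file.path(dir, sprintf("cluster%d_top%d.txt", k, length(ids))))
    }
  }
  invisible(path)
}
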