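#' Filter genes by total count and prevalence
#'
#' Keeps genes whose column total is at least `min_total` and which have a
#' nonzero count in at least `min_samples_expressed` samples. A generic
#' minimum-expression filter; the sample set is never changed. Idempotent.
#'
#' @param m a [count_matrix()].
#' @param min_total minimum column total (reads summed over samples).
#' @param min_samples_expressed minimum number of samples with a nonzero count.
#' @return a `count_matrix` restricted to the surviving genes.
#' @export
filter_genes <- function(m, min_total = 0, min_samples_expressed = 0) {
  stopifnot(is_count_matrix(m), min_total >= 0, min_samples_expressed >= 0)
  x <- as_plain_matrix(m)
  keep <- colSums(x) >= min_total & colSums(x > 0) >= min_samples_expressed
  if (!any(keep)) {
    abort("all genes removed by filter; reduce min_total / min_samples_expressed")
  }
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(sprintf("filter_genes: removed %d of %d genes", n_removed, ncol(x)))
  }
  count_matrix(x[, keep, drop = FALSE])
}

#' Log counts-per-million transform
#'
#' Computes `log2(1 + 1e6 * c_ng / c_n+)` per entry, removing library-size
#' effects. Used as input to hierarchical clustering and external embeddings;
#' zero counts map to exactly 0.
#'
#' @param m a [count_matrix()].
#' @return a numeric samples-by-genes matrix (dimnames preserved).
#' @export
log_cpm <- function(m) {
  stopifnot(is_count_matrix(m))
  rt <- row_totals(m)
  if (any(rt == 0)) {
    abort(paste0("zero total reads for sample(s): ",
                 paste(rownames(m)[rt == 0], collapse = ", ")))
  }
  log2(1 + 1e6 * as_plain_matrix(m) / rt)
}
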