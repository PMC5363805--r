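#' Binomial thinning of a count matrix
#'
#' Simulates lower sequencing depth: each entry is replaced by an
#' independent draw `t_ng ~ Binomial(c_ng, p_thin)`, so a retention
#' probability of 0.01 emulates a 100-fold shallower library.
#'
#' Reproducibility contract: one global seed drives a single random stream
#' consumed in fixed row-major entry order, and zero entries do not consume
#' draws. The thinned matrix therefore depends only on `(m, p_thin, seed)`,
#' never on storage layout.
#'
#' @param m a [count_matrix()].
#' @param p_thin per-read retention probability in \[0, 1\].
#' @param seed integer seed.
#' @return a `count_matrix` of thinned counts with recomputed row totals;
#'   `t_ng <= c_ng` everywhere. Samples emptied by thinning are kept (with
#'   a warning) but must be dropped before model fitting.
#' @examples
#' m <- count_matrix(matrix(100, 2, 3))
#' thin_counts(m, p_thin = 0.5, seed = 1)
#' @export
thin_counts <- function(m, p_thin, seed = 1) {
  stopifnot(is_count_matrix(m))
  if (!is.numeric(p_thin) || length(p_thin) != 1 || p_thin < 0 || p_thin > 1) {
    abort("p_thin must be a single probability in [0, 1]")
  }
  v <- as.vector(t(as_plain_matrix(m)))   # row-major entry order
  nz <- v > 0
  out <- v
  set.seed(seed)
  out[nz] <- rbinom(sum(nz), size = v[nz], prob = p_thin)
  thinned <- t(matrix(out, nrow = ncol(m), ncol = nrow(m)))
  dimnames(thinned) <- dimnames(m)
  if (any(rowSums(thinned) == 0)) {
    warn(sprintf("thinning left %d sample(s) with zero reads; drop them before fitting",
                 sum(rowSums(thinned) == 0)))
  }
  count_matrix(thinned, allow_zero_rows = TRUE)
}
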