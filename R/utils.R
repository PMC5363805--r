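#' @importFrom stats rbinom rgamma rmultinom hclust cutree dist setNames runif
#' @importFrom utils head packageVersion
#' @importFrom rlang .data abort warn
NULL

#' Draw rows from a Dirichlet distribution
#'
#' @param n number of draws.
#' @param alpha concentration vector; recycled scalars allowed via `len`.
#' @param len length of the probability vector when `alpha` is scalar.
#' @return an `n x len` matrix whose rows sum to 1.
#' @keywords internal
rdirichlet <- function(n, alpha, len = length(alpha)) {
  if (length(alpha) == 1L) alpha <- rep(alpha, len)
  x <- matrix(rgamma(n * len, shape = alpha, rate = 1), nrow = n, byrow = TRUE)
  # guard against all-zero rows at tiny concentrations
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, ] <- 1 / len
  x / rowSums(x)
}

#' All permutations of 1..k
#' @keywords internal
all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Normalize rows of a matrix to sum to 1
#' @keywords internal
row_normalize <- function(x) {
  s <- rowSums(x)
  bad <- !is.finite(s) | s <= 0
  if (any(bad)) {
    warn(sprintf("%d row(s) had zero/non-finite mass; reset to uniform", sum(bad)))
    x[bad, ] <- 1
    s[bad] <- ncol(x)
  }
  x / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
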