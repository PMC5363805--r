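#' Construct a validated count matrix
#'
#' The central data container: a samples-by-genes matrix of non-negative
#' integer read counts, with unique sample ids as rownames and unique gene
#' ids as colnames. Per-sample totals (library sizes) are the row sums.
#'
#' Non-integer entries within `1e-9` of an integer are rounded; anything
#' further from an integer, any negative entry, duplicated ids, or (by
#' default) a sample with zero total reads is rejected — the multinomial
#' likelihood is defined on integer counts and undefined for an empty
#' library. `allow_zero_rows = TRUE` admits empty samples; this arises
#' legitimately only downstream of aggressive thinning, and such samples
#' must be dropped before fitting.
#'
#' @param counts numeric matrix (samples x genes) of non-negative integers.
#' @param sample_ids,gene_ids optional character vectors overriding dimnames.
#' @param allow_zero_rows admit samples with zero total reads?
#' @return an integer matrix of class `count_matrix` with dimnames set.
#' @examples
#' m <- count_matrix(rbind(s1 = c(g1 = 3, g2 = 1), s2 = c(1, 3)))
#' row_totals(m)
#' @export
count_matrix <- function(counts, sample_ids = NULL, gene_ids = NULL,
                         allow_zero_rows = FALSE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) abort("counts must be a numeric matrix")
  if (is.null(sample_ids)) sample_ids <- rownames(counts) %||% paste0("sample_", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- colnames(counts) %||% paste0("gene_", seq_len(ncol(counts)))
  if (length(sample_ids) != nrow(counts) || length(gene_ids) != ncol(counts)) {
    abort("sample_ids / gene_ids do not match matrix dimensions")
  }
  if (anyDuplicated(sample_ids)) abort("duplicate sample identifiers")
  if (anyDuplicated(gene_ids)) abort("duplicate gene identifiers")
  if (anyNA(counts)) abort("counts contain missing values")
  if (any(counts < 0)) abort("counts contain negative entries")
  rounded <- round(counts)
  if (any(abs(counts - rounded) > 1e-9)) {
    abort("counts contain non-integer entries (beyond 1e-9 rounding tolerance)")
  }
  storage.mode(rounded) <- if (max(rounded) <= .Machine$integer.max) "integer" else "double"
  dimnames(rounded) <- list(sample_ids, gene_ids)
  rt <- rowSums(rounded)
  if (!allow_zero_rows && any(rt == 0)) {
    abort(paste0("sample(s) with zero total reads: ",
                 paste(sample_ids[rt == 0], collapse = ", ")))
  }
  structure(rounded, class = c("count_matrix", class(rounded)))
}

#' Per-sample read totals (library sizes)
#' @param m a `count_matrix`.
#' @return named numeric vector of row sums.
#' @export
row_totals <- function(m) rowSums(unclass(m))

#' @method print count_matrix
#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d samples x %d genes; library sizes %s..%s\n",
              nrow(x), ncol(x),
              format(min(row_totals(x))), format(max(row_totals(x)))))
  invisible(x)
}

#' Test whether an object is a valid count matrix
#' @param x object to test.
#' @export
is_count_matrix <- function(x) inherits(x, "count_matrix")

as_plain_matrix <- function(m) {
  x <- unclass(m)
  attr(x, "class") <- NULL
  x
}
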