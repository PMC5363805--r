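#' Serialize a fitted model to a directory
#'
#' Writes `q.tsv` and `theta.tsv` (labeled rows and columns, full double
#' precision) plus `fit.json` holding the config, seeds, log-posterior
#' trace, and convergence flags — everything needed to reload or audit the
#' fit.
#'
#' @param fit a `gom_fit`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_gom_fit <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_named_matrix <- function(x, path, rowname_col) {
    df <- data.frame(rn = rownames(x), format(x, digits = 17, trim = TRUE,
                                              scientific = TRUE),
                     check.names = FALSE)
    names(df)[1] <- rowname_col
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_named_matrix(fit$q, file.path(dir, "q.tsv"), "sample_id")
  write_named_matrix(fit$theta, file.path(dir, "theta.tsv"), "cluster")
  meta <- fit[c("log_likelihood", "log_posterior_trace", "converged", "n_iter",
                "restart_index", "seed_used", "restart_log_likelihoods", "config")]
  jsonlite::write_json(meta, file.path(dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a fitted model written by [write_gom_fit()]
#'
#' @param dir directory containing `q.tsv`, `theta.tsv`, `fit.json`.
#' @return a `gom_fit`.
#' @export
read_gom_fit <- function(dir) {
  read_named_matrix <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE, comment.char = "")
    as.matrix(df)
  }
  q <- read_named_matrix(file.path(dir, "q.tsv"))
  theta <- read_named_matrix(file.path(dir, "theta.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "fit.json"), simplifyVector = TRUE)
  structure(c(list(q = q, theta = theta), meta), class = "gom_fit")
}
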