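#' Read a count matrix from disk
#'
#' Supports three on-disk layouts:
#' \describe{
#'   \item{dense-tsv / dense-csv}{first row gene ids, first column sample ids,
#'     samples-by-genes orientation.}
#'   \item{mtx-triplet}{Matrix Market coordinate format (1-based indices,
#'     header line required) storing genes implicitly by index, with sidecar
#'     files `genes.tsv` and `samples.tsv` (one id per line) in the same
#'     directory. Matrix Market files are conventionally genes-by-samples
#'     (rows = genes); that orientation is used here.}
#' }
#'
#' @param path file path.
#' @param format one of `"dense-tsv"`, `"dense-csv"`, `"mtx-triplet"`.
#'   Default guesses from the file extension.
#' @return a validated [count_matrix()].
#' @export
read_counts <- function(path, format = c("auto", "dense-tsv", "dense-csv", "mtx-triplet")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "dense-tsv", txt = "dense-tsv",
                     csv = "dense-csv", mtx = "mtx-triplet",
                     abort(sprintf("cannot guess format from extension of '%s'", path)))
  }
  if (format == "mtx-triplet") {
    dir <- dirname(path)
    genes_f <- file.path(dir, "genes.tsv")
    samples_f <- file.path(dir, "samples.tsv")
    if (!file.exists(genes_f) || !file.exists(samples_f)) {
      abort("mtx-triplet requires 'genes.tsv' and 'samples.tsv' sidecars alongside the .mtx file")
    }
    mm <- tryCatch(Matrix::readMM(path),
                   error = function(e) abort(sprintf("malformed Matrix Market file '%s': %s",
                                                     path, conditionMessage(e))))
    genes <- readLines(genes_f)
    samples <- readLines(samples_f)
    if (nrow(mm) != length(genes) || ncol(mm) != length(samples)) {
      abort(sprintf("mtx dimensions %dx%d do not match sidecars (%d genes, %d samples)",
                    nrow(mm), ncol(mm), length(genes), length(samples)))
    }
    dense <- t(as.matrix(mm))           # genes x samples on disk -> samples x genes
    return(count_matrix(dense, sample_ids = samples, gene_ids = genes))
  }
  sep <- if (format == "dense-tsv") "\t" else ","
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                      check.names = FALSE, comment.char = ""),
    error = function(e) abort(sprintf("parse error in '%s': %s", path, conditionMessage(e))))
  count_matrix(as.matrix(df))
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]; `read_counts(write_counts(m, p), fmt)` returns
#' a matrix identical to `m` for every supported format.
#'
#' @param m a [count_matrix()].
#' @param path output file path (for mtx-triplet, sidecars are written next to it).
#' @param format as in [read_counts()] (no `"auto"`).
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, format = c("dense-tsv", "dense-csv", "mtx-triplet")) {
  format <- match.arg(format)
  stopifnot(is_count_matrix(m))
  if (format == "mtx-triplet") {
    dir <- dirname(path)
    sp <- Matrix::Matrix(t(as_plain_matrix(m)), sparse = TRUE)  # genes x samples
    Matrix::writeMM(sp, path)
    writeLines(colnames(m), file.path(dir, "genes.tsv"))
    writeLines(rownames(m), file.path(dir, "samples.tsv"))
    return(invisible(path))
  }
  sep <- if (format == "dense-tsv") "\t" else ","
  df <- data.frame(sample_id = rownames(m), as_plain_matrix(m), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample group labels
#'
#' Two-column TSV `sample_id<TAB>label`; a header line is detected and
#' skipped when its first field is `sample_id`.
#'
#' @param path file path.
#' @param m optional `count_matrix`; when given, every sample id in the file
#'   must appear in `m` and labels are returned in the order of `m`'s samples.
#' @return a tibble with columns `sample_id`, `label`.
#' @export
read_labels <- function(path, m = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("sample_id", "label"),
                           colClasses = "character", comment.char = "")
  if (nrow(raw) > 0 && raw$sample_id[1] == "sample_id") raw <- raw[-1, , drop = FALSE]
  out <- tibble::as_tibble(raw)
  if (!is.null(m)) out <- align_labels(out, m)
  out
}

#' Write labels as two-column TSV
#' @param labels tibble with `sample_id`, `label`.
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels[, c("sample_id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Validate label coverage against a count matrix and align row order.
align_labels <- function(labels, m) {
  stopifnot(is_count_matrix(m))
  unknown <- setdiff(labels$sample_id, rownames(m))
  if (length(unknown)) {
    abort(paste0("labels refer to unknown sample(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  missing <- setdiff(rownames(m), labels$sample_id)
  if (length(missing)) {
    abort(paste0("labels missing for sample(s): ", paste(head(missing, 5), collapse = ", ")))
  }
  labels[match(rownames(m), labels$sample_id), , drop = FALSE]
}
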