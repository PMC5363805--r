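# Fixed qualitative palette (20 colors). Larger K needs a custom palette:
# stacked bars with more than ~20 colors stop being readable.
structure_palette_20 <- c(
  "#1F77B4", "#FF7F0E", "#2CA02C", "#D62728", "#9467BD",
  "#8C564B", "#E377C2", "#7F7F7F", "#BCBD22", "#17BECF",
  "#AEC7E8", "#FFBB78", "#98DF8A", "#FF9896", "#C5B0D5",
  "#C49C94", "#F7B6D2", "#C7C7C7", "#DBDB8D", "#9EDAE5")

#' Order samples for a Structure plot
#'
#' Arranges samples so that each label group occupies one contiguous block
#' (groups in `group_order`, default sorted label order). Within a group,
#' the cluster with the highest mean membership in that group is identified
#' and the group's samples are sorted by that cluster's membership,
#' descending, with stable ties — producing the within-group gradient that
#' makes mixed membership visible.
#'
#' @param fit a `gom_fit`.
#' @param labels tibble with `sample_id`, `label` covering all samples.
#' @param group_order optional character vector of labels.
#' @return a tibble of class `structure_ordering` with columns `position`,
#'   `sample_id`, `label`, `sort_cluster`; attribute `group_boundaries`
#'   holds the first position of each group block, attribute `palette` the
#'   cluster colors.
#' @export
structure_order <- function(fit, labels, group_order = NULL) {
  q <- fit$q
  K <- ncol(q)
  if (K > length(structure_palette_20)) {
    abort(sprintf("K = %d exceeds the built-in 20-color palette; supply a custom palette", K))
  }
  ids <- rownames(q)
  lab <- labels$label[match(ids, labels$sample_id)]
  if (anyNA(lab)) abort("labels do not cover all fitted samples")
  groups <- group_order %||% sort(unique(lab))
  unknown <- setdiff(groups, lab)
  if (length(unknown)) abort(paste0("unknown label(s) in group_order: ",
                                    paste(unknown, collapse = ", ")))
  rows <- list()
  for (g in groups) {
    in_g <- which(lab == g)
    dom <- which.max(colMeans(q[in_g, , drop = FALSE]))
    ord <- in_g[order(-q[in_g, dom], seq_along(in_g))]   # stable descending
    rows[[g]] <- tibble::tibble(sample_id = ids[ord], label = g,
                                sort_cluster = as.integer(dom))
  }
  out <- dplyr::bind_rows(rows)
  out$position <- seq_len(nrow(out))
  out <- out[, c("position", "sample_id", "label", "sort_cluster")]
  attr(out, "group_boundaries") <- match(unique(out$label), out$label)
  attr(out, "palette") <- structure_palette_20[seq_len(K)]
  class(out) <- c("structure_ordering", class(out))
  out
}

#' Build a Structure plot
#'
#' One horizontal stacked bar per sample: segment lengths are the sample's
#' membership proportions (summing to 1), colors identify clusters, and
#' samples sharing a label form contiguous blocks separated by facets.
#'
#' @param fit a `gom_fit`.
#' @param ordering a `structure_ordering` from [structure_order()]; when
#'   `NULL`, all samples form one unlabelled block in input order.
#' @return a ggplot object.
#' @export
plot_structure <- function(fit, ordering = NULL) {
  q <- fit$q
  K <- ncol(q)
  if (is.null(ordering)) {
    ordering <- tibble::tibble(position = seq_len(nrow(q)),
                               sample_id = rownames(q), label = "all")
    attr(ordering, "palette") <- structure_palette_20[seq_len(K)]
  }
  pal <- attr(ordering, "palette") %||% structure_palette_20[seq_len(K)]
  df <- tidy.gom_fit(fit, "q") |>
    dplyr::inner_join(ordering[, c("position", "sample_id", "label")],
                      by = "sample_id") |>
    dplyr::mutate(cluster = factor(.data$cluster, levels = seq_len(K)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$membership,
                                   y = stats::reorder(.data$sample_id, -.data$position),
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1, position = ggplot2::position_stack(reverse = TRUE)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$label), scales = "free_y",
                        space = "free_y", switch = "y") +
    ggplot2::scale_fill_manual(values = pal, name = "cluster") +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = "membership proportion", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank(),
                   strip.text.y.left = ggplot2::element_text(angle = 0),
                   panel.spacing.y = ggplot2::unit(2, "pt"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Structure plot via the autoplot generic
#' @param object a `gom_fit`.
#' @param labels optional tibble with `sample_id`, `label` for grouping.
#' @param ... passed to [structure_order()].
#' @export
autoplot.gom_fit <- function(object, labels = NULL, ...) {
  ordering <- if (is.null(labels)) NULL else structure_order(object, labels, ...)
  plot_structure(object, ordering)
}

#' Render a Structure plot to a file
#'
#' @param fit a `gom_fit`.
#' @param ordering a `structure_ordering` (or `NULL`, see [plot_structure()]).
#' @param path output file; format from `format` or the file extension
#'   (`svg`, `png`, `pdf`).
#' @param format output device; `"auto"` uses the extension.
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
structure_plot_file <- function(fit, ordering, path,
                                format = c("auto", "svg", "png", "pdf"),
                                width = 7, height = 5) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("svg", "png", "pdf")) {
      abort(sprintf("cannot infer figure format from '%s'", path))
    }
  }
  if (!dir.exists(dirname(path))) abort(sprintf("directory does not exist: %s", dirname(path)))
  p <- plot_structure(fit, ordering)
  switch(format,
         svg = grDevices::svg(path, width = width, height = height),
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(path, width = width, height = height))
  print(p)
  grDevices::dev.off()
  invisible(path)
}

#' Export membership proportions for external embedding tools
#'
#' Writes `q` as a TSV with header `sample_id`, `cluster_1` .. `cluster_K`
#' — the coordinates external 2-D embedding tools (t-SNE, PCA) consume;
#' the embedding itself is delegated to those tools.
#'
#' @param fit a `gom_fit`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_membership_coordinates <- function(fit, path) {
  df <- data.frame(sample_id = rownames(fit$q), fit$q, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
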