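# Plots: per-phenotype expression ranges (points = phenotype mean, bars =
# maximal expression interval) and an OFC overview of the DE results.

#' Plot normalized expression intervals per phenotype
#'
#' One panel per miRNA: the phenotype mean of normalized counts with an
#' error bar spanning the maximal expression interval (replicate min to max)
#' over the included libraries.
#'
#' @param norm_counts Long tibble with `mirna`, `library_id`, `norm_count`.
#' @param sample_sheet Tibble with `library_id` and `phenotype`.
#' @param mirnas miRNAs to show (default: all, alphabetically).
#' @param qualities Optional screen result; excluded libraries are dropped.
#' @return A ggplot object.
#' @export
plot_expression_intervals <- function(norm_counts, sample_sheet,
                                      mirnas = NULL, qualities = NULL) {
  keep <- sample_sheet$library_id
  if (!is.null(qualities)) {
    keep <- setdiff(keep, qualities$library_id[qualities$excluded])
  }
  x <- norm_counts %>%
    dplyr::filter(.data$library_id %in% keep) %>%
    dplyr::inner_join(sample_sheet[, c("library_id", "phenotype")],
                      by = "library_id")
  if (!is.null(mirnas)) x <- dplyr::filter(x, .data$mirna %in% mirnas)
  stats <- x %>%
    dplyr::group_by(.data$mirna, .data$phenotype) %>%
    dplyr::summarise(mean = mean(.data$norm_count),
                     lo = min(.data$norm_count), hi = max(.data$norm_count),
                     .groups = "drop")
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$phenotype, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey80", colour = "grey30") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.25) +
    ggplot2::facet_wrap(~mirna, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "normalized read count") +
    ggplot2::theme_bw()
}

#' Plot a `mir_de` result as an OFC overview
#'
#' Shows the signed log2 offset fold change of the top-ranked miRNAs of each
#' comparison, DE calls highlighted.
#'
#' @param object A `mir_de` object from [run_comparisons()].
#' @param n_top Number of top-|ofc| miRNAs per comparison.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mir_de <- function(object, n_top = 10, ...) {
  top <- object$results %>%
    dplyr::group_by(.data$comparison) %>%
    dplyr::slice_max(abs(.data$ofc), n = n_top, with_ties = FALSE) %>%
    dplyr::ungroup()
  ggplot2::ggplot(top, ggplot2::aes(
    x = stats::reorder(.data$mirna, abs(.data$ofc)), y = .data$ofc,
    fill = .data$de)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-object$params$ofc_threshold,
                                       object$params$ofc_threshold),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~comparison, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "grey70"),
                               name = "DE call") +
    ggplot2::labs(x = NULL, y = expression(log[2] * "(OFC)")) +
    ggplot2::theme_bw()
}
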