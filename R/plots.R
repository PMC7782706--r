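# ggplot2 displays for the main result types

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_text geom_col geom_vline geom_hline labs scale_fill_gradient2
#'   scale_fill_viridis_c theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Volcano plot of a differential-expression table
#' @param object A `de_table` from [differential_expression()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.de_table <- function(object, ...) {
  ggplot(object, aes(x = .data$logfd, y = -log10(.data$fdr),
                     colour = .data$de_flag)) +
    geom_point(alpha = 0.7) +
    geom_vline(xintercept = c(-1, 1), linetype = "dashed") +
    geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    labs(x = "log2 fold difference", y = "-log10 FDR",
         colour = "DE") +
    theme_minimal()
}

#' Confusion-matrix heatmap with counts
#' @param object A `pv_confusion` from [confusion_matrix()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pv_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$col_label, y = .data$row_label,
                 fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n)) +
    scale_fill_viridis_c() +
    labs(x = NULL, y = NULL, fill = "cells") +
    theme_minimal()
}

#' Similarity-matrix heatmap
#' @param object A `pv_similarity` from [cam_similarity()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pv_similarity <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$type_a, y = .data$type_b,
                 fill = .data$similarity)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$similarity))) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "mean r") +
    theme_minimal()
}

#' F-I curve with fitted working points
#' @param object A `fi_curve` from [fi_curve()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.fi_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$i_pa, y = .data$freq_hz)) +
    geom_line() + geom_point() +
    labs(x = "injected current (pA)", y = "firing rate (Hz)") +
    theme_minimal()
}

#' Per-repeat accuracy distribution of the balanced RF protocol
#' @param object A `pv_rf_accuracy` from [balanced_rf_accuracy()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pv_rf_accuracy <- function(object, ...) {
  df <- tibble::tibble(repeat_id = seq_along(object$per_repeat),
                       accuracy = object$per_repeat)
  ggplot(df, aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    geom_vline(xintercept = 0.5, linetype = "dashed") +
    geom_vline(xintercept = object$overall_accuracy, colour = "red") +
    labs(x = "test-set accuracy per repeat", y = "repeats") +
    theme_minimal()
}

#' Binary-expression heatmap of detected transition genes
#'
#' Cells (columns) ordered by age, detected genes (rows) ordered by
#' transition day, coloured by the binary expressed state.
#'
#' @param transitions A `transition_table` from [detect_transitions()].
#' @param ds The `pv_dataset` the table was computed from.
#' @param cutoff_tpm Binarization cutoff (default taken from the table).
#' @return A ggplot.
#' @export
plot_transition_heatmap <- function(transitions, ds,
                                    cutoff_tpm = attr(transitions, "cutoff_tpm") %||% 0.6) {
  stopifnot(inherits(transitions, "transition_table"),
            inherits(ds, "pv_dataset"))
  if (!nrow(transitions)) abort("no detected transitions to plot")
  ord <- order(ds$meta$age_days)
  bx <- binarize(ds, cutoff_tpm)[transitions$gene, ord, drop = FALSE]
  df <- tibble::as_tibble(as.table(bx * 1), .name_repair = "minimal") |>
    stats::setNames(c("gene", "cell_id", "expressed"))
  df$gene <- factor(df$gene, levels = rev(transitions$gene))
  df$cell_id <- factor(df$cell_id, levels = ds$meta$cell_id[ord])
  ggplot(df, aes(x = .data$cell_id, y = .data$gene,
                 fill = factor(.data$expressed))) +
    geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey90", `1` = "firebrick"),
                               labels = c("off", "on")) +
    labs(x = "cells (ordered by age)", y = NULL, fill = "expressed") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
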