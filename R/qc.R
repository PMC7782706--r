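#' Robust cell-level quality control
#'
#' Flags cells whose library metrics fall more than three (unscaled) median
#' absolute deviations below the cohort median. Two metrics are used: the
#' number of unique genes detected and the number of aligned reads; a cell
#' fails if *either* metric is below its threshold.
#'
#' @param counts A data frame with columns `cell_id`, `unique_gene_count`,
#'   `aligned_read_count` (one row per cell; at least 3 cells).
#' @param n_mads Number of MADs below the median that defines failure
#'   (default 3).
#' @return A `qc_report`: tibble with per-cell metrics and `pass`, carrying
#'   the thresholds as attributes (`thresholds`, a named vector).
#' @export
qc_filter <- function(counts, n_mads = 3) {
  counts <- tibble::as_tibble(counts)
  needed <- c("cell_id", "unique_gene_count", "aligned_read_count")
  if (!all(needed %in% names(counts))) {
    abort(paste0("counts must have columns: ", paste(needed, collapse = ", ")))
  }
  if (nrow(counts) < 3) abort("qc_filter needs at least 3 cells to define thresholds")
  thr_gene <- stats::median(counts$unique_gene_count) -
    n_mads * mad_unscaled(counts$unique_gene_count)
  thr_read <- stats::median(counts$aligned_read_count) -
    n_mads * mad_unscaled(counts$aligned_read_count)
  out <- dplyr::mutate(
    counts,
    pass_genes = .data$unique_gene_count >= thr_gene,
    pass_reads = .data$aligned_read_count >= thr_read,
    pass = .data$pass_genes & .data$pass_reads)
  structure(out,
            thresholds = c(unique_gene_count = thr_gene,
                           aligned_read_count = thr_read,
                           n_mads = n_mads),
            class = c("qc_report", class(out)))
}

#' Library metrics for QC from an expression matrix
#'
#' Computes the unique-gene count (genes with TPM > 0) per cell and, because
#' aligned-read counts are not recoverable from a TPM matrix, uses total TPM
#' mass as a stand-in for the read metric (flagged in the output attribute
#' `read_metric`).
#'
#' @param ds A `pv_dataset` or genes x cells matrix.
#' @return Tibble with `cell_id`, `unique_gene_count`, `aligned_read_count`.
#' @export
qc_metrics <- function(ds) {
  expr <- if (inherits(ds, "pv_dataset")) ds$expr else ds
  assert_expression_matrix(expr)
  out <- tibble::tibble(
    cell_id = colnames(expr),
    unique_gene_count = colSums(expr > 0),
    aligned_read_count = colSums(expr))
  attr(out, "read_metric") <- "total_tpm_mass (proxy; aligned reads unavailable)"
  out
}

#' @export
glance.qc_report <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble::tibble(n_cells = nrow(x), n_pass = sum(x$pass),
                 n_fail = sum(!x$pass),
                 threshold_genes = thr[["unique_gene_count"]],
                 threshold_reads = thr[["aligned_read_count"]],
                 n_mads = thr[["n_mads"]])
}
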