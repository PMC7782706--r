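#' Expression gate for differential testing
#'
#' Keeps genes expressed at TPM strictly above `min_tpm` in at least
#' `min_cells` cells, pooled over the two groups being compared.
#'
#' @param ds A `pv_dataset`.
#' @param group_a,group_b Character vectors of cell ids (disjoint, nonempty).
#' @param min_tpm Expression threshold (strict `>`; default 15).
#' @param min_cells Minimum number of pooled cells above threshold
#'   (default 5).
#' @return Tibble with `gene`, `n_above` for the genes passing the gate,
#'   ordered as in the matrix.
#' @export
feature_gate <- function(ds, group_a, group_b, min_tpm = 15, min_cells = 5) {
  stopifnot(inherits(ds, "pv_dataset"))
  check_groups(ds, group_a, group_b)
  pooled <- ds$expr[, c(group_a, group_b), drop = FALSE]
  n_above <- rowSums(pooled > min_tpm)
  keep <- n_above >= min_cells
  tibble::tibble(gene = rownames(pooled)[keep], n_above = n_above[keep])
}

check_groups <- function(ds, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) abort("both groups must be nonempty")
  if (length(intersect(group_a, group_b))) abort("groups must be disjoint")
  missing <- setdiff(c(group_a, group_b), colnames(ds$expr))
  if (length(missing)) {
    abort(paste0("cell id(s) absent from dataset: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Two-group differential expression with fold-change gating
#'
#' Runs a pluggable two-sample test per gene on the gated gene set and
#' labels genes as differentially expressed when the fold difference exceeds
#' 2 (|log2 fold difference| > 1) at Benjamini-Hochberg FDR < 0.05. The
#' default test is a two-sided rank-sum (Wilcoxon) test on log2(TPM + 1);
#' `welch_log` uses Welch's t test on the same scale. The log2 fold
#' difference uses a 1 TPM pseudo-value: `log2((mean_a + 1)/(mean_b + 1))`
#' on linear-TPM group means.
#'
#' @inheritParams feature_gate
#' @param test `"rank_sum"` (default) or `"welch_log"`.
#' @param fdr_cutoff,logfd_cutoff Gates for `de_flag` (defaults 0.05, 1).
#' @return A `de_table`: tibble with `gene`, `mean_a`, `mean_b`, `logfd`,
#'   `p`, `fdr`, `de_flag`, sorted by `fdr` then `p`.
#' @export
differential_expression <- function(ds, group_a, group_b,
                                    test = c("rank_sum", "welch_log"),
                                    min_tpm = 15, min_cells = 5,
                                    fdr_cutoff = 0.05, logfd_cutoff = 1) {
  test <- match.arg(test)
  stopifnot(inherits(ds, "pv_dataset"))
  check_groups(ds, group_a, group_b)
  if (length(group_a) < 3 || length(group_b) < 3) {
    abort("each group needs >= 3 cells for the two-sample test")
  }
  gate <- feature_gate(ds, group_a, group_b, min_tpm = min_tpm,
                       min_cells = min_cells)
  a <- ds$expr[gate$gene, group_a, drop = FALSE]
  b <- ds$expr[gate$gene, group_b, drop = FALSE]
  la <- log2p1(a); lb <- log2p1(b)
  p <- vapply(seq_len(nrow(a)), function(i) {
    x <- la[i, ]; y <- lb[i, ]
    if (stats::sd(c(x, y)) == 0) return(1)
    if (test == "rank_sum") {
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    } else {
      if (stats::sd(x) == 0 && stats::sd(y) == 0) return(1)
      stats::t.test(x, y)$p.value
    }
  }, numeric(1))
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  logfd <- log2((mean_a + 1) / (mean_b + 1))
  out <- tibble::tibble(
    gene = gate$gene, mean_a = mean_a, mean_b = mean_b,
    logfd = logfd, p = p, fdr = stats::p.adjust(p, method = "BH"))
  out$de_flag <- abs(out$logfd) > logfd_cutoff & out$fdr < fdr_cutoff
  out <- dplyr::arrange(out, .data$fdr, .data$p)
  structure(out, test = test, class = c("de_table", class(out)))
}

#' @export
glance.de_table <- function(x, ...) {
  tibble::tibble(n_genes_tested = nrow(x), n_de = sum(x$de_flag),
                 n_up = sum(x$de_flag & x$logfd > 0),
                 n_down = sum(x$de_flag & x$logfd < 0),
                 test = attr(x, "test"))
}

#' Expression filter for cell-adhesion-molecule (CAM) panels
#'
#' Keeps CAM genes expressed (TPM strictly above the binarization cutoff)
#' in at least `min_cells` cells of the dataset.
#'
#' @param ds A `pv_dataset` (typically restricted to PV cells).
#' @param cam_genes Character vector of CAM gene symbols.
#' @param min_cells Minimum expressing cells (default 3).
#' @param cutoff_tpm Expressed cutoff (strict `>`; default 0.6).
#' @return Tibble with `gene`, `n_expressing` for retained CAMs, in the
#'   order given.
#' @export
cam_expression_filter <- function(ds, cam_genes, min_cells = 3,
                                  cutoff_tpm = 0.6) {
  stopifnot(inherits(ds, "pv_dataset"))
  cam_genes <- unique(as.character(cam_genes))
  present <- intersect(cam_genes, rownames(ds$expr))
  if (!length(present)) {
    return(tibble::tibble(gene = character(), n_expressing = integer()))
  }
  n_expr <- rowSums(ds$expr[present, , drop = FALSE] > cutoff_tpm)
  keep <- n_expr >= min_cells
  tibble::tibble(gene = present[keep], n_expressing = as.integer(n_expr[keep]))
}
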