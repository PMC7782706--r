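#' Map query cells onto a reference embedding by correlation kNN
#'
#' For each query cell, finds its `k` nearest reference cells by correlation
#' distance (1 - Pearson r on log2(TPM + 1), restricted to a shared gene
#' set) and places the cell at the component-wise median of those neighbors'
#' 2-D embedding coordinates. Ties at the k-th distance are broken by
#' reference cell order; rank (Spearman) correlation is available for
#' depth-mismatched reference data.
#'
#' @param query Genes x cells TPM matrix (or `pv_dataset`) to map.
#' @param ref_expr Genes x cells reference TPM matrix.
#' @param ref_coords Data frame/matrix of reference coordinates: columns
#'   `x`, `y` (rows matching `ref_expr` cells, or with a `cell_id` column).
#' @param genes Gene set used for the correlation (character vector);
#'   must be present in both matrices.
#' @param k Neighbor count (default 10; `1 <= k <=` reference size).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble with `cell_id`, `x`, `y`, `mean_neighbor_r`, `note`
#'   (`NA` or a per-cell degeneracy flag; degenerate cells get `NA`
#'   coordinates and the run continues).
#' @export
knn_map <- function(query, ref_expr, ref_coords, genes, k = 10,
                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (inherits(query, "pv_dataset")) query <- query$expr
  assert_expression_matrix(query, "query matrix")
  assert_expression_matrix(ref_expr, "reference matrix")
  ref_coords <- tibble::as_tibble(ref_coords)
  if ("cell_id" %in% names(ref_coords)) {
    if (!setequal(ref_coords$cell_id, colnames(ref_expr))) {
      abort("ref_coords cell ids must match reference matrix cells")
    }
    ref_coords <- ref_coords[match(colnames(ref_expr), ref_coords$cell_id), ]
  } else if (nrow(ref_coords) != ncol(ref_expr)) {
    abort("ref_coords must have one row per reference cell")
  }
  if (!all(c("x", "y") %in% names(ref_coords))) {
    abort("ref_coords needs columns x and y")
  }
  if (!all(is.finite(ref_coords$x)) || !all(is.finite(ref_coords$y))) {
    abort("reference coordinates must be finite")
  }
  genes <- unique(as.character(genes))
  missing <- setdiff(genes, intersect(rownames(query), rownames(ref_expr)))
  if (length(missing)) {
    abort(paste0("gene(s) absent from query or reference: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  if (k < 1 || k > ncol(ref_expr)) abort("k must be in [1, reference size]")

  q <- log2p1(query[genes, , drop = FALSE])
  r <- log2p1(ref_expr[genes, , drop = FALSE])
  out <- purrr::map_dfr(seq_len(ncol(q)), function(i) {
    v <- q[, i]
    if (stats::sd(v) == 0) {
      return(tibble::tibble(cell_id = colnames(q)[i], x = NA_real_,
                            y = NA_real_, mean_neighbor_r = NA_real_,
                            note = "constant expression over gene set"))
    }
    cors <- suppressWarnings(stats::cor(v, r, method = method))[1, ]
    cors[!is.finite(cors)] <- 0   # constant reference cells
    d <- 1 - cors
    nb <- order(d, seq_along(d))[seq_len(k)]   # ties: reference order
    tibble::tibble(cell_id = colnames(q)[i],
                   x = stats::median(ref_coords$x[nb]),
                   y = stats::median(ref_coords$y[nb]),
                   mean_neighbor_r = mean(cors[nb]),
                   note = NA_character_)
  })
  structure(out, k = k, method = method, n_genes = length(genes),
            class = c("pv_mapping", class(out)))
}
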