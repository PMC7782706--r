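#' Between-type similarity from CAM expression
#'
#' Similarity between cell groups measured as the average pairwise Pearson
#' correlation of cells on the log2(TPM + 1) expression of a
#' cell-adhesion-molecule (CAM) gene panel: the off-diagonal entry for two
#' groups averages over all cross-group cell pairs, the diagonal over all
#' within-group pairs excluding self-pairs. Groups can be the five
#' morphological PV types, the three axonal classes, or the two dendritic
#' orientations.
#'
#' @param ds A `pv_dataset`.
#' @param cam_genes Character vector of CAM genes, typically the output of
#'   [cam_expression_filter()].
#' @param group_by `"five_types"` (morph_type), `"axo"`, or `"dendro"`;
#'   alternatively a per-cell character vector of group labels.
#' @param scale `"log2"` (default) or `"linear"` TPM.
#' @return A `pv_similarity`: symmetric numeric matrix of mean correlations
#'   (diagonal `NA` for singleton groups).
#' @export
cam_similarity <- function(ds, cam_genes,
                           group_by = c("five_types", "axo", "dendro"),
                           scale = c("log2", "linear")) {
  stopifnot(inherits(ds, "pv_dataset"))
  scale <- match.arg(scale)
  default_modes <- c("five_types", "axo", "dendro")
  if (is.character(group_by) &&
      (length(group_by) == 1 || identical(group_by, default_modes))) {
    group_by <- match.arg(group_by)
    labels <- switch(group_by,
                     five_types = ds$meta$morph_type,
                     axo = ds$meta$axo,
                     dendro = ds$meta$dendro)
  } else {
    if (length(group_by) != ncol(ds$expr)) {
      abort("per-cell group_by must match dataset cells")
    }
    labels <- as.character(group_by)
  }
  cam_genes <- intersect(unique(as.character(cam_genes)), rownames(ds$expr))
  if (!length(cam_genes)) abort("no CAM gene present in the matrix")
  keep <- !is.na(labels)
  labels <- labels[keep]
  x <- ds$expr[cam_genes, keep, drop = FALSE]
  if (scale == "log2") x <- log2p1(x)
  const <- apply(x, 2, stats::sd) == 0
  if (any(const)) {
    warn(sprintf("excluding %d cell(s) with constant CAM expression", sum(const)))
    x <- x[, !const, drop = FALSE]
    labels <- labels[!const]
  }
  groups <- sort(unique(labels))
  if (any(table(labels) < 1)) abort("empty group")
  r <- stats::cor(x)
  out <- matrix(NA_real_, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (i in seq_along(groups)) {
    for (j in seq(i, length(groups))) {
      a <- which(labels == groups[i]); b <- which(labels == groups[j])
      vals <- r[a, b, drop = FALSE]
      if (i == j) {
        if (length(a) < 2) { out[i, j] <- NA_real_; next }
        vals <- vals[upper.tri(vals)]          # exclude self-pairs
      }
      out[i, j] <- out[j, i] <- mean(vals)
    }
  }
  structure(out, genes = cam_genes, scale = scale,
            class = c("pv_similarity", "matrix"))
}

#' @export
tidy.pv_similarity <- function(x, ...) {
  m <- unclass(x)
  tibble::as_tibble(as.table(m), .name_repair = "minimal") |>
    stats::setNames(c("type_a", "type_b", "similarity"))
}
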