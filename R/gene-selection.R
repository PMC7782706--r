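#' Select marker genes by one of six methods
#'
#' A single interface to the six gene-selection strategies used for
#' cell-type separation and reference mapping:
#'
#' * `chi2` — chi-squared score between class labels and log2(TPM + 1)
#'   expression (class-wise expression sums vs their expected share).
#' * `mutual_info` — mutual information between class labels and the binary
#'   expressed indicator (TPM > `expressed_cutoff`).
#' * `anova_f` — one-way ANOVA F statistic on the binary expressed
#'   indicator.
#' * `reference_list` — a supplied gene list intersected with the matrix,
#'   order preserved.
#' * `correlated_with_reference` — genes most strongly correlated (maximal
#'   |Pearson r| on log2(TPM + 1)) with any reference gene, excluding the
#'   reference genes themselves.
#' * `rate_adjusted_variable` — see [select_rate_adjusted_variable()].
#'
#' Scored methods return the top `n_genes` ranked by score descending, ties
#' broken alphabetically. All methods are deterministic and invariant to
#' cell order.
#'
#' @param ds A `pv_dataset`.
#' @param method One of the six method names.
#' @param n_genes Number of genes to return (default 150).
#' @param labels Per-cell class labels (same length/order as cells); needed
#'   by the supervised methods.
#' @param reference_genes Character vector of reference genes; needed by the
#'   reference-based methods.
#' @param expressed_cutoff Binarization cutoff in TPM for `mutual_info` and
#'   `anova_f` (default 0.6, matching the transition detector).
#' @param tpm_cutoff Cutoff for `rate_adjusted_variable` (default 32).
#' @return A `gene_set`: tibble with `gene`, `score`, ranked; attribute
#'   `method` records the method and its parameters.
#' @export
select_genes <- function(ds, method = c("chi2", "mutual_info", "anova_f",
                                        "reference_list",
                                        "correlated_with_reference",
                                        "rate_adjusted_variable"),
                         n_genes = 150, labels = NULL,
                         reference_genes = NULL,
                         expressed_cutoff = 0.6, tpm_cutoff = 32) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "pv_dataset"))
  expr <- ds$expr
  if (method %in% c("chi2", "mutual_info", "anova_f")) {
    if (is.null(labels)) abort(sprintf("method '%s' requires per-cell labels", method))
    labels <- as.character(labels)
    if (length(labels) != ncol(expr)) {
      abort("labels must have one entry per cell, in dataset order")
    }
  }
  if (method %in% c("reference_list", "correlated_with_reference") &&
      is.null(reference_genes)) {
    abort(sprintf("method '%s' requires reference_genes", method))
  }

  if (method == "reference_list") {
    genes <- intersect(as.character(reference_genes), rownames(expr))
    out <- tibble::tibble(gene = genes, score = NA_real_)
    return(new_gene_set(out, method, n_genes = length(genes)))
  }
  if (method == "rate_adjusted_variable") {
    return(select_rate_adjusted_variable(ds, n_genes = n_genes,
                                         tpm_cutoff = tpm_cutoff))
  }

  score <- switch(
    method,
    chi2 = chi2_score(log2p1(expr), labels),
    mutual_info = mutual_info_score(expr > expressed_cutoff, labels),
    anova_f = anova_f_score(expr > expressed_cutoff, labels),
    correlated_with_reference = {
      ref <- intersect(as.character(reference_genes), rownames(expr))
      if (!length(ref)) abort("no reference gene present in the matrix")
      lx <- t(log2p1(expr))
      r <- suppressWarnings(stats::cor(lx, lx[, ref, drop = FALSE]))
      r[!is.finite(r)] <- 0                 # constant genes: score 0
      s <- apply(abs(r), 1, max)
      s[ref] <- NA_real_                    # "correlated with, but not, them"
      s
    })
  ranked <- order(-score, rownames(expr), na.last = NA)
  if (n_genes > length(ranked)) {
    warn(sprintf("requested %d genes but only %d available", n_genes,
                 length(ranked)))
  }
  take <- head(ranked, n_genes)
  out <- tibble::tibble(gene = rownames(expr)[take],
                        score = unname(score[take]))
  new_gene_set(out, method, n_genes = n_genes,
               expressed_cutoff = expressed_cutoff)
}

new_gene_set <- function(tbl, method, ...) {
  structure(tbl, method = method, params = list(...),
            class = c("gene_set", class(tbl)))
}

# chi-squared feature score: for non-negative feature values x and classes c,
# observed class-wise sums O_c = sum(x | class c), expected E_c = n_c/n * sum(x),
# score = sum (O - E)^2 / E
chi2_score <- function(lx, labels) {
  classes <- sort(unique(labels))
  n <- length(labels)
  obs <- vapply(classes, function(cl) rowSums(lx[, labels == cl, drop = FALSE]),
                numeric(nrow(lx)))
  frac <- vapply(classes, function(cl) mean(labels == cl), numeric(1))
  tot <- rowSums(lx)
  exp_ <- outer(tot, frac)
  s <- rowSums((obs - exp_)^2 / exp_)
  s[tot == 0] <- 0
  stats::setNames(s, rownames(lx))
}

# mutual information between a binary indicator (rows of bx) and labels
mutual_info_score <- function(bx, labels) {
  classes <- sort(unique(labels))
  n <- length(labels)
  p_c <- vapply(classes, function(cl) mean(labels == cl), numeric(1))
  # joint counts per gene: expressed x class
  s <- numeric(nrow(bx))
  n1c <- vapply(classes, function(cl) rowSums(bx[, labels == cl, drop = FALSE]),
                numeric(nrow(bx)))
  n_cl <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  p1 <- rowSums(n1c) / n
  for (j in seq_along(classes)) {
    p11 <- n1c[, j] / n
    p01 <- (n_cl[j] - n1c[, j]) / n
    t1 <- ifelse(p11 > 0, p11 * log(p11 / (p1 * p_c[j])), 0)
    t0 <- ifelse(p01 > 0, p01 * log(p01 / ((1 - p1) * p_c[j])), 0)
    s <- s + t1 + t0
  }
  stats::setNames(pmax(s, 0), rownames(bx))
}

# one-way ANOVA F statistic per gene on the binary indicator
anova_f_score <- function(bx, labels) {
  bx <- bx * 1
  classes <- sort(unique(labels))
  k <- length(classes)
  n <- length(labels)
  gm <- rowMeans(bx)
  ssb <- numeric(nrow(bx)); ssw <- numeric(nrow(bx))
  for (cl in classes) {
    sub <- bx[, labels == cl, drop = FALSE]
    m <- rowMeans(sub)
    ssb <- ssb + ncol(sub) * (m - gm)^2
    ssw <- ssw + rowSums((sub - m)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssw == 0 & ssb == 0] <- 0
  f[ssw == 0 & ssb > 0] <- Inf
  stats::setNames(f, rownames(bx))
}

#' Rate-adjusted variable gene selection
#'
#' Selects genes on the low-detection-rate / high-expression frontier, a
#' reconstruction of the expression-rate-adjusted variable-gene rule used
#' for reference mapping. For each gene let `d` be the fraction of cells
#' with TPM > `tpm_cutoff` and `m` the mean log2(TPM) over those cells; a
#' gene is selected when `d < exp(-decay * (m - b)) + floor_rate`, with the
#' offset `b` tuned so that exactly `n_genes` genes are selected (tuning has
#' the closed form `b > m + log(d - floor_rate)/decay` per gene, which is
#' used directly). Genes never exceeding the cutoff are excluded.
#'
#' @param ds A `pv_dataset`.
#' @param n_genes Number of genes (default 150).
#' @param tpm_cutoff Detection cutoff in TPM (strict `>`; default 32).
#' @param decay,floor_rate Frontier shape constants (defaults 1.5, 0.02).
#' @return A `gene_set` tibble (`gene`, `score` = mean log2 TPM over
#'   detected cells), ranked by score descending.
#' @export
select_rate_adjusted_variable <- function(ds, n_genes = 150, tpm_cutoff = 32,
                                          decay = 1.5, floor_rate = 0.02) {
  stopifnot(inherits(ds, "pv_dataset"))
  expr <- ds$expr
  above <- expr > tpm_cutoff
  d <- rowMeans(above)
  m <- vapply(seq_len(nrow(expr)), function(i) {
    v <- expr[i, above[i, ]]
    if (!length(v)) NA_real_ else mean(log2(v))
  }, numeric(1))
  qual <- which(d > 0)
  if (!length(qual)) {
    warn("no gene ever exceeds tpm_cutoff; returning empty set")
    return(new_gene_set(tibble::tibble(gene = character(), score = numeric()),
                        "rate_adjusted_variable", n_genes = n_genes,
                        tpm_cutoff = tpm_cutoff))
  }
  # selection threshold on the offset b: gene selected iff b > beta_g
  beta <- ifelse(d[qual] <= floor_rate, -Inf,
                 m[qual] + log(d[qual] - floor_rate) / decay)
  ord <- order(beta, -m[qual], rownames(expr)[qual])
  if (n_genes > length(qual)) {
    warn(sprintf("only %d genes exceed the cutoff; returning all", length(qual)))
  }
  take <- qual[head(ord, n_genes)]
  take <- take[order(-m[take], rownames(expr)[take])]
  out <- tibble::tibble(gene = rownames(expr)[take], score = m[take])
  new_gene_set(out, "rate_adjusted_variable", n_genes = n_genes,
               tpm_cutoff = tpm_cutoff, decay = decay, floor_rate = floor_rate)
}
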