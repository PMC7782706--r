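#' Class-balanced random-forest classification accuracy
#'
#' The balanced resampling protocol for asking whether two cell classes are
#' transcriptomically separable: each repeat (i) randomly downsamples the
#' larger class so both classes have equal size, (ii) draws a stratified
#' 80/20 train/test split, (iii) trains a fresh forest of `n_trees` trees on
#' log2(TPM + 1), and (iv) scores the held-out cells. With no class
#' difference the expected accuracy is the 50% baseline. Per-cell accuracy
#' is the fraction of a cell's test-set appearances that were classified
#' correctly.
#'
#' @param ds A `pv_dataset`, or a genes x cells matrix.
#' @param labels Binary per-cell class labels (character/factor, 2 levels),
#'   in dataset cell order.
#' @param n_trees Trees per forest (default 100).
#' @param n_repeats Number of repeats (default 100).
#' @param train_fraction Training fraction (default 0.8).
#' @param seed Integer seed; the whole protocol is reproducible given it.
#' @return A `pv_rf_accuracy` object: list with `overall_accuracy`,
#'   `per_repeat` (accuracy per repeat), `per_cell` (tibble of cell_id,
#'   n_test, n_correct, accuracy), and the protocol parameters.
#' @export
balanced_rf_accuracy <- function(ds, labels, n_trees = 100, n_repeats = 100,
                                 train_fraction = 0.8, seed = 1L) {
  expr <- if (inherits(ds, "pv_dataset")) ds$expr else ds
  assert_expression_matrix(expr)
  labels <- as.character(labels)
  if (length(labels) != ncol(expr)) abort("labels must match dataset cells")
  classes <- sort(unique(labels))
  if (length(classes) != 2) abort("labels must be binary (exactly 2 classes)")
  sizes <- table(labels)
  if (any(sizes < 5)) abort("each class needs >= 5 cells")
  x <- t(log2p1(expr))
  cell_ids <- colnames(expr)
  n_test_hits <- stats::setNames(integer(length(cell_ids)), cell_ids)
  n_test_seen <- n_test_hits
  per_repeat <- numeric(n_repeats)

  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      m <- min(sizes)
      keep <- unlist(lapply(classes, function(cl) {
        idx <- which(labels == cl)
        if (length(idx) > m) sample(idx, m) else idx
      }), use.names = FALSE)
      # stratified 80/20 split within the balanced subset
      train <- unlist(lapply(classes, function(cl) {
        idx <- keep[labels[keep] == cl]
        sample(idx, max(1L, round(train_fraction * length(idx))))
      }), use.names = FALSE)
      test <- setdiff(keep, train)
      if (!length(test)) abort("train_fraction leaves no test cells")
      fit <- randomForest::randomForest(
        x = x[train, , drop = FALSE], y = factor(labels[train], levels = classes),
        ntree = n_trees)
      pred <- as.character(predict(fit, x[test, , drop = FALSE]))
      correct <- pred == labels[test]
      per_repeat[r] <- mean(correct)
      ids <- cell_ids[test]
      n_test_seen[ids] <- n_test_seen[ids] + 1L
      n_test_hits[ids] <- n_test_hits[ids] + as.integer(correct)
    }
  })
  per_cell <- tibble::tibble(
    cell_id = cell_ids, label = labels,
    n_test = as.integer(n_test_seen), n_correct = as.integer(n_test_hits),
    accuracy = ifelse(n_test_seen > 0, n_test_hits / n_test_seen, NA_real_))
  structure(list(overall_accuracy = mean(per_repeat),
                 per_repeat = per_repeat, per_cell = per_cell,
                 n_trees = n_trees, n_repeats = n_repeats,
                 train_fraction = train_fraction, seed = seed,
                 classes = classes,
                 forest_defaults = list(mtry = "sqrt(p)",
                                        nodesize = 1, maxnodes = NULL)),
            class = "pv_rf_accuracy")
}

#' @export
print.pv_rf_accuracy <- function(x, ...) {
  cat(sprintf(
    "<pv_rf_accuracy> %s vs %s: %.1f%% mean test accuracy (%d repeats, %d trees)\n",
    x$classes[1], x$classes[2], 100 * x$overall_accuracy, x$n_repeats, x$n_trees))
  invisible(x)
}

#' @export
tidy.pv_rf_accuracy <- function(x, ...) x$per_cell

#' @export
glance.pv_rf_accuracy <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall_accuracy,
                 se = stats::sd(x$per_repeat) / sqrt(x$n_repeats),
                 n_repeats = x$n_repeats, n_trees = x$n_trees,
                 train_fraction = x$train_fraction, seed = x$seed)
}

#' Linear-SVM recursive feature elimination
#'
#' Ranks genes by iteratively training a linear support-vector machine on
#' log2(TPM + 1), scoring genes by absolute hyperplane weight (multi-class:
#' maximum across one-vs-rest machines), and dropping the lowest-ranked
#' fraction until `n_keep` genes remain.
#'
#' @param ds A `pv_dataset` or matrix.
#' @param labels Per-cell class labels (>= 2 classes, each >= 3 cells).
#' @param n_keep Genes to keep (default 50).
#' @param drop_fraction Fraction of remaining genes dropped each round
#'   (default 0.2).
#' @param cost SVM cost parameter (default 1).
#' @return A `gene_set` tibble (`gene`, `score` = final |weight|), ranked.
#' @export
svm_rfe <- function(ds, labels, n_keep = 50, drop_fraction = 0.2, cost = 1) {
  expr <- if (inherits(ds, "pv_dataset")) ds$expr else ds
  assert_expression_matrix(expr)
  labels <- as.character(labels)
  if (length(labels) != ncol(expr)) abort("labels must match dataset cells")
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("need >= 2 classes")
  if (any(table(labels) < 3)) abort("each class needs >= 3 cells")
  x <- t(log2p1(expr))
  genes <- colnames(x)
  if (n_keep >= length(genes)) {
    warn("n_keep >= gene count; returning all genes unranked")
    return(new_gene_set(tibble::tibble(gene = genes, score = NA_real_),
                        "svm_rfe", n_keep = n_keep))
  }
  current <- genes
  w <- NULL
  while (length(current) > n_keep) {
    w <- svm_ovr_weights(x[, current, drop = FALSE], labels, classes, cost)
    n_drop <- max(1L, min(length(current) - n_keep,
                          floor(drop_fraction * length(current))))
    current <- current[order(-w, current)][seq_len(length(current) - n_drop)]
  }
  w <- svm_ovr_weights(x[, current, drop = FALSE], labels, classes, cost)
  ord <- order(-w, current)
  out <- tibble::tibble(gene = current[ord], score = unname(w[ord]))
  new_gene_set(out, "svm_rfe", n_keep = n_keep, drop_fraction = drop_fraction,
               cost = cost)
}

# max absolute one-vs-rest linear SVM weight per feature
svm_ovr_weights <- function(x, labels, classes, cost) {
  agg <- rep(0, ncol(x))
  targets <- if (length(classes) == 2) classes[1] else classes
  for (cl in targets) {
    y <- factor(ifelse(labels == cl, cl, "rest"),
                levels = c(cl, "rest"))
    fit <- e1071::svm(x = x, y = y, kernel = "linear", cost = cost,
                      scale = FALSE)
    w <- drop(crossprod(fit$coefs, fit$SV))
    agg <- pmax(agg, abs(w))
  }
  stats::setNames(agg, colnames(x))
}

#' Cross-tabulate two labelings of the same cells
#'
#' Counts how many cells carry each combination of a row label (e.g.
#' morphological type) and a column label (e.g. transcriptomic type).
#'
#' @param labels_a,labels_b Named vectors (names = cell ids) or plain
#'   vectors of equal length over the same cells.
#' @param row_order,col_order Optional explicit label orders.
#' @return A `pv_confusion`: integer matrix with row/column labels.
#' @export
confusion_matrix <- function(labels_a, labels_b, row_order = NULL,
                             col_order = NULL) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b))) {
      abort("labels_a and labels_b must cover the same cells")
    }
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    abort("labels_a and labels_b must have the same length")
  }
  row_order <- row_order %||% sort(unique(as.character(labels_a)))
  col_order <- col_order %||% sort(unique(as.character(labels_b)))
  m <- table(factor(labels_a, levels = row_order),
             factor(labels_b, levels = col_order))
  m <- matrix(as.integer(m), nrow = length(row_order),
              dimnames = list(row_order, col_order))
  structure(m, class = c("pv_confusion", "matrix"))
}

#' @export
tidy.pv_confusion <- function(x, ...) {
  tibble::as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    stats::setNames(c("row_label", "col_label", "n"))
}
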