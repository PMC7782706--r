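test_that("the balanced RF protocol is deterministic and perfect when separable", {
  x <- noise_matrix(5, 30, seed = 5)
  x["g0001", ] <- c(rep(100, 15), rep(0, 15))   # noiseless separator
  labels <- rep(c("A", "B"), each = 15)
  r1 <- balanced_rf_accuracy(x, labels, n_repeats = 10, seed = 3)
  expect_equal(r1$overall_accuracy, 1.0)

  r2 <- balanced_rf_accuracy(x, labels, n_repeats = 10, seed = 3)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_identical(r1$per_cell, r2$per_cell)

  # per-cell accuracies are fractions of test-set appearances
  pc <- tidy(r1)
  expect_true(all(pc$accuracy >= 0 & pc$accuracy <= 1, na.rm = TRUE))
  expect_true(all(pc$n_correct <= pc$n_test))

  expect_error(balanced_rf_accuracy(x, rep(c("A", "B", "C"), each = 10)),
               "binary")
  expect_error(balanced_rf_accuracy(x[, 1:8], c(rep("A", 4), rep("B", 4))),
               ">= 5")
})

test_that("label-permuted data hovers at the 50% baseline over repeats", {
  # permute labels relative to a structured dataset; average over several
  # permutations so the dataset-conditional bias cancels
  x <- noise_matrix(100, 40, dropout = 0.1, seed = 6)
  set.seed(11)
  accs <- vapply(1:6, function(i) {
    labels <- sample(rep(c("A", "B"), each = 20))
    balanced_rf_accuracy(x, labels, n_repeats = 20, seed = i)$overall_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.06)
})

test_that("SVM-RFE retains a planted separator among noise", {
  cfg <- simulation_config(
    n_cells_per_type = c(vBC = 25, hBC = 25), n_genes = 500,
    de_spec = tibble::tibble(gene = 42L, type_a = "vBC", type_b = "hBC",
                             fold = 16),
    baseline_log2_sd = 0.3, dropout_rate = 0, seed = 8)
  sim <- simulate_expression(cfg)
  sel <- svm_rfe(sim$dataset, sim$dataset$meta$morph_type, n_keep = 50)
  expect_equal(nrow(sel), 50)
  expect_true(sim$truth$de$gene_symbol[1] %in% sel$gene)

  # n_keep >= gene count returns everything with a warning
  small <- toy_dataset(sim$dataset$expr[1:10, ], sim$dataset$meta$age_days)
  expect_warning(all_genes <- svm_rfe(small, sim$dataset$meta$morph_type,
                                      n_keep = 10), "unranked")
  expect_equal(nrow(all_genes), 10)

  # duplicated separating genes do not crash the elimination
  dup <- rbind(sim$dataset$expr[1:50, ],
               dup_sep = sim$dataset$expr[sim$truth$de$gene_symbol[1], ])
  ds_dup <- toy_dataset(dup, sim$dataset$meta$age_days)
  expect_no_error(svm_rfe(ds_dup, sim$dataset$meta$morph_type, n_keep = 10))
})

test_that("confusion matrices count co-occurring labels and conserve totals", {
  a <- rep(c("x", "y"), c(6, 4))
  b <- a
  m <- confusion_matrix(a, b)
  expect_equal(diag(unclass(m)), c(x = 6, y = 4))
  expect_equal(sum(m), 10)
  expect_equal(unclass(m)["x", "y"], 0)

  set.seed(2)
  b2 <- sample(rep(c("x", "y", "z"), c(3, 3, 4)))
  m2 <- confusion_matrix(a, b2)
  expect_equal(unname(rowSums(m2)), c(6, 4))   # marginals = class sizes
  expect_equal(sum(m2), 10)

  expect_equal(sum(confusion_matrix("x", "y")), 1)
  expect_error(confusion_matrix(c(a = "x"), c(b = "y")), "same cells")
})

test_that("knn_map reproduces reference coordinates and takes component medians", {
  ref <- noise_matrix(30, 5, seed = 12)
  coords <- tibble::tibble(cell_id = colnames(ref),
                           x = c(0, 0, 4, 9, 2), y = c(0, 2, 6, 1, 8))
  genes <- rownames(ref)

  # query identical to a reference cell, k = 1 -> that cell's coordinates
  q <- ref[, 2, drop = FALSE]; colnames(q) <- "query1"
  hit <- knn_map(q, ref, coords, genes, k = 1)
  expect_equal(c(hit$x, hit$y), c(0, 2))

  # k = 3 median of (0,0), (0,2), (4,6) = (0,2)
  ref3 <- ref[, 1:3]
  hit3 <- knn_map(q, ref3, coords[1:3, ], genes, k = 3)
  expect_equal(c(hit3$x, hit3$y), c(0, 2))

  # mapped position lies in the bounding box of the k neighbours
  set.seed(4)
  q2 <- matrix(2^rnorm(30, 4), 30, 1, dimnames = list(genes, "q2"))
  out <- knn_map(q2, ref, coords, genes, k = 3)
  expect_gte(out$x, min(coords$x)); expect_lte(out$x, max(coords$x))
  expect_gte(out$y, min(coords$y)); expect_lte(out$y, max(coords$y))

  # constant query is flagged, not fatal
  qc <- matrix(1, 30, 1, dimnames = list(genes, "flat"))
  flat <- knn_map(qc, ref, coords, genes, k = 2)
  expect_true(is.na(flat$x))
  expect_match(flat$note, "constant")

  expect_error(knn_map(q, ref, coords, genes, k = 99), "k must be")
  expect_error(knn_map(q, ref, coords, c(genes, "absent"), k = 1), "absent")
})
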