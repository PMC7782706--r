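test_that("MAD QC removes the hand-computed failing cell and fails on either metric", {
  counts <- tibble::tibble(cell_id = paste0("c", 1:5),
                           unique_gene_count = c(100, 98, 102, 95, 10),
                           aligned_read_count = rep(1e6, 5))
  r <- qc_filter(counts)
  thr <- attr(r, "thresholds")
  # median 98, unscaled MAD 3 -> threshold 98 - 9 = 89
  expect_equal(unname(thr["unique_gene_count"]), 89)
  expect_equal(r$pass, c(TRUE, TRUE, TRUE, TRUE, FALSE))

  # cell above the gene threshold but below the read threshold still fails
  counts$unique_gene_count <- rep(100, 5)
  counts$aligned_read_count <- c(1e6, 1, 1e6, 1e6, 1e6)   # cell 2 far below
  r2 <- qc_filter(counts)
  expect_false(r2$pass[2])
  expect_true(all(r2$pass[-2]))

  # identical metrics: MAD 0, nothing strictly below the median
  same <- tibble::tibble(cell_id = paste0("c", 1:4),
                         unique_gene_count = rep(50, 4),
                         aligned_read_count = rep(9, 4))
  expect_true(all(qc_filter(same)$pass))

  expect_error(qc_filter(counts[1:2, ]), "at least 3")
})

test_that("QC pass/fail partition is scale-equivariant", {
  set.seed(8)
  counts <- tibble::tibble(cell_id = paste0("c", 1:30),
                           unique_gene_count = rpois(30, 5000),
                           aligned_read_count = rpois(30, 1e5))
  counts$unique_gene_count[c(4, 17)] <- c(100, 200)
  base <- qc_filter(counts)$pass
  for (k in c(0.5, 3, 1000)) {
    scaled <- dplyr::mutate(counts,
                            unique_gene_count = unique_gene_count * k,
                            aligned_read_count = aligned_read_count * k)
    expect_equal(qc_filter(scaled)$pass, base)
  }
})

test_that("feature_gate applies the strict pooled TPM > 15 in >= 5 cells rule", {
  x <- matrix(0, 3, 20, dimnames = list(c("gA", "gB", "gC"), paste0("c", 1:20)))
  x["gA", 1:5] <- 16     # strictly above 15 in exactly 5 pooled cells -> kept
  x["gB", ] <- 15        # exactly 15 everywhere, never strictly above -> dropped
  x["gC", 1:4] <- 100    # above in only 4 cells -> dropped
  ds <- toy_dataset(x, rep(30L, 20))
  kept <- feature_gate(ds, paste0("c", 1:10), paste0("c", 11:20))
  expect_equal(kept$gene, "gA")

  expect_error(feature_gate(ds, paste0("c", 1:10), paste0("c", 10:20)), "disjoint")

  # monotone in min_tpm: raising the threshold never adds genes
  set.seed(3)
  y <- noise_matrix(50, 20, dropout = 0.3, seed = 3)
  ds2 <- toy_dataset(y, rep(30L, 20))
  prev <- feature_gate(ds2, colnames(y)[1:10], colnames(y)[11:20],
                       min_tpm = 5)$gene
  for (thr in c(10, 15, 30, 60)) {
    cur <- feature_gate(ds2, colnames(y)[1:10], colnames(y)[11:20],
                        min_tpm = thr)$gene
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("differential expression flags planted fold changes and gates on fold", {
  cfg <- simulation_config(
    n_cells_per_type = c(vBC = 50, hBC = 50), n_genes = 300,
    de_spec = tibble::tibble(gene = 1L, type_a = "vBC", type_b = "hBC", fold = 8),
    baseline_log2_sd = 0.3, dropout_rate = 0, seed = 3)
  sim <- simulate_expression(cfg)
  meta <- sim$dataset$meta
  de <- differential_expression(sim$dataset,
                                meta$cell_id[meta$morph_type == "vBC"],
                                meta$cell_id[meta$morph_type == "hBC"])
  planted <- sim$truth$de$gene_symbol[1]
  expect_true(de$de_flag[de$gene == planted])
  # significance without a 2-fold difference is not flagged
  small_fold <- de$fdr < 0.05 & abs(de$logfd) <= 1
  expect_true(all(!de$de_flag[small_fold]))

  expect_error(differential_expression(sim$dataset, meta$cell_id[1:2],
                                       meta$cell_id[3:10]), ">= 3")
})

test_that("differential expression keeps type-I error under control on null data", {
  # identical distributions in both groups; count genes flagged DE
  n_flagged <- n_tested <- 0
  for (rep in 1:20) {
    x <- noise_matrix(500, 100, mean_log2 = 5, sd_log2 = 0.8, dropout = 0.1,
                      seed = 100 + rep)
    ds <- toy_dataset(x, rep(30L, 100))
    de <- differential_expression(ds, colnames(x)[1:50], colnames(x)[51:100])
    n_flagged <- n_flagged + sum(de$de_flag)
    n_tested <- n_tested + nrow(de)
  }
  expect_lte(n_flagged / n_tested, 0.005)
})

test_that("CAM expression filter keeps genes expressed in >= 3 cells", {
  x <- matrix(0, 4, 10, dimnames = list(paste0("cam", 1:4), paste0("c", 1:10)))
  x["cam1", 1:3] <- 5      # 3 expressing cells -> kept
  x["cam2", 1:2] <- 5      # 2 -> dropped
  x["cam3", ] <- 2         # all cells -> kept
  x["cam4", 1:5] <- 0.6    # at the cutoff, not strictly above -> dropped
  ds <- toy_dataset(x, rep(30L, 10))
  kept <- cam_expression_filter(ds, paste0("cam", 1:4))
  expect_equal(kept$gene, c("cam1", "cam3"))
  expect_equal(nrow(cam_expression_filter(ds, character(0))), 0)
})
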