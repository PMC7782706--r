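test_that("binarization is strict at the cutoff", {
  x <- matrix(c(0, 0.6, 0.7, 5), 1, 4,
              dimnames = list("g1", paste0("c", 1:4)))
  ds <- toy_dataset(x, c(10L, 12L, 14L, 16L))
  bx <- binarize(ds)
  expect_equal(as.logical(bx), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(attr(bx, "cutoff_tpm"), 0.6)
})

test_that("eligibility requires >= 6 cells on both sides", {
  bx <- matrix(FALSE, 3, 50, dimnames = list(paste0("g", 1:3), NULL))
  bx[1, 1:6] <- TRUE    # expressed in 6 -> eligible
  bx[2, 1:5] <- TRUE    # expressed in 5 -> excluded
  bx[3, 1:46] <- TRUE   # not expressed in only 4 -> excluded
  el <- eligible_genes(bx)
  expect_equal(el$gene, "g1")
  expect_equal(el$n_expressed, 6L)
})

test_that("gini impurity matches analytic values", {
  expect_identical(gini_impurity(c(5, 5)), 0.5)
  expect_identical(gini_impurity(c(7, 0)), 0)
  expect_equal(gini_impurity(c(3, 1)), 0.375)
  expect_error(gini_impurity(c(0, 0)), "empty")
  expect_error(gini_impurity(c(-1, 2)), "non-negative")
  # symmetric under swapping the two categories
  expect_equal(gini_impurity(c(3, 9)), gini_impurity(c(9, 3)))
})

test_that("best_split finds the maximal-loss age boundary with earliest-tie rule", {
  # perfect block separation over distinct ages
  bs <- best_split(c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1), ages = 1:10)
  expect_equal(bs$split_position, 5)
  expect_equal(bs$gini_loss, 0.5)

  # alternating vector: loss 0.1 at positions 1 and 5; earliest reported,
  # both listed as tied (exhaustive evaluation of the 5 candidate splits)
  bs2 <- best_split(c(0, 1, 0, 1, 0, 1), ages = 1:6)
  expect_equal(bs2$split_position, 1)
  expect_equal(bs2$gini_loss, 0.1, tolerance = 1e-12)
  expect_equal(bs2$tied_positions, c(1, 5))

  # within-age splits are not candidates: permuting cells inside an age
  # tie never changes the result
  x <- c(1, 0, 1, 0, 0, 0, 1, 1)
  ages <- c(10, 10, 10, 10, 20, 20, 20, 20)
  ref <- best_split(x, ages)
  set.seed(1)
  for (i in 1:10) {
    p1 <- sample(1:4); p2 <- sample(5:8)
    alt <- best_split(x[c(p1, p2)], ages)
    expect_equal(alt$gini_loss, ref$gini_loss)
    expect_equal(alt$split_position, ref$split_position)
  }

  expect_error(best_split(c(0, 1, 1), ages = c(5, 5, 5)), "one age")
})

test_that("enumeration p values match hand-derived exact fractions", {
  # n=6, k=3: only the two block arrangements achieve the maximal loss 0.5
  expect_equal(monte_carlo_p(6, 3, 1:6, 0.5, mode = "enumerate"), 2 / 20)
  # n=4, k=2
  expect_equal(monte_carlo_p(4, 2, 1:4, 0.5, mode = "enumerate"), 2 / 6)
  # observed loss 0: every arrangement qualifies
  expect_equal(monte_carlo_p(6, 3, 1:6, 0, mode = "enumerate"), 1)
  expect_error(monte_carlo_p(6, 0, 1:6, 0.1), "n_expressed")
  expect_error(monte_carlo_p(6, 6, 1:6, 0.1), "n_expressed")
})

test_that("simulated p values carry the add-one correction and are never zero", {
  p <- monte_carlo_p(8, 4, 1:8, observed_loss = 10, n_sims = 500, seed = 1,
                     mode = "simulate")   # impossible loss: zero exceedances
  expect_equal(p, 1 / 501)
  expect_gt(p, 0)
})

test_that("simulate mode agrees with enumeration within Monte Carlo error", {
  # spot-check a grid of (n, k) at the maximal observed loss; the full
  # n <= 12 sweep runs in the calibration checks
  b <- 20000
  for (n in c(6, 9, 12)) {
    for (k in c(2, floor(n / 2))) {
      obs <- best_split(c(rep(0, n - k), rep(1, k)), 1:n)$gini_loss
      pe <- monte_carlo_p(n, k, 1:n, obs, mode = "enumerate")
      ps <- monte_carlo_p(n, k, 1:n, obs, n_sims = b, seed = n * 100 + k,
                          mode = "simulate")
      tol <- 3 * sqrt(pe * (1 - pe) / b) + 2 / b
      expect_lt(abs(ps - pe), tol + 1e-12)
    }
  }
})

test_that("ties in age are respected by the null (age-block structure)", {
  ages <- c(10, 10, 10, 20, 20, 20)
  # only one candidate split (between the two blocks); maximal loss needs a
  # perfect 3/3 block arrangement: C(6,3)=20 arrangements, 2 achieve it
  x <- c(1, 1, 1, 0, 0, 0)
  bs <- best_split(x, ages)
  expect_equal(bs$gini_loss, 0.5)
  expect_equal(monte_carlo_p(6, 3, ages, 0.5, mode = "enumerate"), 2 / 20)
})

test_that("detect_transitions recovers a planted switch and reports direction", {
  cfg <- simulation_config(
    n_cells_per_type = c(vBC = 40), n_genes = 60,
    transition_spec = tibble::tibble(gene = 5L, onset_age = 21L,
                                     direction = "up", pre_fraction = 0,
                                     post_fraction = 1),
    age_range = c(10L, 40L), dropout_rate = 0.2, seed = 7)
  sim <- simulate_expression(cfg)
  tt <- detect_transitions(sim$dataset, n_sims = 2e4, seed = 2)
  planted <- sim$truth$transitions$gene_symbol[1]
  expect_true(planted %in% tt$gene)
  row <- tt[tt$gene == planted, ]
  expect_equal(row$direction, "up")
  # the split corresponds to the last pre-onset / first post-onset boundary
  n_pre <- sum(sim$dataset$meta$age_days < 21)
  expect_lte(abs(row$split_position - n_pre), 1)
  expect_lt(row$fdr, 0.10)
  expect_lt(row$split_age_before, 21)
  expect_gte(row$split_age_after, 21)

  # results ordered by transition day; all tested genes kept in attribute
  expect_false(is.unsorted(tt$split_age_after))
  expect_gt(nrow(attr(tt, "all_tested")), nrow(tt))
})

test_that("genes below the eligibility bound never reach the output", {
  x <- noise_matrix(10, 30, dropout = 0.3, seed = 14)
  x["g0001", ] <- 0
  x["g0001", 1:5] <- 100   # expressed in 5 cells only
  ds <- toy_dataset(x, sort(sample(10:40, 30, replace = TRUE)))
  tt <- detect_transitions(ds, n_sims = 2000, seed = 1)
  expect_false("g0001" %in% attr(tt, "all_tested")$gene)
})
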