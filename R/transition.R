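#' Binarize expression at a low TPM cutoff
#'
#' A gene is "expressed" in a cell when its TPM is strictly above
#' `cutoff_tpm`. The low default (0.6 TPM) guards against pseudo-alignment
#' occasionally assigning trace expression to absent transcripts.
#'
#' @param ds A `pv_dataset`.
#' @param cutoff_tpm Cutoff (strict `>`; default 0.6).
#' @return A `binary_expression`: logical genes x cells matrix carrying
#'   `cutoff_tpm` and the cells' `age_days` as attributes.
#' @export
binarize <- function(ds, cutoff_tpm = 0.6) {
  stopifnot(inherits(ds, "pv_dataset"))
  bx <- ds$expr > cutoff_tpm
  structure(bx, cutoff_tpm = cutoff_tpm,
            age_days = stats::setNames(ds$meta$age_days, ds$meta$cell_id),
            class = c("binary_expression", "matrix"))
}

#' Genes eligible for transition testing
#'
#' To keep statistical power, genes expressed in fewer than `min_cells`
#' cells, or *not* expressed in fewer than `min_cells` cells, are excluded.
#'
#' @param bx A [binarize()] result (or logical matrix).
#' @param min_cells Minimum count on each side (default 6).
#' @return Tibble with `gene`, `n_expressed`, `n_not_expressed` for
#'   eligible genes.
#' @export
eligible_genes <- function(bx, min_cells = 6) {
  k <- rowSums(bx)
  n <- ncol(bx)
  keep <- k >= min_cells & (n - k) >= min_cells
  tibble::tibble(gene = rownames(bx)[keep],
                 n_expressed = as.integer(k[keep]),
                 n_not_expressed = as.integer(n - k[keep]))
}

#' Gini impurity of a labeled set
#'
#' `1 - sum(p_i^2)` where `p_i` are the category fractions; 0 for a uniform
#' set, at most 0.5 for two categories.
#'
#' @param counts Non-negative category counts (total > 0).
#' @return The impurity.
#' @export
gini_impurity <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) abort("gini impurity of an empty set is undefined")
  p <- counts / total
  1 - sum(p^2)
}

# candidate split structure for an age vector (non-decreasing):
# splits are allowed only between consecutive cells of different age.
# Returns prefix sizes of the candidate splits and the block sizes.
age_split_structure <- function(ages) {
  if (is.unsorted(ages)) abort("ages must be non-decreasing")
  block_sizes <- as.integer(table(factor(ages, levels = unique(ages))))
  prefix <- cumsum(block_sizes)
  list(block_sizes = block_sizes,
       candidate_prefix = prefix[-length(prefix)],
       ages = ages)
}

# Gini loss at each candidate prefix, vectorised over a matrix of
# cumulative expressed counts (one column per candidate split).
# c1: ones in the left part, j: left size, k: total ones, n: total.
gini_loss_at <- function(c1, j, k, n) {
  parent <- 1 - ((k / n)^2 + ((n - k) / n)^2)
  gl <- 1 - ((c1 / j)^2 + ((j - c1) / j)^2)
  c2 <- k - c1
  nr <- n - j
  gr <- 1 - ((c2 / nr)^2 + ((nr - c2) / nr)^2)
  parent - (j * gl + nr * gr) / n
}

#' Best age-split of a binary expression vector
#'
#' Slides over all candidate transition points (positions between
#' consecutive cells of *different* age; within-age splits are disallowed so
#' the statistic does not depend on arbitrary cell order among ties) and
#' returns the split with the largest Gini impurity loss
#' `parent - (n_left * gini_left + n_right * gini_right) / n`.
#' Ties are broken by the earliest position; all tied positions are
#' reported.
#'
#' @param x Logical/0-1 vector of expressed indicators, ordered by age.
#' @param ages Non-decreasing integer ages matching `x`.
#' @return List with `split_position` (cells before the split), `gini_loss`,
#'   `split_age_before`, `split_age_after`, `tied_positions`.
#' @export
best_split <- function(x, ages) {
  x <- as.integer(x)
  if (length(x) < 2) abort("need at least 2 cells")
  if (length(x) != length(ages)) abort("x and ages must have equal length")
  st <- age_split_structure(ages)
  if (!length(st$candidate_prefix)) {
    abort("all cells share one age: no candidate split exists")
  }
  n <- length(x); k <- sum(x)
  cum <- cumsum(x)
  j <- st$candidate_prefix
  loss <- gini_loss_at(cum[j], j, k, n)
  best <- max(loss)
  tied <- j[loss >= best - 1e-12]
  pos <- tied[1]
  list(split_position = pos,
       gini_loss = best,
       split_age_before = ages[pos],
       split_age_after = ages[pos + 1],
       tied_positions = tied)
}

#' P value of an observed Gini loss under random arrangement
#'
#' Null hypothesis: the `n_expressed` expressed cells are a uniformly random
#' subset of the `n_cells` cells (age order fixed). The statistic is the
#' maximal Gini loss over candidate age splits.
#'
#' `mode = "simulate"` draws `n_sims` random arrangements (expressed counts
#' per age block drawn sequentially from hypergeometrics, which samples the
#' sufficient statistic of a uniform arrangement exactly) and applies an
#' add-one correction: `p = (1 + #{loss >= observed}) / (1 + n_sims)`, so
#' simulated p values are never exactly 0. `mode = "enumerate"` computes the
#' exact fraction over all `choose(n, k)` arrangements (feasible for
#' `n_cells <= 20`) with no correction.
#'
#' @param n_cells Total cells.
#' @param n_expressed Expressed cells (`0 < n_expressed < n_cells`).
#' @param ages Non-decreasing ages defining the candidate-split structure.
#' @param observed_loss Observed maximal Gini loss.
#' @param n_sims Simulated arrangements (default 1e5).
#' @param seed Seed for simulate mode.
#' @param mode `"simulate"` or `"enumerate"`.
#' @return The p value.
#' @export
monte_carlo_p <- function(n_cells, n_expressed, ages, observed_loss,
                          n_sims = 1e5, seed = 1L,
                          mode = c("simulate", "enumerate")) {
  mode <- match.arg(mode)
  if (n_expressed <= 0 || n_expressed >= n_cells) {
    abort("n_expressed must satisfy 0 < n_expressed < n_cells")
  }
  if (length(ages) != n_cells) abort("ages must have length n_cells")
  if (mode == "simulate") {
    null_losses <- simulate_null_losses(n_cells, n_expressed, ages, n_sims, seed)
    (1 + sum(null_losses >= observed_loss - 1e-12)) / (1 + n_sims)
  } else {
    enumerate_p(n_cells, n_expressed, ages, observed_loss)
  }
}

# vectorised null draws: counts of expressed cells per age block follow a
# multivariate hypergeometric; draw blocks sequentially with rhyper.
simulate_null_losses <- function(n_cells, n_expressed, ages, n_sims, seed) {
  st <- age_split_structure(ages)
  if (!length(st$candidate_prefix)) abort("no candidate split for these ages")
  bs <- st$block_sizes
  n_blocks <- length(bs)
  with_seed(seed, {
    counts <- matrix(0L, n_sims, n_blocks)
    rem_k <- rep.int(n_expressed, n_sims)
    rem_n <- n_cells
    for (b in seq_len(n_blocks - 1L)) {
      drawn <- rhyper(n_sims, rem_k, rem_n - rem_k, bs[b])
      counts[, b] <- drawn
      rem_k <- rem_k - drawn
      rem_n <- rem_n - bs[b]
    }
    counts[, n_blocks] <- rem_k
    cum <- counts
    for (b in seq_len(n_blocks - 1L)[-1]) cum[, b] <- cum[, b - 1L] + counts[, b]
    if (n_blocks > 1) cum[, n_blocks] <- n_expressed
    j <- st$candidate_prefix
    loss <- gini_loss_at(cum[, seq_along(j), drop = FALSE],
                         matrix(j, n_sims, length(j), byrow = TRUE),
                         n_expressed, n_cells)
    apply(loss, 1, max)
  })
}

# exact p over all C(n, k) arrangements
enumerate_p <- function(n_cells, n_expressed, ages, observed_loss) {
  st <- age_split_structure(ages)
  if (!length(st$candidate_prefix)) abort("no candidate split for these ages")
  combos <- combn(n_cells, n_expressed)
  j <- st$candidate_prefix
  hits <- 0L
  for (i in seq_len(ncol(combos))) {
    x <- integer(n_cells); x[combos[, i]] <- 1L
    cum <- cumsum(x)
    loss <- max(gini_loss_at(cum[j], j, n_expressed, n_cells))
    if (loss >= observed_loss - 1e-12) hits <- hits + 1L
  }
  hits / ncol(combos)
}

#' Detect age-dependent binary expression transitions
#'
#' The full detector: binarize at `cutoff_tpm`, drop ineligible genes, order
#' cells by age, find each gene's best age split by Gini impurity loss,
#' calibrate the loss against a Monte Carlo (or exact) null of random
#' arrangements with the same expressed count and age structure, adjust
#' p values by Benjamini-Hochberg across tested genes, and keep genes below
#' the FDR gate. Null distributions are computed once per distinct expressed
#' count (the age structure is shared) and cached within the call.
#'
#' @param ds A `pv_dataset` whose cells span at least 2 distinct ages.
#' @param cutoff_tpm Expressed cutoff (default 0.6).
#' @param min_cells Eligibility bound (default 6).
#' @param n_sims Null arrangements per expressed count (default 1e5).
#' @param seed Seed for the null simulations.
#' @param fdr_cutoff FDR gate (default 0.10).
#' @param gate `"fdr"` (default) gates on BH-adjusted values, `"p"` on raw
#'   Monte Carlo p values (both are always reported).
#' @param mode `"simulate"` or `"enumerate"` null.
#' @return A `transition_table`: tibble of gene, split_position,
#'   split_age_before, split_age_after, gini_loss, direction, n_expressed,
#'   p_value, fdr, sorted by split age then FDR. The unfiltered table is in
#'   attribute `all_tested`.
#' @export
detect_transitions <- function(ds, cutoff_tpm = 0.6, min_cells = 6,
                               n_sims = 1e5, seed = 1L, fdr_cutoff = 0.10,
                               gate = c("fdr", "p"),
                               mode = c("simulate", "enumerate")) {
  gate <- match.arg(gate)
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "pv_dataset"))
  ord <- order(ds$meta$age_days)
  ages <- ds$meta$age_days[ord]
  if (length(unique(ages)) < 2) abort("cells must span >= 2 distinct ages")
  bx <- binarize(ds, cutoff_tpm)[, ord, drop = FALSE]
  elig <- eligible_genes(bx, min_cells)
  if (!nrow(elig)) {
    warn("no eligible gene for transition testing")
    empty <- tibble::tibble(gene = character(), split_position = integer(),
                            split_age_before = integer(),
                            split_age_after = integer(), gini_loss = numeric(),
                            direction = character(), n_expressed = integer(),
                            p_value = numeric(), fdr = numeric())
    return(structure(empty, all_tested = empty,
                     class = c("transition_table", class(empty))))
  }
  n <- ncol(bx)
  null_cache <- new.env(parent = emptyenv())
  rows <- purrr::map_dfr(seq_len(nrow(elig)), function(i) {
    g <- elig$gene[i]
    x <- as.integer(bx[g, ])
    bs <- best_split(x, ages)
    k <- elig$n_expressed[i]
    p <- if (mode == "simulate") {
      key <- as.character(k)
      if (is.null(null_cache[[key]])) {
        # derive a distinct sub-seed per expressed count
        null_cache[[key]] <- simulate_null_losses(n, k, ages, n_sims,
                                                  seed = seed + k)
      }
      (1 + sum(null_cache[[key]] >= bs$gini_loss - 1e-12)) / (1 + n_sims)
    } else {
      enumerate_p(n, k, ages, bs$gini_loss)
    }
    pre <- mean(x[seq_len(bs$split_position)])
    post <- mean(x[(bs$split_position + 1):n])
    tibble::tibble(gene = g, split_position = bs$split_position,
                   split_age_before = bs$split_age_before,
                   split_age_after = bs$split_age_after,
                   gini_loss = bs$gini_loss,
                   direction = if (post > pre) "up" else "down",
                   n_expressed = k, p_value = p)
  })
  rows$fdr <- stats::p.adjust(rows$p_value, method = "BH")
  keep <- if (gate == "fdr") rows$fdr < fdr_cutoff else rows$p_value < fdr_cutoff
  out <- dplyr::arrange(rows[keep, , drop = FALSE],
                        .data$split_age_after, .data$fdr)
  structure(out, all_tested = rows, cutoff_tpm = cutoff_tpm,
            n_sims = n_sims, mode = mode, gate = gate,
            fdr_cutoff = fdr_cutoff,
            class = c("transition_table", class(out)))
}

#' @export
glance.transition_table <- function(x, ...) {
  tibble::tibble(n_detected = nrow(x),
                 n_up = sum(x$direction == "up"),
                 n_down = sum(x$direction == "down"),
                 n_tested = nrow(attr(x, "all_tested")),
                 fdr_cutoff = attr(x, "fdr_cutoff"),
                 mode = attr(x, "mode"))
}
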