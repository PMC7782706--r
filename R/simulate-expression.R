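#' Build a simulation configuration
#'
#' Defines the generative model for synthetic Patch-seq datasets: log-normal
#' baseline expression with Bernoulli dropout, planted fold-change genes
#' between labeled types, planted binary on/off transition genes at a
#' configurable postnatal age, and an RC-membrane electrophysiology model.
#' Defaults emulate the study conditions of a CA1 PV-interneuron cohort:
#' five PV morphological types plus SST-OLM, ages P10-P77.
#'
#' @param n_cells_per_type Named integer vector, cells per morphological type.
#' @param n_genes Number of genes.
#' @param baseline_log2_mean Mean of per-gene baseline log2 TPM.
#' @param baseline_log2_sd Per-cell log2-scale noise SD around the gene
#'   baseline.
#' @param dropout_rate Probability that a nonzero value is zeroed.
#' @param de_spec Tibble/data frame with columns `gene` (index), `type_a`,
#'   `type_b`, `fold` (> 0): gene's mean in `type_a` is `fold` times its mean
#'   in `type_b`.
#' @param transition_spec Tibble with columns `gene` (index), `onset_age`
#'   (postnatal day), `direction` (`"up"`/`"down"`), `pre_fraction`,
#'   `post_fraction` (expression probabilities strictly before / at-or-after
#'   onset).
#' @param age_range Integer length-2, min and max postnatal day; ages are
#'   sampled uniformly on integer days.
#' @param ephys_spec Named list: `r_in_mohm`, `r_s_mohm`, `c_pf`, logistic
#'   F-I parameters `f_max_hz`, `i0_pa`, `s_pa`, plus AP template
#'   (`ap_amp_mv`, `ap_rise_ms`, `ap_fall_ms`, `ap_trough_mv`),
#'   `sag_mv`, `accommodation` (fractional amplitude decline across the
#'   train at the maximal step), `v_rest_mv`, `noise_sd_mv`.
#' @param seed Integer seed making the whole simulation deterministic.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_cells_per_type = c(vAAC = 7, vBIC = 9, hBIC = 11,
                                                   vBC = 31, hBC = 9, `SST-OLM` = 10),
                              n_genes = 500,
                              baseline_log2_mean = 4,
                              baseline_log2_sd = 0.5,
                              dropout_rate = 0.1,
                              de_spec = NULL,
                              transition_spec = NULL,
                              age_range = c(10L, 77L),
                              ephys_spec = default_ephys_spec(),
                              seed = 1L) {
  if (is.null(names(n_cells_per_type)) || any(!nzchar(names(n_cells_per_type)))) {
    abort("n_cells_per_type must be a named vector of type -> count")
  }
  bad <- setdiff(names(n_cells_per_type), pv_morph_types)
  if (length(bad)) abort(paste0("unknown type(s) in n_cells_per_type: ",
                                paste(bad, collapse = ", ")))
  de_spec <- if (is.null(de_spec)) {
    tibble::tibble(gene = integer(), type_a = character(),
                   type_b = character(), fold = numeric())
  } else tibble::as_tibble(de_spec)
  transition_spec <- if (is.null(transition_spec)) {
    tibble::tibble(gene = integer(), onset_age = integer(),
                   direction = character(), pre_fraction = numeric(),
                   post_fraction = numeric())
  } else tibble::as_tibble(transition_spec)
  if (nrow(de_spec) && (any(de_spec$gene < 1) || any(de_spec$gene > n_genes))) {
    abort("de_spec gene index out of range")
  }
  if (nrow(de_spec) && any(de_spec$fold <= 0)) abort("de_spec folds must be > 0")
  if (nrow(transition_spec)) {
    if (any(transition_spec$gene < 1) || any(transition_spec$gene > n_genes)) {
      abort("transition_spec gene index out of range")
    }
    if (any(transition_spec$pre_fraction < 0 | transition_spec$pre_fraction > 1) ||
        any(transition_spec$post_fraction < 0 | transition_spec$post_fraction > 1)) {
      abort("transition fractions must lie in [0, 1]")
    }
    if (any(transition_spec$onset_age < age_range[1]) ||
        any(transition_spec$onset_age > age_range[2])) {
      abort("transition onset_age must lie within age_range")
    }
  }
  if (dropout_rate < 0 || dropout_rate > 1) abort("dropout_rate must be in [0, 1]")
  overlap <- intersect(de_spec$gene, transition_spec$gene)
  if (length(overlap)) abort("a gene cannot be both a DE and a transition gene")
  structure(list(n_cells_per_type = n_cells_per_type, n_genes = n_genes,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 dropout_rate = dropout_rate, de_spec = de_spec,
                 transition_spec = transition_spec,
                 age_range = as.integer(age_range),
                 ephys_spec = ephys_spec, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default electrophysiology ground truth for the sweep simulator
#' @return Named list of RC, F-I, AP template and sag parameters.
#' @export
default_ephys_spec <- function() {
  list(r_in_mohm = 90, r_s_mohm = 10, c_pf = 150,
       f_max_hz = 100, i0_pa = 200, s_pa = 50,
       ap_amp_mv = 60, ap_rise_ms = 0.4, ap_fall_ms = 0.4,
       ap_trough_mv = -8, sag_mv = 5, accommodation = 0,
       v_rest_mv = -65, noise_sd_mv = 0)
}

#' Simulate an expression dataset with planted ground truth
#'
#' Generates a genes x cells TPM matrix plus metadata. Baseline gene means
#' are log-normal; per-cell values add Gaussian log2 noise; dropout zeroes
#' nonzero values independently. DE genes scale one type's mean by the
#' planted fold; transition genes are expressed (drawn from the gene's
#' log-normal, guaranteed above the 0.6 TPM binarization cutoff) with
#' probability `pre_fraction` before the onset age and `post_fraction`
#' at/after it, independently per cell. Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @return A list with `dataset` (a `pv_dataset`) and `truth` (list with
#'   `de`, `transitions`, `gene_baseline_log2`, per-cell `ages`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    types <- rep(names(config$n_cells_per_type), config$n_cells_per_type)
    n_cells <- length(types)
    cell_ids <- sprintf("cell_%03d", seq_len(n_cells))
    ages <- sample(seq(config$age_range[1], config$age_range[2]),
                   n_cells, replace = TRUE)
    genes <- sprintf("Gene%04d", seq_len(config$n_genes))
    base <- rnorm(config$n_genes, config$baseline_log2_mean, 1)

    # per-type log2 mean matrix, starting from the shared baseline
    mu <- matrix(base, config$n_genes, n_cells)
    if (nrow(config$de_spec)) {
      for (i in seq_len(nrow(config$de_spec))) {
        g <- config$de_spec$gene[i]
        mu[g, types == config$de_spec$type_a[i]] <-
          base[g] + log2(config$de_spec$fold[i])
        mu[g, types == config$de_spec$type_b[i]] <- base[g]
      }
    }
    vals <- 2^(mu + matrix(rnorm(config$n_genes * n_cells, 0, config$baseline_log2_sd),
                           config$n_genes, n_cells))
    if (config$dropout_rate > 0) {
      drop <- matrix(runif(config$n_genes * n_cells) < config$dropout_rate,
                     config$n_genes, n_cells)
      vals[drop] <- 0
    }
    # transition genes: binary on/off, off = 0 TPM, on = lognormal draw
    # clamped above the 0.6 TPM expressed cutoff
    if (nrow(config$transition_spec)) {
      for (i in seq_len(nrow(config$transition_spec))) {
        ts <- config$transition_spec[i, ]
        g <- ts$gene
        # pre_fraction/post_fraction are the expression probabilities before
        # and at/after onset; `direction` is descriptive metadata
        p_on <- ifelse(ages >= ts$onset_age, ts$post_fraction, ts$pre_fraction)
        on <- runif(n_cells) < p_on
        draw <- 2^(base[g] + rnorm(n_cells, 0, config$baseline_log2_sd))
        vals[g, ] <- ifelse(on, pmax(draw, 1), 0)
      }
    }
    dimnames(vals) <- list(genes, cell_ids)
    meta <- validate_metadata(tibble::tibble(
      cell_id = cell_ids, age_days = ages, morph_type = types,
      region = "CA1"))
    truth <- list(
      de = dplyr::mutate(config$de_spec, gene_symbol = genes[.data$gene]),
      transitions = if (nrow(config$transition_spec)) {
        dplyr::mutate(config$transition_spec, gene_symbol = genes[.data$gene])
      } else config$transition_spec,
      gene_baseline_log2 = stats::setNames(base, genes),
      ages = stats::setNames(ages, cell_ids),
      ephys = config$ephys_spec)
    list(dataset = align_dataset(vals, meta), truth = truth)
  })
}
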