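# fixture builders shared across test files

# small dataset with explicit values and ages
toy_dataset <- function(values, ages, morph_type = NULL) {
  meta <- tibble::tibble(cell_id = colnames(values), age_days = ages)
  if (!is.null(morph_type)) meta$morph_type <- morph_type
  suppressMessages(align_dataset(values, meta))
}

# i.i.d. log-normal noise matrix with optional dropout
noise_matrix <- function(n_genes, n_cells, mean_log2 = 4, sd_log2 = 0.5,
                         dropout = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(2^rnorm(n_genes * n_cells, mean_log2, sd_log2), n_genes, n_cells,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("c%04d", seq_len(n_cells))))
  if (dropout > 0) x[matrix(runif(n_genes * n_cells) < dropout,
                            n_genes, n_cells)] <- 0
  x
}

# exact F-I curve from the logistic law, as a fi_curve tibble
logistic_fi <- function(currents, f_max, i0, s) {
  out <- tibble::tibble(i_pa = currents,
                        freq_hz = f_max / (1 + exp(-(currents - i0) / s)),
                        n_spikes = NA_integer_, sweep = NA_character_)
  structure(out, class = c("fi_curve", class(out)))
}
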