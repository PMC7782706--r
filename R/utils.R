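# internal helpers shared across modules

# log2(TPM + 1), the working scale for correlations, tests and SVM weights
log2p1 <- function(x) log2(x + 1)

# run `code` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# unscaled median absolute deviation: median(|x - median(x)|)
mad_unscaled <- function(x) {
  stats::median(abs(x - stats::median(x)))
}

assert_expression_matrix <- function(values, what = "expression matrix") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort(sprintf("%s must be a numeric matrix (genes x cells)", what))
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort(sprintf("%s must carry gene symbols as rownames and cell ids as colnames", what))
  }
  if (anyDuplicated(rownames(values))) {
    abort(sprintf("%s has duplicated gene symbols", what))
  }
  if (anyDuplicated(colnames(values))) {
    abort(sprintf("%s has duplicated cell ids", what))
  }
  if (any(!is.finite(values))) {
    abort(sprintf("%s contains non-finite values", what))
  }
  if (any(values < 0)) {
    abort(sprintf("%s contains negative values; TPM must be >= 0", what))
  }
  invisible(values)
}
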