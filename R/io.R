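#' Read a gene x cell TPM matrix
#'
#' Reads TSV/CSV (genes as rows, first column gene symbols, header = cell
#' ids) or Matrix Market coordinate triplets with sidecar gene/cell label
#' files. Duplicate gene symbols (e.g. several Ensembl ids collapsing to the
#' same symbol) are summed element-wise.
#'
#' @param path Path to the matrix file.
#' @param format One of `"tsv"`, `"csv"`, `"mtx_triplet"`.
#' @param genes_path,cells_path For `mtx_triplet`: one-symbol-per-line and
#'   one-cell-id-per-line sidecar files. Default `<path>.genes` /
#'   `<path>.cells`.
#' @return Numeric genes x cells matrix with unique dimnames, all values
#'   finite and `>= 0`.
#' @export
read_expression <- function(path, format = c("tsv", "csv", "mtx_triplet"),
                            genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format %in% c("tsv", "csv")) {
    delim <- if (format == "tsv") "\t" else ","
    tab <- tryCatch(
      readr::read_delim(path, delim = delim, show_col_types = FALSE,
                        progress = FALSE),
      error = function(e) abort(sprintf("failed to parse %s as %s: %s",
                                        path, format, conditionMessage(e)))
    )
    if (ncol(tab) < 2) abort(sprintf("%s: need a gene column plus >=1 cell column", path))
    genes <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(!vapply(tab[-1], is.numeric, logical(1)))[1]
      abort(sprintf("%s: non-numeric expression column '%s'",
                    path, names(tab)[-1][bad]))
    }
    rownames(vals) <- genes
  } else {
    genes_path <- genes_path %||% paste0(path, ".genes")
    cells_path <- cells_path %||% paste0(path, ".cells")
    for (p in c(genes_path, cells_path)) {
      if (!file.exists(p)) abort(sprintf("mtx sidecar file not found: %s", p))
    }
    genes <- readr::read_lines(genes_path, progress = FALSE)
    cells <- readr::read_lines(cells_path, progress = FALSE)
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) abort(sprintf(
                    "%s: failed to parse Matrix Market file: %s",
                    path, conditionMessage(e))))
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      abort(sprintf("%s: dimensions (%d x %d) disagree with sidecar labels (%d x %d)",
                    path, nrow(m), ncol(m), length(genes), length(cells)))
    }
    vals <- as.matrix(m)
    dimnames(vals) <- list(genes, cells)
  }
  if (any(is.na(vals))) abort(sprintf("%s: missing values in expression matrix", path))
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("%s: negative value at gene '%s', cell '%s'; TPM must be >= 0",
                  path, rownames(vals)[bad[1]], colnames(vals)[bad[2]]))
  }
  vals <- sum_duplicate_genes(vals)
  assert_expression_matrix(vals)
  vals
}

# collapse duplicated gene symbols by element-wise summation
sum_duplicate_genes <- function(values) {
  if (!anyDuplicated(rownames(values))) return(values)
  out <- rowsum(values, group = rownames(values), reorder = FALSE)
  # rowsum reorders on first appearance already with reorder = FALSE
  out
}

#' Write a TPM matrix
#'
#' Inverse of [read_expression()]; values are written in full precision so a
#' read/write round trip reproduces them.
#'
#' @param values Genes x cells matrix.
#' @param path Output file.
#' @param format `"tsv"`, `"csv"` or `"mtx_triplet"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(values, path, format = c("tsv", "csv", "mtx_triplet")) {
  format <- match.arg(format)
  assert_expression_matrix(values)
  if (format %in% c("tsv", "csv")) {
    tab <- tibble::as_tibble(values, rownames = "gene")
    if (format == "tsv") readr::write_tsv(tab, path, progress = FALSE)
    else readr::write_csv(tab, path, progress = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(values, sparse = TRUE), path)
    readr::write_lines(rownames(values), paste0(path, ".genes"))
    readr::write_lines(colnames(values), paste0(path, ".cells"))
  }
  invisible(path)
}

#' Read a cell metadata table
#'
#' Reads a TSV/CSV metadata table and validates it via [validate_metadata()]:
#' enum columns are checked against the allowed vocabulary and `dendro`/`axo`
#' are derived from `morph_type` when absent.
#'
#' @param path Path to the table (delimiter inferred from extension, `.csv`
#'   vs anything else = tab).
#' @return A validated metadata tibble.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  meta <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  validate_metadata(meta)
}

#' Write a cell metadata table
#' @param meta Metadata tibble.
#' @param path Output file (`.csv` for comma, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  meta <- validate_metadata(meta)
  if (grepl("\\.csv$", path)) readr::write_csv(meta, path, progress = FALSE)
  else readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' Write a sweep set to CSV + JSON sidecar
#'
#' One CSV per cell: column 1 = time in ms, remaining columns = sweeps; a
#' JSON sidecar records `sampling_rate_hz` and the protocol (per sweep:
#' type `vc`/`cc`, amplitude in mV/pA, onset/offset in ms).
#'
#' @param sweeps A `sweep_set` (see [simulate_sweeps()]).
#' @param path CSV output path; sidecar written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(sweeps, path) {
  stopifnot(inherits(sweeps, "sweep_set"))
  tab <- tibble::as_tibble(cbind(time_ms = sweeps$time_ms, sweeps$traces))
  readr::write_csv(tab, path, progress = FALSE)
  sidecar <- list(sampling_rate_hz = sweeps$sampling_rate_hz,
                  cell_id = sweeps$cell_id,
                  protocol = sweeps$protocol)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a sweep set written by [write_sweeps()]
#' @param path CSV path; sidecar expected at `<path>.json`.
#' @return A `sweep_set`.
#' @export
read_sweeps <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) abort(sprintf("sidecar not found: %s", side_path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  traces <- as.matrix(tab[, -1, drop = FALSE])
  new_sweep_set(time_ms = tab[[1]], traces = traces,
                sampling_rate_hz = side$sampling_rate_hz,
                protocol = tibble::as_tibble(side$protocol),
                cell_id = side$cell_id %||% NA_character_)
}

new_sweep_set <- function(time_ms, traces, sampling_rate_hz, protocol,
                          cell_id = NA_character_) {
  stopifnot(is.numeric(sampling_rate_hz), sampling_rate_hz > 0)
  if (!all(is.finite(traces))) abort("sweep traces must be finite")
  needed <- c("sweep", "type", "amplitude", "onset_ms", "offset_ms")
  if (!all(needed %in% names(protocol))) {
    abort(paste0("protocol must have columns: ", paste(needed, collapse = ", ")))
  }
  structure(list(time_ms = as.numeric(time_ms), traces = traces,
                 sampling_rate_hz = sampling_rate_hz,
                 protocol = tibble::as_tibble(protocol),
                 cell_id = cell_id),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> cell %s: %d sweeps (%d vc, %d cc), %.0f Hz, %.0f ms\n",
              x$cell_id, nrow(x$protocol),
              sum(x$protocol$type == "vc"), sum(x$protocol$type == "cc"),
              x$sampling_rate_hz, max(x$time_ms)))
  invisible(x)
}
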