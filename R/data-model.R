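#' Morphological type vocabulary
#'
#' The five parvalbumin (PV) morphological types recorded in CA1 plus the
#' SST-OLM control type. PV types factor into a dendritic orientation
#' (vertical/horizontal) and an axonal target class (AAC, BC, BIC).
#'
#' @format A character vector of allowed `morph_type` tokens.
#' @export
pv_morph_types <- c("vAAC", "vBIC", "hBIC", "vBC", "hBC", "SST-OLM",
                    "unclassified")

# decomposition of a PV morph label into dendro / axo components
morph_decomposition <- function(morph_type) {
  lut <- list(
    vAAC = c(dendro = "vertical",   axo = "AAC"),
    vBIC = c(dendro = "vertical",   axo = "BIC"),
    hBIC = c(dendro = "horizontal", axo = "BIC"),
    vBC  = c(dendro = "vertical",   axo = "BC"),
    hBC  = c(dendro = "horizontal", axo = "BC")
  )
  out <- lapply(morph_type, function(m) {
    if (!is.na(m) && m %in% names(lut)) lut[[m]] else c(dendro = NA_character_, axo = NA_character_)
  })
  tibble::tibble(
    dendro = vapply(out, `[[`, character(1), "dendro"),
    axo    = vapply(out, `[[`, character(1), "axo")
  )
}

#' Validate a cell metadata table
#'
#' Checks and completes a per-cell metadata table: enforces unique cell ids,
#' non-negative integer ages, the allowed morphological vocabulary, and
#' derives the dendritic (`dendro`) and axonal (`axo`) components from
#' `morph_type` when absent.
#'
#' @param meta A data frame with at least `cell_id` and `age_days`; optional
#'   `morph_type`, `dendro`, `axo`, `region`, `transcriptomic_type`.
#' @return A tibble with columns `cell_id`, `age_days`, `morph_type`,
#'   `dendro`, `axo`, `region`, `transcriptomic_type`.
#' @export
validate_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  required <- c("cell_id", "age_days")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    abort(paste0("metadata is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  meta$cell_id <- as.character(meta$cell_id)
  if (anyDuplicated(meta$cell_id)) abort("cell_id values must be unique")
  meta$age_days <- as.integer(meta$age_days)
  if (any(is.na(meta$age_days)) || any(meta$age_days < 0)) {
    abort("age_days must be integer and >= 0 (postnatal day)")
  }
  for (col in c("morph_type", "dendro", "axo", "region", "transcriptomic_type")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
    meta[[col]] <- as.character(meta[[col]])
    meta[[col]][!is.na(meta[[col]]) & meta[[col]] == ""] <- NA_character_
  }
  bad <- setdiff(stats::na.omit(unique(meta$morph_type)), pv_morph_types)
  if (length(bad)) {
    abort(paste0("unknown morph_type token(s): ", paste(bad, collapse = ", "),
                 "; allowed: ", paste(pv_morph_types, collapse = ", ")))
  }
  dec <- morph_decomposition(meta$morph_type)
  meta$dendro <- dplyr::coalesce(meta$dendro, dec$dendro)
  meta$axo    <- dplyr::coalesce(meta$axo, dec$axo)
  # consistency: a stated dendro/axo must agree with the morph label
  is_pv <- !is.na(meta$morph_type) &
    meta$morph_type %in% c("vAAC", "vBIC", "hBIC", "vBC", "hBC")
  mism <- is_pv & (meta$dendro != dec$dendro | meta$axo != dec$axo)
  if (any(mism, na.rm = TRUE)) {
    abort(paste0("dendro/axo inconsistent with morph_type for cell(s): ",
                 paste(meta$cell_id[which(mism)], collapse = ", ")))
  }
  bad_region <- setdiff(stats::na.omit(unique(meta$region)), c("CA1", "cortex"))
  if (length(bad_region)) {
    abort(paste0("unknown region token(s): ", paste(bad_region, collapse = ", "),
                 "; allowed: CA1, cortex"))
  }
  dplyr::select(meta, "cell_id", "age_days", "morph_type", "dendro", "axo",
                "region", "transcriptomic_type")
}

#' Align an expression matrix with a cell metadata table
#'
#' Restricts both components to the cells they share and imposes the metadata
#' cell order on the expression matrix (downstream age ordering relies on
#' metadata order). Dropped cell ids are reported via a message.
#'
#' @param expr Numeric genes x cells matrix of TPM with dimnames.
#' @param meta Metadata table accepted by [validate_metadata()].
#' @return A `pv_dataset`: list with elements `expr` (matrix) and `meta`
#'   (tibble), cells matched one-to-one in identical order.
#' @export
align_dataset <- function(expr, meta) {
  assert_expression_matrix(expr)
  meta <- validate_metadata(meta)
  keep <- intersect(meta$cell_id, colnames(expr))
  if (length(keep) == 0L) abort("expression and metadata share no cell ids")
  dropped <- setdiff(union(meta$cell_id, colnames(expr)), keep)
  if (length(dropped)) {
    message(sprintf("align_dataset: dropping %d unmatched cell id(s): %s",
                    length(dropped),
                    paste(head(dropped, 10), collapse = ", ")))
  }
  meta <- meta[meta$cell_id %in% keep, , drop = FALSE]
  expr <- expr[, meta$cell_id, drop = FALSE]
  structure(list(expr = expr, meta = meta), class = "pv_dataset")
}

#' @export
print.pv_dataset <- function(x, ...) {
  cat(sprintf("<pv_dataset> %d genes x %d cells\n", nrow(x$expr), ncol(x$expr)))
  ages <- range(x$meta$age_days)
  cat(sprintf("  ages P%d-P%d; types: %s\n", ages[1], ages[2],
              paste(utils::head(sort(unique(stats::na.omit(x$meta$morph_type))), 8),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.pv_dataset <- function(x) dim(x$expr)
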