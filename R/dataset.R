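#' Single-cell expression dataset
#'
#' A lightweight container pairing a cell-by-gene value matrix with per-cell
#' metadata. Values may be raw counts or depth-normalized, log-transformed
#' expression (see [normalize_counts()]); the `normalized` attribute records
#' which.
#'
#' @param values cell x gene matrix (base matrix or `Matrix` sparse matrix);
#'   rows are cells, columns are genes.
#' @param genes character vector of gene symbols, one per column, no
#'   duplicates.
#' @param cell_meta a data frame with one row per cell and columns `cell_id`,
#'   `donor_id`, `label`, and optionally `split` (one of `"train"`,
#'   `"validation"`, `"test"`).
#' @param normalized logical; `TRUE` if `values` are already depth-normalized
#'   and log-transformed.
#'
#' @return An object of class `sc_dataset`: a list with elements `values`,
#'   `genes`, `cell_meta` (a tibble) and attribute-like field `normalized`.
#' @export
sc_dataset <- function(values, genes, cell_meta, normalized = FALSE) {
  if (anyDuplicated(genes)) {
    abort("Duplicate gene symbols are not allowed.", class = "scprogram_argument")
  }
  if (ncol(values) != length(genes)) {
    abort("`values` must have one column per gene.", class = "scprogram_argument")
  }
  cell_meta <- as_tibble(cell_meta)
  required <- c("cell_id", "donor_id", "label")
  missing_cols <- setdiff(required, names(cell_meta))
  if (length(missing_cols)) {
    abort(sprintf("`cell_meta` is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "scprogram_schema")
  }
  if (nrow(cell_meta) != nrow(values)) {
    abort("`cell_meta` must have one row per cell.", class = "scprogram_argument")
  }
  if (!"split" %in% names(cell_meta)) cell_meta$split <- NA_character_
  if (anyNA(cell_meta$donor_id) || anyNA(cell_meta$label)) {
    abort("Every cell needs a donor and a label.", class = "scprogram_schema")
  }
  structure(
    list(values = values, genes = as.character(genes), cell_meta = cell_meta,
         normalized = isTRUE(normalized)),
    class = "sc_dataset"
  )
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("<sc_dataset> %d cells x %d genes (%s)\n",
              nrow(x$values), length(x$genes),
              if (x$normalized) "normalized" else "counts"))
  cat(sprintf("  donors: %d; labels: %s\n",
              length(unique(x$cell_meta$donor_id)),
              paste(sort(unique(x$cell_meta$label)), collapse = "/")))
  splits <- table(x$cell_meta$split, useNA = "ifany")
  cat("  split:", paste(names(splits), splits, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of cells and genes
#' @param x an `sc_dataset`.
#' @export
dim.sc_dataset <- function(x) dim(x$values)

#' Subset cells by logical or integer index, keeping metadata in step
#' @param data an `sc_dataset`.
#' @param idx logical or integer cell index.
#' @export
subset_cells <- function(data, idx) {
  sc_dataset(data$values[idx, , drop = FALSE], data$genes,
             data$cell_meta[idx, , drop = FALSE], normalized = data$normalized)
}

#' Subset and reorder genes by symbol
#' @param data an `sc_dataset`.
#' @param genes character vector of genes to keep, in the desired order.
#' @export
subset_genes <- function(data, genes) {
  idx <- match(genes, data$genes)
  if (anyNA(idx)) {
    abort(sprintf("Genes not present in dataset: %s.",
                  paste(head(genes[is.na(idx)], 5L), collapse = ", ")),
          class = "scprogram_argument")
  }
  sc_dataset(data$values[, idx, drop = FALSE], genes,
             data$cell_meta, normalized = data$normalized)
}
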