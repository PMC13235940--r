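#' Project cells into gene-program space
#'
#' Computes the program-space representation `X_r = X' S`. When the
#' dataset's gene list differs from the model's, the shared genes are matched
#' via [align_genes()] and the corresponding submatrices of the data and of
#' the loading matrix are used; missing genes contribute nothing. Submatrix
#' rows are not renormalized (set `renormalize = TRUE` to rescale each
#' retained row of S to unit sum).
#'
#' @param data a normalized [sc_dataset()].
#' @param model a `gene_program_fit` (or any list with `gene_list` and
#'   `loading`).
#' @param renormalize rescale the subset loading rows to unit sum.
#' @return cells x d numeric matrix.
#' @export
project_cells <- function(data, model, renormalize = FALSE) {
  stopifnot(inherits(data, "sc_dataset"))
  map <- align_genes(model$gene_list, data$genes)
  S <- model$loading[map$train_idx, , drop = FALSE]
  if (renormalize) S <- S / rowSums(S)
  V <- data$values[, map$other_idx, drop = FALSE]
  Xr <- as.matrix(V %*% S)
  rownames(Xr) <- data$cell_meta$cell_id
  Xr
}

#' Score cells with a trained model
#'
#' Projects cells through the learned loading matrix and applies the trained
#' MLP head in evaluation mode (dropout disabled). Binary scores are
#' sigmoid-transformed logits in \[0, 1\]; multiclass scores are softmax
#' probability vectors; regression returns raw predictions.
#'
#' @param data a normalized [sc_dataset()].
#' @param model a `gene_program_fit`.
#' @param renormalize passed to [project_cells()].
#' @return a `prediction_table` tibble with `cell_id`, `donor_id`, `label`
#'   and `score` (or one `score_<class>` column per class for multiclass).
#' @export
score_cells <- function(data, model, renormalize = FALSE) {
  stopifnot(inherits(model, "gene_program_fit"))
  Xr <- project_cells(data, model, renormalize = renormalize)
  out <- head_forward(model$params, Xr, length(model$config$head_hidden),
                      NULL)$out
  meta <- data$cell_meta
  tbl <- tibble(cell_id = meta$cell_id, donor_id = meta$donor_id,
                label = meta$label)
  if (model$config$task == "binary") {
    tbl$score <- as.numeric(1 / (1 + exp(-out)))
  } else if (model$config$task == "multiclass") {
    P <- exp(out - logsumexp_rows(out))
    colnames(P) <- paste0("score_", model$classes)
    tbl <- bind_cols(tbl, as_tibble(P))
    tbl$score <- P[, ncol(P)]
  } else {
    tbl$score <- as.numeric(out)
  }
  structure(tbl, class = c("prediction_table", class(tbl)))
}

#' Aggregate cell scores to individuals
#'
#' Each individual's prediction score is the unweighted arithmetic mean of
#' the cell-level scores across all of that individual's cells.
#'
#' @param predictions a [score_cells()] table (needs `donor_id` and `score`;
#'   `label` is carried through when present and constant per donor).
#' @return tibble with one row per donor: `donor_id`, `label`, `n_cells`,
#'   `score`.
#' @export
aggregate_donors <- function(predictions) {
  stopifnot(all(c("donor_id", "score") %in% names(predictions)))
  if (anyNA(predictions$donor_id)) {
    abort("Every scored cell needs a donor.", class = "scprogram_schema")
  }
  has_label <- "label" %in% names(predictions)
  out <- predictions |>
    group_by(.data$donor_id) |>
    summarise(
      label = if (has_label) unique(.data$label)[1L] else NA,
      n_cells = n(),
      score = mean(.data$score),
      .groups = "drop"
    )
  out
}

#' Predict method for fitted gene-program models
#'
#' @param object a `gene_program_fit`.
#' @param newdata a normalized [sc_dataset()].
#' @param level `"cell"` for per-cell scores, `"donor"` for individual-level
#'   mean scores.
#' @param ... passed to [score_cells()].
#' @return a prediction tibble (see [score_cells()] / [aggregate_donors()]).
#' @export
predict.gene_program_fit <- function(object, newdata,
                                     level = c("cell", "donor"), ...) {
  level <- match.arg(level)
  cells <- score_cells(newdata, object, ...)
  if (level == "cell") cells else aggregate_donors(cells)
}

#' Write per-cell and per-individual prediction tables
#'
#' @param predictions a [score_cells()] table.
#' @param cell_path,donor_path output TSV paths (either may be `NULL`).
#' @export
write_predictions <- function(predictions, cell_path = NULL,
                              donor_path = NULL) {
  if (!is.null(cell_path)) readr::write_tsv(predictions, cell_path)
  if (!is.null(donor_path)) {
    readr::write_tsv(aggregate_donors(predictions), donor_path)
  }
  invisible(predictions)
}
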