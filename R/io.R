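#' Write an expression dataset as MTX + TSV
#'
#' Writes `matrix.mtx` (cells x genes, MatrixMarket), `genes.tsv` (one
#' column `gene`) and `cells.tsv` (`cell_id`, `donor_id`, `label`, `split`).
#'
#' @param data an [sc_dataset()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "sc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(Matrix::Matrix(data$values, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(gene = data$genes), file.path(dir, "genes.tsv"))
  readr::write_tsv(data$cell_meta, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read an expression dataset from MTX + TSV
#'
#' Counterpart of [write_dataset()].
#'
#' @param dir directory with `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @param normalized whether the stored values are already normalized.
#' @return an [sc_dataset()].
#' @export
read_dataset <- function(dir, normalized = FALSE) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"),
                           show_col_types = FALSE)$gene
  meta <- readr::read_tsv(file.path(dir, "cells.tsv"), show_col_types = FALSE)
  sc_dataset(methods::as(m, "CsparseMatrix"), genes, meta,
             normalized = normalized)
}

#' Save a trained model as a plain-text directory bundle
#'
#' Writes `gene_list.txt`, `loading.tsv`, one `param_<name>.tsv` per weight
#' matrix/vector, `config.yaml`, `classes.txt` and `history.csv`. Everything
#' is plain text so bundles survive text-only archival and are diffable.
#'
#' @param model a `gene_program_fit`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "gene_program_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(model$gene_list, file.path(dir, "gene_list.txt"))
  write_matrix_tsv(model$loading, file.path(dir, "loading.tsv"))
  for (nm in names(model$params)) {
    write_matrix_tsv(as.matrix(model$params[[nm]]),
                     file.path(dir, sprintf("param_%s.tsv", nm)))
  }
  cfg <- model$config
  cfg$head_hidden <- as.list(cfg$head_hidden)
  meta <- list(config = unclass(cfg),
               best_epoch = model$best_epoch, best_val = model$best_val,
               n_train_cells = model$n_train_cells,
               param_names = names(model$params))
  yaml::write_yaml(meta, file.path(dir, "config.yaml"))
  writeLines(as.character(model$classes %||% character(0)),
             file.path(dir, "classes.txt"))
  writeLines(model$validation_cells %||% character(0),
             file.path(dir, "validation_cells.txt"))
  readr::write_csv(model$history, file.path(dir, "history.csv"))
  invisible(dir)
}

#' Load a trained model bundle
#'
#' @param dir a [save_model()] directory.
#' @return a `gene_program_fit`.
#' @export
load_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- meta$config
  cfg$head_hidden <- as.integer(unlist(cfg$head_hidden))
  cfg$w_grid <- if (!is.null(cfg$w_grid)) as.numeric(unlist(cfg$w_grid))
  config <- do.call(train_config, cfg[setdiff(names(cfg), character(0))])
  gene_list <- readLines(file.path(dir, "gene_list.txt"))
  loading <- read_matrix_tsv(file.path(dir, "loading.tsv"))
  rownames(loading) <- gene_list
  params <- lapply(setNames(nm = meta$param_names), function(nm) {
    m <- read_matrix_tsv(file.path(dir, sprintf("param_%s.tsv", nm)))
    if (grepl("^Hb", nm)) as.numeric(m) else m
  })
  classes_raw <- readLines(file.path(dir, "classes.txt"))
  classes <- if (length(classes_raw)) {
    suppressWarnings({
      num <- as.numeric(classes_raw)
      if (anyNA(num)) classes_raw else num
    })
  }
  history <- readr::read_csv(file.path(dir, "history.csv"),
                             show_col_types = FALSE)
  structure(
    list(gene_list = gene_list, loading = loading, params = params,
         config = config, classes = classes, graph_genes = gene_list,
         history = history, best_epoch = meta$best_epoch,
         best_val = meta$best_val, n_train_cells = meta$n_train_cells,
         validation_cells = {
           vf <- file.path(dir, "validation_cells.txt")
           if (file.exists(vf)) readLines(vf) else character(0)
         }),
    class = "gene_program_fit"
  )
}

write_matrix_tsv <- function(m, path) {
  readr::write_tsv(as_tibble(as.data.frame(m), .name_repair = "unique_quiet"),
                   path, col_names = FALSE)
}

read_matrix_tsv <- function(path) {
  m <- as.matrix(readr::read_tsv(path, col_names = FALSE,
                                 show_col_types = FALSE, progress = FALSE))
  dimnames(m) <- NULL
  m
}
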