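#' Depth-normalize and log-transform counts
#'
#' Scales each cell to `target_sum` total counts and applies `log1p`, the
#' standard single-cell normalization. Cells with zero total counts are an
#' error (they carry no information and would divide by zero); the error
#' message names them.
#'
#' @param data an [sc_dataset()] of nonnegative counts.
#' @param target_sum per-cell total after scaling (default 10,000).
#' @return an [sc_dataset()] with `normalized = TRUE`.
#' @export
normalize_counts <- function(data, target_sum = 1e4) {
  stopifnot(inherits(data, "sc_dataset"))
  totals <- if (inherits(data$values, "Matrix")) {
    Matrix::rowSums(data$values)
  } else {
    rowSums(data$values)
  }
  if (any(totals <= 0)) {
    bad <- data$cell_meta$cell_id[totals <= 0]
    abort(sprintf("Cells with zero total counts: %s.",
                  paste(head(bad, 10L), collapse = ", ")),
          class = "scprogram_degenerate")
  }
  if (inherits(data$values, "Matrix")) {
    v <- Matrix::Diagonal(x = target_sum / totals) %*% data$values
    v <- methods::as(v, "CsparseMatrix")
    v@x <- log1p(v@x)
  } else {
    v <- log1p(data$values * (target_sum / totals))
  }
  sc_dataset(v, data$genes, data$cell_meta, normalized = TRUE)
}

#' One-sided Mann-Whitney U test (greater)
#'
#' Tests whether `a` is stochastically greater than `b`. Uses exact
#' enumeration when both groups have at most 8 observations and there are no
#' ties, and the tie-corrected normal approximation (with continuity
#' correction) otherwise.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return list with `statistic` (the U statistic of `a` over `b`) and
#'   `p_value`.
#' @export
mann_whitney_greater <- function(a, b) {
  if (!length(a) || !length(b)) {
    abort("Both groups must be non-empty.", class = "scprogram_argument")
  }
  exact <- length(a) <= 8L && length(b) <= 8L && !anyDuplicated(c(a, b))
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = "greater", exact = exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment with a rejection mask at level `q`.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param q FDR level for the rejection mask.
#' @return list with `adjusted` (monotone BH-adjusted values) and `reject`
#'   (logical, `adjusted <= q`).
#' @export
adjust_bh <- function(p, q = 0.05) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].", class = "scprogram_argument")
  }
  adjusted <- p.adjust(p, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Preselect candidate genes by per-class differential expression
#'
#' For each class, performs one-vs-rest one-sided Mann-Whitney tests (that
#' class stochastically greater) per gene on the training cells, controls the
#' FDR with Benjamini-Hochberg at level `fdr`, ranks the surviving genes by
#' normalized variance (variance of the normalized expression across all
#' training cells, ties broken by gene symbol), truncates to `max_per_class`,
#' and returns the de-duplicated union across classes in stable order (class
#' of first appearance, then rank).
#'
#' @param data a normalized [sc_dataset()]; only cells with `split ==
#'   "train"` (or all cells when no split tags are present) enter the tests.
#' @param fdr BH level (default 0.05).
#' @param max_per_class cap on markers per class (default 1000).
#' @return object of class `marker_selection`: list with `genes` (ordered
#'   character vector) and `stats` (tibble with class, statistic, p, adjusted
#'   p, normalized variance, rank and selection flag per gene and class).
#' @export
select_marker_genes <- function(data, fdr = 0.05, max_per_class = 1000L) {
  stopifnot(inherits(data, "sc_dataset"))
  if (!data$normalized) {
    warn("`data` does not look normalized; marker selection expects depth-normalized, log-transformed values.")
  }
  max_per_class <- assert_count(max_per_class, "max_per_class")
  in_train <- if (all(is.na(data$cell_meta$split))) {
    rep(TRUE, nrow(data$values))
  } else {
    data$cell_meta$split %in% "train"
  }
  labels <- data$cell_meta$label[in_train]
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    abort("Training cells must contain at least two classes.",
          class = "scprogram_argument")
  }
  v <- as.matrix(data$values[in_train, , drop = FALSE])
  norm_var <- apply(v, 2L, var)

  stats_by_class <- lapply(classes, function(cl) {
    in_cl <- labels == cl
    tests <- apply(v, 2L, function(g) {
      ht <- mann_whitney_greater(g[in_cl], g[!in_cl])
      c(ht$statistic, ht$p_value)
    })
    bh <- adjust_bh(tests[2L, ], q = fdr)
    tab <- tibble(
      class = cl, gene = data$genes,
      statistic = tests[1L, ], p = tests[2L, ],
      p_adjusted = bh$adjusted, norm_var = norm_var,
      significant = bh$reject
    )
    sig <- tab[tab$significant, , drop = FALSE]
    sig <- sig[order(-sig$norm_var, sig$gene), , drop = FALSE]
    keep <- head(sig$gene, max_per_class)
    tab$rank <- NA_integer_
    tab$rank[match(sig$gene, tab$gene)] <- seq_len(nrow(sig))
    tab$selected <- tab$gene %in% keep
    tab
  })
  stats <- bind_rows(stats_by_class)
  selected <- unique(unlist(lapply(stats_by_class,
                                   function(t) t$gene[t$selected])))
  if (!length(selected)) {
    abort("No gene passes the marker-selection filter in any class.",
          class = "scprogram_empty_selection")
  }
  structure(list(genes = selected, stats = stats), class = "marker_selection")
}

#' @export
print.marker_selection <- function(x, ...) {
  cat(sprintf("<marker_selection> %d genes across %d classes\n",
              length(x$genes), length(unique(x$stats$class))))
  invisible(x)
}

#' Write per-gene marker statistics as TSV
#' @param x a `marker_selection`.
#' @param path output TSV; the selected gene list itself is written (one
#'   symbol per line) when `gene_list_path` is given.
#' @param gene_list_path optional path for the plain gene list.
#' @export
write_marker_stats <- function(x, path, gene_list_path = NULL) {
  stopifnot(inherits(x, "marker_selection"))
  readr::write_tsv(x$stats, path)
  if (!is.null(gene_list_path)) {
    writeLines(x$genes, gene_list_path)
  }
  invisible(path)
}

#' Align two gene lists
#'
#' Matches the intersection of two duplicate-free gene lists, ordered by the
#' training list, returning the positions in both. Used to project external
#' datasets through a trained loading matrix via the corresponding
#' submatrices.
#'
#' @param train_genes,other_genes character vectors without duplicates.
#' @return tibble with `gene`, `train_idx`, `other_idx`.
#' @export
align_genes <- function(train_genes, other_genes) {
  if (anyDuplicated(train_genes) || anyDuplicated(other_genes)) {
    abort("Gene lists must be duplicate-free.", class = "scprogram_argument")
  }
  shared <- train_genes[train_genes %in% other_genes]
  if (!length(shared)) {
    abort("The gene lists share no genes.", class = "scprogram_empty_overlap")
  }
  tibble(gene = shared,
         train_idx = match(shared, train_genes),
         other_idx = match(shared, other_genes))
}
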