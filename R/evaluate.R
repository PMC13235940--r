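#' Hoyer sparsity of a nonnegative weight vector
#'
#' Scale-invariant concentration measure
#' \deqn{(\sqrt d - \|v\|_1 / \|v\|_2) / (\sqrt d - 1)}
#' in \[0, 1\]: 0 for a uniform vector, 1 for a one-hot vector.
#'
#' @param v nonnegative numeric vector of length >= 2, not all zero.
#' @return scalar in \[0, 1\].
#' @export
hoyer_sparsity <- function(v) {
  d <- length(v)
  if (d < 2L) abort("Hoyer sparsity needs length >= 2.", class = "scprogram_argument")
  if (any(v < 0)) abort("Weights must be nonnegative.", class = "scprogram_argument")
  l2 <- sqrt(sum(v^2))
  if (l2 == 0) abort("All-zero vector.", class = "scprogram_degenerate")
  (sqrt(d) - sum(v) / l2) / (sqrt(d) - 1)
}

#' Extract gene sets from a loading matrix
#'
#' A gene belongs to a program iff its loading for that program strictly
#' exceeds `threshold` (default 0.8, under which each gene joins at most one
#' program). Programs without any member gene are empty.
#'
#' @param S p x d loading matrix with gene rownames, or a `gene_program_fit`.
#' @param threshold membership threshold in (0, 1).
#' @return a `gene_set_collection` tibble with one row per program:
#'   `program`, `genes` (list column), `size`; attribute `threshold` and
#'   `non_empty_count`.
#' @export
extract_gene_sets <- function(S, threshold = 0.8) {
  if (inherits(S, "gene_program_fit")) S <- S$loading
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie in (0, 1).", class = "scprogram_argument")
  }
  genes <- rownames(S) %||% sprintf("g%d", seq_len(nrow(S)))
  sets <- lapply(seq_len(ncol(S)), function(j) genes[S[, j] > threshold])
  out <- tibble(program = seq_len(ncol(S)),
                genes = sets,
                size = lengths(sets))
  attr(out, "threshold") <- threshold
  attr(out, "non_empty_count") <- sum(out$size > 0L)
  class(out) <- c("gene_set_collection", class(out))
  out
}

#' Within-set connectivity
#'
#' Average degree within a gene set on the annotation graph:
#' `2 * edges / genes`, counting an edge between each pair of distinct set
#' members with positive adjacency weight; self-loops are excluded. With
#' `weighted = TRUE` the weighted sum of within-set edges is used instead of
#' the count.
#'
#' @param genes non-empty character vector of set members.
#' @param graph a [gene_graph()].
#' @param weighted use edge weights rather than presence.
#' @return scalar connectivity.
#' @export
connectivity <- function(genes, graph, weighted = FALSE) {
  if (!length(genes)) abort("Empty gene set.", class = "scprogram_argument")
  idx <- match(genes, graph$genes)
  if (anyNA(idx)) {
    abort(sprintf("Unknown gene symbol(s): %s.",
                  paste(head(genes[is.na(idx)], 5L), collapse = ", ")),
          class = "scprogram_argument")
  }
  sub <- graph$A[idx, idx, drop = FALSE]
  Matrix::diag(sub) <- 0
  total <- if (weighted) sum(sub) / 2 else sum(sub > 0) / 2
  2 * total / length(genes)
}

#' Connectivity quantile against same-size random gene sets
#'
#' Samples `n_null` gene sets of the same size uniformly (without
#' replacement within each set) from the graph's gene universe, computes
#' their connectivities, and returns the mid-rank quantile of the observed
#' set's connectivity within this null distribution:
#' `(#{null < C} + 0.5 * #{null == C}) / n_null`.
#'
#' @param genes set members.
#' @param graph a [gene_graph()].
#' @param n_null number of null sets (default 1000).
#' @param seed RNG seed for the null sampling.
#' @param weighted passed to [connectivity()].
#' @return quantile in \[0, 1\].
#' @export
connectivity_quantile <- function(genes, graph, n_null = 1000L, seed = 1L,
                                  weighted = FALSE) {
  n_null <- assert_count(n_null, "n_null")
  if (length(genes) > length(graph$genes)) {
    abort("Set larger than the gene universe.", class = "scprogram_argument")
  }
  c_obs <- connectivity(genes, graph, weighted = weighted)
  set.seed(as.integer(seed))
  null_c <- vapply(seq_len(n_null), function(i) {
    connectivity(sample(graph$genes, length(genes)), graph,
                 weighted = weighted)
  }, numeric(1))
  (sum(null_c < c_obs) + 0.5 * sum(null_c == c_obs)) / n_null
}

#' Rank-based AUC
#'
#' Probability that a uniformly chosen positive outranks a uniformly chosen
#' negative, ties counted one half (equivalently the normalized
#' Mann-Whitney U of the scores).
#'
#' @param scores numeric scores.
#' @param labels binary labels (two distinct values; the larger one is the
#'   positive class).
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, labels) {
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    abort("AUC needs both classes present.", class = "scprogram_argument")
  }
  pos <- labels == classes[2L]
  r <- rank(scores)                         # midranks handle ties
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Match a reference gene set against candidate loadings
#'
#' AUC of a per-gene weight vector as a ranking of membership in a reference
#' set: 1 when the weights separate members perfectly, 0.5 for uninformative
#' weights. `best_match_auc()` scans all columns of a loading matrix and
#' reports the best-matching program.
#'
#' @param reference_set character vector of member genes (non-empty, not the
#'   whole universe).
#' @param loadings named numeric vector of candidate weights covering the
#'   gene universe.
#' @return scalar AUC.
#' @export
loading_match_auc <- function(reference_set, loadings) {
  genes <- names(loadings)
  if (is.null(genes)) {
    abort("`loadings` must be named by gene.", class = "scprogram_argument")
  }
  member <- genes %in% reference_set
  if (!any(member) || all(member)) {
    abort("Reference set must be non-empty and not the whole universe.",
          class = "scprogram_argument")
  }
  rank_auc(loadings, as.integer(member))
}

#' @rdname loading_match_auc
#' @param S loading matrix with gene rownames (or a `gene_program_fit`).
#' @return `best_match_auc()`: list with `program` and `auc`.
#' @export
best_match_auc <- function(reference_set, S) {
  if (inherits(S, "gene_program_fit")) S <- S$loading
  aucs <- vapply(seq_len(ncol(S)), function(j) {
    loading_match_auc(reference_set, setNames(S[, j], rownames(S)))
  }, numeric(1))
  list(program = which.max(aucs), auc = max(aucs))
}

#' Per-program diagnostics table
#'
#' Summarizes a fitted model's gene programs: member count at the threshold,
#' within-set connectivity and its null quantile, and the mean Hoyer sparsity
#' of the member genes' loading rows.
#'
#' @param model a `gene_program_fit`.
#' @param graph a [gene_graph()] containing the model genes.
#' @param threshold membership threshold.
#' @param n_null,seed null-sampling settings for the quantile.
#' @return tibble with `program`, `size`, `connectivity`, `conn_quantile`,
#'   `mean_hoyer`.
#' @export
program_diagnostics <- function(model, graph, threshold = 0.8,
                                n_null = 1000L, seed = 1L) {
  stopifnot(inherits(model, "gene_program_fit"))
  graph <- subset_graph(graph, model$gene_list)
  sets <- extract_gene_sets(model$loading, threshold = threshold)
  hoyer <- apply(model$loading, 1L, hoyer_sparsity)
  rows <- lapply(seq_len(nrow(sets)), function(i) {
    g <- sets$genes[[i]]
    if (!length(g)) {
      return(tibble(program = sets$program[i], size = 0L,
                    connectivity = NA_real_, conn_quantile = NA_real_,
                    mean_hoyer = NA_real_))
    }
    tibble(program = sets$program[i], size = length(g),
           connectivity = connectivity(g, graph),
           conn_quantile = connectivity_quantile(g, graph, n_null = n_null,
                                                 seed = seed),
           mean_hoyer = mean(hoyer[match(g, model$gene_list)]))
  })
  bind_rows(rows)
}

#' Write gene sets in GMT format
#'
#' One line per non-empty program: set name, description, then member genes,
#' tab-separated.
#'
#' @param sets a [extract_gene_sets()] collection.
#' @param path output file.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "gene_program") {
  keep <- sets$size > 0L
  lines <- vapply(which(keep), function(i) {
    paste(c(sprintf("program_%02d", sets$program[i]), description,
            sets$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
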