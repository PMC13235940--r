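#' Tidy a fitted gene-program model
#'
#' One row per gene: the argmax program, its loading, the Hoyer sparsity of
#' the gene's loading row, and whether the gene is assigned to a set at the
#' membership threshold.
#'
#' @param x a `gene_program_fit`.
#' @param threshold membership threshold (default 0.8).
#' @param ... unused.
#' @return a tibble with `gene`, `program`, `loading`, `hoyer`, `assigned`.
#' @export
tidy.gene_program_fit <- function(x, threshold = 0.8, ...) {
  S <- x$loading
  best <- max.col(S, ties.method = "first")
  tibble(
    gene = x$gene_list,
    program = best,
    loading = S[cbind(seq_len(nrow(S)), best)],
    hoyer = apply(S, 1L, hoyer_sparsity),
    assigned = S[cbind(seq_len(nrow(S)), best)] > threshold
  )
}

#' One-row model summary
#'
#' @param x a `gene_program_fit`.
#' @param threshold membership threshold for the non-empty program count.
#' @param ... unused.
#' @return one-row tibble with gene/program counts, non-empty programs,
#'   training length, best epoch and validation metric, final loss terms and
#'   mean row Hoyer sparsity.
#' @export
glance.gene_program_fit <- function(x, threshold = 0.8, ...) {
  sets <- extract_gene_sets(x$loading, threshold = threshold)
  last <- x$history[nrow(x$history), ]
  tibble(
    n_genes = length(x$gene_list),
    d = ncol(x$loading),
    w = x$config$w,
    non_empty_programs = attr(sets, "non_empty_count"),
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val = x$best_val,
    l_c = last$l_c,
    l_o = last$l_o,
    mean_hoyer = mean(apply(x$loading, 1L, hoyer_sparsity))
  )
}

#' Plot the training history of a fit
#'
#' Loss components and validation metric per epoch.
#'
#' @param object a `gene_program_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gene_program_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL,
                  title = "Training history",
                  subtitle = sprintf("best validation at epoch %d",
                                     object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' Plot a graph-loss weight sweep
#'
#' Validation metric, non-empty program count and mean connectivity quantile
#' against `w`.
#'
#' @param object a [sweep_w()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.w_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("w", "val_metric", "non_empty", "mean_conn_quantile")],
    -"w", names_to = "diagnostic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$w, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~diagnostic, scales = "free_y") +
    ggplot2::labs(x = "graph-loss weight w", y = NULL,
                  title = "Weight-sweep diagnostics") +
    ggplot2::theme_minimal()
}

#' Plot cell-score distributions by donor label
#'
#' Histogram of cell-level prediction scores stratified by the donor-level
#' class, the standard diagnostic for score separation.
#'
#' @param predictions a [score_cells()] table.
#' @param bins histogram bins.
#' @return a ggplot.
#' @export
plot_score_distribution <- function(predictions, bins = 30L) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$score,
                               fill = factor(.data$label))) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "cell-level prediction score", fill = "label",
                  title = "Cell score distribution by donor label") +
    ggplot2::theme_minimal()
}
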