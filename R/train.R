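#' Training configuration
#'
#' Hyperparameters of the joint gene-program / classifier fit. Defaults match
#' the reference settings: graph-loss weight `w = 2`, Adam with learning rate
#' 1e-4 and weight decay 1e-4, at most 50,000 and at least 10,000 epochs with
#' early stopping after 3,000 epochs without validation improvement, dropout
#' 0.5, 10% of training cells reserved for validation, `d = 40` gene
#' programs, two graph-convolution layers of `h = 64` units and an MLP head
#' of three 64-unit hidden layers. Desk-scale runs shrink the epoch budget
#' via `max_epochs`/`min_epochs`.
#'
#' @param w weight on the unsupervised graph losses.
#' @param learning_rate,weight_decay Adam settings.
#' @param max_epochs,min_epochs,patience_epochs early-stopping schedule:
#'   training stops after `max_epochs`, or once the validation metric has not
#'   improved for `patience_epochs` after at least `min_epochs`.
#' @param dropout_p dropout probability after MLP hidden layers.
#' @param validation_fraction fraction of training cells reserved for
#'   validation when the data carry no validation tags.
#' @param d number of gene programs.
#' @param h hidden units per graph-convolution layer.
#' @param head_hidden hidden-layer sizes of the MLP head.
#' @param seed master seed for initialization, validation split and dropout.
#' @param task `"binary"`, `"multiclass"` or `"regression"`.
#' @param w_grid optional grid for [sweep_w()].
#' @param ortho_target orthogonality-loss target, see [mincut_losses()].
#' @param early_stopping_metric `"classification"` (validation classification
#'   loss; the graph terms are cell-independent) or `"total"`.
#' @param log_every message the loss terms every `log_every` epochs
#'   (0 = silent).
#' @return a `train_config` list.
#' @export
train_config <- function(w = 2, learning_rate = 1e-4, weight_decay = 1e-4,
                         max_epochs = 50000L, min_epochs = 10000L,
                         patience_epochs = 3000L, dropout_p = 0.5,
                         validation_fraction = 0.1, d = 40L, h = 64L,
                         head_hidden = c(64L, 64L, 64L), seed = 1L,
                         task = c("binary", "multiclass", "regression"),
                         w_grid = NULL,
                         ortho_target = c("scaled", "identity"),
                         early_stopping_metric = c("classification", "total"),
                         log_every = 0L) {
  task <- match.arg(task)
  ortho_target <- match.arg(ortho_target)
  early_stopping_metric <- match.arg(early_stopping_metric)
  max_epochs <- assert_count(max_epochs, "max_epochs")
  min_epochs <- assert_count(min_epochs, "min_epochs", min = 0L)
  patience_epochs <- assert_count(patience_epochs, "patience_epochs")
  if (min_epochs > max_epochs) {
    abort("`min_epochs` must not exceed `max_epochs`.",
          class = "scprogram_argument")
  }
  assert_fraction(dropout_p, "dropout_p")
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    abort("`validation_fraction` must be in (0, 1).", class = "scprogram_argument")
  }
  if (w < 0) abort("`w` must be nonnegative.", class = "scprogram_argument")
  structure(
    list(w = w, learning_rate = learning_rate, weight_decay = weight_decay,
         max_epochs = max_epochs, min_epochs = min_epochs,
         patience_epochs = patience_epochs, dropout_p = dropout_p,
         validation_fraction = validation_fraction,
         d = assert_count(d, "d"), h = assert_count(h, "h"),
         head_hidden = as.integer(head_hidden), seed = as.integer(seed),
         task = task, w_grid = w_grid, ortho_target = ortho_target,
         early_stopping_metric = early_stopping_metric,
         log_every = assert_count(log_every, "log_every", min = 0L)),
    class = "train_config"
  )
}

#' Reserve validation cells within the training split
#'
#' Tags a label-stratified random fraction of the `train` cells as
#' `validation`; cells tagged `test` (or anything else) are untouched.
#' Deterministic given `seed`. Stratification is by class label; disable it
#' for continuous outcomes.
#'
#' @param data an [sc_dataset()].
#' @param fraction validation fraction of the training cells.
#' @param seed RNG seed.
#' @param stratify stratify by label (default) or split at random.
#' @return the dataset with updated `split` tags.
#' @export
split_validation <- function(data, fraction = 0.1, seed = 1L,
                             stratify = TRUE) {
  stopifnot(inherits(data, "sc_dataset"))
  assert_fraction(fraction, "fraction")
  meta <- data$cell_meta
  train_idx <- if (all(is.na(meta$split))) {
    seq_len(nrow(meta))
  } else {
    which(meta$split %in% "train")
  }
  if (length(train_idx) < 10L) {
    abort("Need at least 10 training cells to reserve validation data.",
          class = "scprogram_argument")
  }
  meta$split[is.na(meta$split)] <- "train"
  set.seed(as.integer(seed))
  groups <- if (stratify) {
    split(train_idx, meta$label[train_idx])
  } else {
    list(all = train_idx)
  }
  for (cl in names(groups)) {
    cls_idx <- groups[[cl]]
    n_val <- round(fraction * length(cls_idx))
    if (n_val == 0L) {
      warn(sprintf("Group '%s' received no validation cells.", cl))
      next
    }
    meta$split[sample(cls_idx, n_val)] <- "validation"
  }
  sc_dataset(data$values, data$genes, meta, normalized = data$normalized)
}

# Map raw labels to the representation the loss expects, remembering levels.
encode_labels <- function(labels, task) {
  if (task == "regression") {
    return(list(y = as.numeric(labels), classes = NULL))
  }
  classes <- sort(unique(labels))
  if (task == "binary") {
    if (length(classes) != 2L) {
      abort("Binary task needs exactly two label classes.",
            class = "scprogram_argument")
    }
    list(y = as.numeric(match(labels, classes) - 1L), classes = classes)
  } else {
    list(y = as.integer(match(labels, classes)), classes = classes)
  }
}

#' Jointly fit gene programs and the cell classifier
#'
#' Full-batch joint optimization of the graph-convolutional encoder, the
#' softmax-pooled loading matrix and the MLP head under the objective
#' `L_clf + w * (L_c + L_o)`. Gene node features are the expression of the
#' training-split cells only; validation cells are scored through the current
#' loading matrix and head each epoch for early stopping, and parameters are
#' restored to the best-validation epoch.
#'
#' @param data a normalized [sc_dataset()] restricted to the candidate genes;
#'   cells must carry `train`/`validation` split tags (a validation split is
#'   drawn via [split_validation()] when absent).
#' @param graph a [gene_graph()]; must contain all data genes. The graph is
#'   subset and renormalized to the data's gene list.
#' @param config a [train_config()].
#' @return an object of class `gene_program_fit` with elements `gene_list`,
#'   `loading` (the p x d matrix S at the best epoch), `params`, `config`,
#'   `classes`, `history` (per-epoch loss tibble), `best_epoch`, `best_val`
#'   and `validation_cells` (the cell IDs used for early stopping).
#' @export
fit_gene_programs <- function(data, graph, config = train_config()) {
  stopifnot(inherits(data, "sc_dataset"), inherits(graph, "gene_graph"),
            inherits(config, "train_config"))
  if (!data$normalized) {
    warn("Fitting on values that do not look depth-normalized/log-transformed.")
  }
  graph <- subset_graph(graph, data$genes)
  seeds <- substream_seeds(config$seed, 3L)
  if (!any(data$cell_meta$split %in% "validation")) {
    data <- split_validation(data, config$validation_fraction, seeds[1L],
                             stratify = config$task != "regression")
  }
  meta <- data$cell_meta
  tr <- which(meta$split %in% "train")
  va <- which(meta$split %in% "validation")
  if (!length(tr) || !length(va)) {
    abort("Need both training and validation cells.", class = "scprogram_argument")
  }
  enc_tr <- encode_labels(meta$label[tr], config$task)
  y_tr <- enc_tr$y
  y_va <- if (config$task == "regression") as.numeric(meta$label[va]) else {
    stats_idx <- match(meta$label[va], enc_tr$classes)
    if (anyNA(stats_idx)) {
      abort("Validation labels outside the training classes.",
            class = "scprogram_argument")
    }
    if (config$task == "binary") as.numeric(stats_idx - 1L) else as.integer(stats_idx)
  }
  n_out <- switch(config$task,
                  binary = 1L, regression = 1L,
                  multiclass = length(enc_tr$classes))
  X <- t(as.matrix(data$values[tr, , drop = FALSE]))   # p x n, training cells
  Xva <- as.matrix(data$values[va, , drop = FALSE])    # n_val x p
  p <- nrow(X); n <- ncol(X)
  XA <- as.matrix(graph$A_norm %*% X)
  n_hidden <- length(config$head_hidden)

  set.seed(seeds[2L])
  params <- init_params(n, config$h, config$d, config$head_hidden, n_out)
  state <- adam_init(params)

  set.seed(seeds[3L])                       # dropout stream
  keep <- 1 - config$dropout_p
  best_val <- Inf
  best_epoch <- 0L
  best_params <- params
  hist_cols <- c("l_clf", "l_c", "l_o", "total", "val_loss")
  history <- matrix(NA_real_, config$max_epochs, length(hist_cols),
                    dimnames = list(NULL, hist_cols))

  for (epoch in seq_len(config$max_epochs)) {
    enc <- encoder_forward(params, X, XA, graph$A_norm)
    Xr <- crossprod(X, enc$S)               # n x d
    masks <- if (config$dropout_p > 0) {
      lapply(config$head_hidden, function(hh) {
        matrix((runif(n * hh) < keep) / keep, n, hh)
      })
    }
    head <- head_forward(params, Xr, n_hidden, masks)
    l_clf <- classification_loss(head$out, y_tr, config$task)
    ml <- mincut_losses(enc$S, graph, config$ortho_target)
    total <- l_clf + config$w * (ml$l_c + ml$l_o)
    if (!is.finite(total)) {
      abort(sprintf("Non-finite loss at epoch %d (l_clf=%g, l_c=%g, l_o=%g).",
                    epoch, l_clf, ml$l_c, ml$l_o),
            class = "scprogram_nonfinite")
    }

    # validation before the step: project validation cells through the same
    # loading matrix, score with the same head, dropout disabled
    val_head <- head_forward(params, Xva %*% enc$S, n_hidden, NULL)
    val_clf <- classification_loss(val_head$out, y_va, config$task)
    val_metric <- if (config$early_stopping_metric == "classification") {
      val_clf
    } else {
      val_clf + config$w * (ml$l_c + ml$l_o)
    }
    history[epoch, ] <- c(l_clf, ml$l_c, ml$l_o, total, val_metric)
    if (config$log_every > 0L && epoch %% config$log_every == 0L) {
      message(sprintf(
        "epoch %d: l_clf=%.4f l_c=%.4f l_o=%.4f total=%.4f val=%.4f",
        epoch, l_clf, ml$l_c, ml$l_o, total, val_metric))
    }
    if (val_metric < best_val) {
      best_val <- val_metric
      best_epoch <- epoch
      best_params <- params
    }
    if (epoch >= config$min_epochs &&
        (epoch - best_epoch) >= config$patience_epochs) {
      break
    }
    grads <- backward_pass(params, enc, head, X, XA, graph$A_norm, Xr, y_tr,
                           config$task, config$w, graph, n_hidden, masks,
                           config$ortho_target)
    st <- adam_step(params, grads, state, config$learning_rate,
                    config$weight_decay, epoch)
    params <- st$params; state <- st$state
  }
  n_run <- epoch
  enc_best <- encoder_forward(best_params, X, XA, graph$A_norm)
  S <- enc_best$S
  rownames(S) <- data$genes

  structure(
    list(gene_list = data$genes, loading = S, params = best_params,
         config = config, classes = enc_tr$classes, graph_genes = graph$genes,
         history = as_tibble(cbind(epoch = seq_len(n_run),
                                   history[seq_len(n_run), , drop = FALSE])),
         best_epoch = best_epoch, best_val = best_val,
         n_train_cells = n,
         validation_cells = meta$cell_id[va]),
    class = "gene_program_fit"
  )
}

#' @export
print.gene_program_fit <- function(x, ...) {
  cat(sprintf("<gene_program_fit> %d genes -> %d programs (w = %g, task = %s)\n",
              length(x$gene_list), ncol(x$loading), x$config$w, x$config$task))
  cat(sprintf("  trained %d epochs; best validation %s = %.4f at epoch %d\n",
              nrow(x$history), x$config$early_stopping_metric, x$best_val,
              x$best_epoch))
  invisible(x)
}

# Subset a graph to an ordered gene list and renormalize.
subset_graph <- function(graph, genes) {
  if (identical(graph$genes, genes)) return(graph)
  idx <- match(genes, graph$genes)
  if (anyNA(idx)) {
    abort(sprintf("Genes missing from the graph: %s.",
                  paste(head(genes[is.na(idx)], 5L), collapse = ", ")),
          class = "scprogram_argument")
  }
  gene_graph(graph$A[idx, idx, drop = FALSE], genes, add_self_loops = FALSE)
}

#' Fit over a grid of graph-loss weights
#'
#' Refits the model for each `w` in the grid, recording the best validation
#' metric, the number of non-empty gene programs at the membership threshold,
#' and the mean within-set connectivity quantile — the diagnostics used to
#' choose `w`.
#'
#' @param data,graph,config as in [fit_gene_programs()].
#' @param w_grid numeric grid; defaults to `config$w_grid` or
#'   `c(0, 0.25, 0.5, 1, 2, 5, 10)`.
#' @param threshold membership threshold for gene-set extraction.
#' @param n_null null draws per connectivity quantile.
#' @param keep_models keep each fitted model in the result.
#' @return a `w_sweep` tibble with one row per `w`: `w`, `val_metric`,
#'   `non_empty`, `mean_conn_quantile`, `best_epoch` (+ `model` list column
#'   when `keep_models`).
#' @export
sweep_w <- function(data, graph, config = train_config(), w_grid = NULL,
                    threshold = 0.8, n_null = 1000L, keep_models = FALSE) {
  w_grid <- w_grid %||% config$w_grid %||% c(0, 0.25, 0.5, 1, 2, 5, 10)
  rows <- lapply(w_grid, function(wi) {
    cfg <- config
    cfg$w <- wi
    fit <- fit_gene_programs(data, graph, cfg)
    sets <- extract_gene_sets(fit$loading, threshold = threshold)
    occupied <- sets$size > 0L
    cq <- if (any(occupied)) {
      mean(map_dbl(sets$genes[occupied], function(g) {
        connectivity_quantile(g, subset_graph(graph, fit$gene_list),
                              n_null = n_null, seed = cfg$seed)
      }))
    } else {
      NA_real_
    }
    out <- tibble(w = wi, val_metric = fit$best_val,
                  non_empty = sum(occupied), mean_conn_quantile = cq,
                  best_epoch = fit$best_epoch)
    if (keep_models) out$model <- list(fit)
    out
  })
  structure(bind_rows(rows), class = c("w_sweep", "tbl_df", "tbl", "data.frame"))
}

#' Choose the graph-loss weight from a sweep
#'
#' Returns the smallest `w` whose validation metric (lower is better) lies
#' within `tolerance` of the best observed value, together with the
#' diagnostics table. This favours the least-regularized model that is still
#' competitive while the graph diagnostics have stabilized.
#'
#' @param sweep a [sweep_w()] result (or any data frame with `w` and
#'   `val_metric`).
#' @param tolerance absolute tolerance band around the best metric.
#' @return list with `w` (the recommendation) and `table`.
#' @export
select_w <- function(sweep, tolerance = 0.02) {
  tbl <- as_tibble(sweep)
  if (!nrow(tbl)) abort("Empty sweep.", class = "scprogram_argument")
  best <- min(tbl$val_metric)
  ok <- tbl$w[tbl$val_metric <= best + tolerance]
  list(w = min(ok), table = tbl)
}
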