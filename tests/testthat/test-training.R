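test_that("validation split is stratified, deterministic and size-correct", {
  meta <- data.frame(cell_id = sprintf("c%03d", 1:100),
                     donor_id = rep(sprintf("d%d", 1:10), each = 10),
                     label = rep(c(0, 1), each = 50))
  data <- sc_dataset(matrix(rpois(100 * 5, 5), 100, 5), sprintf("G%d", 1:5),
                     meta)
  sp <- split_validation(data, fraction = 0.1, seed = 3)
  expect_equal(sum(sp$cell_meta$split == "validation"), 10)
  tab <- table(sp$cell_meta$label[sp$cell_meta$split == "validation"])
  expect_equal(unname(c(tab)), c(5, 5))
  sp2 <- split_validation(data, fraction = 0.1, seed = 3)
  expect_identical(sp$cell_meta$split, sp2$cell_meta$split)
  # test-tagged cells are never recruited
  meta2 <- meta; meta2$split <- rep(c("train", "test"), 50)
  data2 <- sc_dataset(data$values, data$genes, meta2)
  sp3 <- split_validation(data2, 0.2, seed = 1)
  expect_true(all(sp3$cell_meta$split[meta2$split == "test"] == "test"))
  # a class too small to contribute validation cells warns, not errors
  meta3 <- meta; meta3$label <- c(rep(0, 98), 1, 1)
  data3 <- sc_dataset(data$values, data$genes, meta3)
  expect_warning(split_validation(data3, 0.1, seed = 1), regexp = "validation")
})

test_that("training is deterministic and reduces the classification loss", {
  dat <- small_training_data(seed = 7, n_genes = 60, n_modules = 3,
                             module_size = 10, n_donors_per_class = 4,
                             cells_per_donor = 8)
  mk <- select_marker_genes(dat$norm)
  sub <- subset_genes(dat$norm, mk$genes)
  cfg <- quick_config(seed = 5, max_epochs = 250, min_epochs = 200,
                      patience_epochs = 100)
  f1 <- fit_gene_programs(sub, dat$sim$graph, cfg)
  f2 <- fit_gene_programs(sub, dat$sim$graph, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loading, f2$loading)

  # descent contract on separable data
  expect_lt(f1$history$l_clf[nrow(f1$history)], f1$history$l_clf[1])
  # loading invariants
  expect_equal(rowSums(f1$loading), rep(1, length(f1$gene_list)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(length(f1$gene_list), nrow(f1$loading))
})

test_that("early stopping respects min_epochs and restores the best epoch", {
  dat <- small_training_data(seed = 3, n_genes = 50, n_modules = 2,
                             module_size = 10, n_donors_per_class = 3,
                             cells_per_donor = 6)
  sub <- subset_genes(dat$norm, dat$sim$truth$gene[1:30])
  cfg <- train_config(d = 5, h = 16, max_epochs = 400, min_epochs = 150,
                      patience_epochs = 20, learning_rate = 5e-3, seed = 2)
  fit <- fit_gene_programs(sub, dat$sim$graph, cfg)
  n_run <- nrow(fit$history)
  expect_gte(n_run, 150)
  # stopped only after patience exhausted (or at the cap)
  if (n_run < 400) expect_gte(n_run - fit$best_epoch, 20)
  expect_equal(min(fit$history$val_loss), fit$best_val)
  expect_equal(which.min(fit$history$val_loss), fit$best_epoch)

  # restored parameters reproduce the recorded best validation loss exactly
  expect_gt(length(fit$validation_cells), 0)
  va <- subset_cells(sub, sub$cell_meta$cell_id %in% fit$validation_cells)
  Xr <- project_cells(va, fit)
  out <- scprogram:::head_forward(fit$params, Xr,
                                  length(fit$config$head_hidden), NULL)$out
  y <- as.numeric(factor(va$cell_meta$label)) - 1
  expect_equal(classification_loss(out, y, "binary"), fit$best_val,
               tolerance = 1e-8)
})

test_that("a w grid runs end-to-end and records per-w diagnostics", {
  dat <- small_training_data(seed = 11, n_genes = 60, n_modules = 3,
                             module_size = 10, n_donors_per_class = 3,
                             cells_per_donor = 6)
  mk <- select_marker_genes(dat$norm)
  sub <- subset_genes(dat$norm, mk$genes)
  cfg <- train_config(d = 5, h = 16, max_epochs = 120, min_epochs = 100,
                      patience_epochs = 50, learning_rate = 2e-3, seed = 4)
  grid <- c(0, 0.25, 0.5, 1, 2, 5, 10)
  sweep <- sweep_w(sub, dat$sim$graph, cfg, w_grid = grid, n_null = 100)
  expect_equal(sweep$w, grid)
  expect_true(all(is.finite(sweep$val_metric)))
  expect_true(all(sweep$non_empty >= 0 & sweep$non_empty <= 5))
  expect_true(all(is.na(sweep$mean_conn_quantile) |
                    (sweep$mean_conn_quantile >= 0 &
                       sweep$mean_conn_quantile <= 1)))
})

test_that("multiclass and regression heads train and score coherently", {
  set.seed(31)
  n <- 90; p <- 12
  classes <- rep(0:2, each = n / 3)
  vals <- matrix(rnorm(n * p), n, p)
  for (k in 0:2) vals[classes == k, k * 3 + 1:3] <- vals[classes == k, k * 3 + 1:3] + 2.5
  meta <- data.frame(cell_id = sprintf("c%d", 1:n),
                     donor_id = sprintf("d%d", rep(1:9, 10)),
                     label = classes)
  data <- sc_dataset(exp(vals), sprintf("G%02d", 1:p), meta)
  norm <- normalize_counts(data)
  g <- gene_graph(diag(p), norm$genes, add_self_loops = FALSE)
  cfg <- train_config(d = 4, h = 8, task = "multiclass", max_epochs = 200,
                      min_epochs = 150, patience_epochs = 50,
                      learning_rate = 2e-3, seed = 2)
  fit <- fit_gene_programs(norm, g, cfg)
  expect_lt(fit$history$l_clf[nrow(fit$history)], fit$history$l_clf[1])
  preds <- score_cells(norm, fit)
  probs <- as.matrix(preds[paste0("score_", 0:2)])
  expect_equal(rowSums(probs), rep(1, n), tolerance = 1e-8,
               ignore_attr = TRUE)
  # the modal predicted class tracks the planted one on training data
  expect_gt(mean((max.col(probs) - 1) == classes), 0.8)

  meta_r <- meta; meta_r$label <- rowSums(vals[, 1:3]) + rnorm(n, sd = 0.1)
  data_r <- sc_dataset(exp(vals), sprintf("G%02d", 1:p), meta_r)
  cfg_r <- train_config(d = 4, h = 8, task = "regression", max_epochs = 200,
                        min_epochs = 150, patience_epochs = 50,
                        learning_rate = 2e-3, seed = 2)
  fit_r <- fit_gene_programs(normalize_counts(data_r), g, cfg_r)
  expect_lt(fit_r$history$l_clf[nrow(fit_r$history)],
            fit_r$history$l_clf[1])
  expect_true(all(is.finite(predict(fit_r, normalize_counts(data_r))$score)))
})

test_that("select_w applies the smallest-within-tolerance rule", {
  tie <- tibble::tibble(w = c(0, 1, 2), val_metric = c(0.3, 0.3, 0.3))
  expect_equal(select_w(tie)$w, 0)
  dominant <- tibble::tibble(w = c(0, 1, 2), val_metric = c(0.5, 0.2, 0.5))
  expect_equal(select_w(dominant)$w, 1)
  plateau <- tibble::tibble(w = c(0, 0.5, 1, 2, 5),
                            val_metric = c(0.40, 0.35, 0.21, 0.205, 0.22))
  expect_equal(select_w(plateau, tolerance = 0.02)$w, 1)
  expect_error(select_w(tibble::tibble(w = numeric(0),
                                       val_metric = numeric(0))),
               class = "scprogram_argument")
})

test_that("with w = 0 and an identity graph, the fit is a softmax-pooled MLP", {
  dat <- small_training_data(seed = 5, n_genes = 40, n_modules = 2,
                             module_size = 10, n_donors_per_class = 3,
                             cells_per_donor = 6)
  sub <- subset_genes(dat$norm, dat$sim$truth$gene[1:25])
  idg <- gene_graph(diag(25), sub$genes, add_self_loops = FALSE)
  cfg <- train_config(d = 4, h = 8, max_epochs = 150, min_epochs = 100,
                      patience_epochs = 50, learning_rate = 5e-3, seed = 6,
                      w = 0)
  fit <- fit_gene_programs(sub, idg, cfg)
  # graph losses are recorded but do not enter the optimized total
  expect_equal(fit$history$total, fit$history$l_clf, tolerance = 1e-12)
  expect_true(all(is.finite(fit$history$l_c)))
  expect_lt(fit$history$l_clf[nrow(fit$history)], fit$history$l_clf[1])

  # with an identity graph the encoder collapses to a plain dense MLP over
  # gene features: recompute the loading matrix with base matrix products
  X <- t(as.matrix(sub$values[sub$cell_meta$cell_id %in%
                                setdiff(sub$cell_meta$cell_id[
                                  sub$cell_meta$split == "train"],
                                  fit$validation_cells), , drop = FALSE]))
  pm <- fit$params
  H1 <- pmax(X %*% pm$W1 + X %*% pm$W1s, 0)
  H2 <- pmax(H1 %*% pm$W2 + H1 %*% pm$W2s, 0)
  L <- H2 %*% pm$WH
  S_manual <- exp(L - apply(L, 1, max))
  S_manual <- S_manual / rowSums(S_manual)
  expect_equal(unname(fit$loading), unname(S_manual), tolerance = 1e-10)
})
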