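# Full pipeline on the planted-module study fixture: simulate, depth-
# normalize, preselect markers, fit. Desk-scale schedule: 2,000 epochs at
# learning rate 1e-3 (the reference schedule of 50,000 epochs at 1e-4 is not
# intended for test suites).
fit_fixture <- function(seed, w = 2, epochs = 2000, lr = 1e-3,
                        effect_size = 2, d = 10) {
  ds <- simulate_dataset(sim_config(seed = seed, effect_size = effect_size))
  norm <- normalize_counts(ds$expression)
  genes <- tryCatch(select_marker_genes(norm)$genes,
                    error = function(e) norm$genes)
  sub <- subset_genes(norm, genes)
  cfg <- train_config(w = w, d = d, max_epochs = epochs, min_epochs = epochs,
                      patience_epochs = epochs, learning_rate = lr,
                      seed = seed)
  fit <- fit_gene_programs(sub, ds$graph, cfg)
  list(sim = ds, data = sub, fit = fit)
}

# Donor-level AUC on the held-out (test-split) donors.
held_out_auc <- function(pipe) {
  te <- subset_cells(pipe$data, pipe$data$cell_meta$split == "test")
  donors <- aggregate_donors(score_cells(te, pipe$fit))
  rank_auc(donors$score, donors$label)
}

# ARI between planted informative modules and learned program assignments,
# over the informative-module genes that entered the model.
informative_ari <- function(pipe) {
  truth <- pipe$sim$truth
  informative <- pipe$sim$config$informative_modules
  td <- tidy(pipe$fit)
  r <- td[td$gene %in% truth$gene[truth$module %in% informative], ]
  mclust::adjustedRandIndex(truth$module[match(r$gene, truth$gene)],
                            r$program)
}
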