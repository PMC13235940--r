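# Independent brute-force oracles used across tests. These deliberately avoid
# the package's own vectorized code paths: explicit loops and first-principles
# formulas only.

# Double-loop minCUT losses: Lc = -sum_ij A~_ij <S_i, S_j> / sum_i d~_i |S_i|^2,
# Lo = || M/||M||_F - target ||_F with M = S'S computed entrywise.
oracle_mincut <- function(S, A_norm, scaled_target = TRUE) {
  p <- nrow(S); d <- ncol(S)
  A_norm <- as.matrix(A_norm)
  num <- 0; den <- 0
  deg_norm <- rowSums(A_norm)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      num <- num + A_norm[i, j] * sum(S[i, ] * S[j, ])
    }
    den <- den + deg_norm[i] * sum(S[i, ]^2)
  }
  M <- matrix(0, d, d)
  for (a in seq_len(d)) for (b in seq_len(d)) M[a, b] <- sum(S[, a] * S[, b])
  f <- sqrt(sum(M^2))
  target <- if (scaled_target) diag(d) / sqrt(d) else diag(d)
  list(l_c = -num / den, l_o = sqrt(sum((M / f - target)^2)))
}

# Step-up Benjamini-Hochberg from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  running <- Inf
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    adj[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Pairwise-enumeration AUC with half-credit ties.
oracle_auc <- function(scores, labels) {
  classes <- sort(unique(labels))
  pos <- which(labels == classes[2]); neg <- which(labels == classes[1])
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  as.numeric(total) / (length(pos) * length(neg))
}

# Exhaustive connectivity quantile: enumerate every same-size subset of the
# graph's genes (feasible for <= 8 genes) and apply the mid-rank convention.
oracle_conn_quantile_exhaustive <- function(genes, graph) {
  c_obs <- connectivity(genes, graph)
  all_sets <- utils::combn(graph$genes, length(genes), simplify = FALSE)
  null_c <- vapply(all_sets, function(g) connectivity(g, graph), numeric(1))
  (sum(null_c < c_obs) + 0.5 * sum(null_c == c_obs)) / length(null_c)
}

# Exact one-sided Mann-Whitney p-value by enumerating all group assignments.
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combos <- utils::combn(length(pooled), na, simplify = FALSE)
  us <- vapply(combos, function(idx) {
    aa <- pooled[idx]; bb <- pooled[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }, numeric(1))
  mean(us >= u_obs)
}

# Small deterministic graphs used in several files.
toy_graph <- function(A, genes = sprintf("G%d", seq_len(nrow(A)))) {
  gene_graph(A, genes, add_self_loops = TRUE)
}

# Random row-stochastic loading matrix.
random_S <- function(p, d) {
  S <- matrix(stats::rexp(p * d), p, d)
  S / rowSums(S)
}

# Random symmetric adjacency with unit self-loops.
random_adjacency <- function(p, density = 0.4) {
  A <- matrix(0, p, p)
  up <- which(upper.tri(A))
  on <- sample(up, ceiling(density * length(up)))
  A[on] <- 1
  A <- A + t(A)
  diag(A) <- 1
  A
}

# Compact normalized dataset with planted structure for training tests.
small_training_data <- function(seed = 7, ...) {
  ds <- simulate_dataset(sim_config(seed = seed, ...))
  norm <- normalize_counts(ds$expression)
  list(sim = ds, norm = norm)
}

# Short-schedule training config for desk-scale tests.
quick_config <- function(...) {
  defaults <- list(d = 10, max_epochs = 300, min_epochs = 100,
                   patience_epochs = 100, learning_rate = 2e-3)
  do.call(train_config, utils::modifyList(defaults, list(...)))
}

# A hand-assembled fitted-model object (no training) for inference tests.
manual_model <- function(gene_list, S, head_hidden = c(4L, 4L, 4L),
                         task = "binary", zero_head = FALSE, seed = 1) {
  d <- ncol(S)
  set.seed(seed)
  dims <- c(d, head_hidden, 1L)
  params <- list()
  for (k in seq_len(length(dims) - 1L)) {
    params[[paste0("Hw", k)]] <- if (zero_head) {
      matrix(0, dims[k], dims[k + 1L])
    } else {
      matrix(stats::rnorm(dims[k] * dims[k + 1L], sd = 0.5), dims[k], dims[k + 1L])
    }
    params[[paste0("Hb", k)]] <- rep(0, dims[k + 1L])
  }
  rownames(S) <- gene_list
  structure(
    list(gene_list = gene_list, loading = S, params = params,
         config = train_config(d = d, head_hidden = head_hidden, task = task),
         classes = c(0, 1), graph_genes = gene_list,
         history = tibble::tibble(epoch = 1, l_clf = NA, l_c = NA, l_o = NA,
                                  total = NA, val_loss = NA),
         best_epoch = 1L, best_val = NA_real_, n_train_cells = 0L),
    class = "gene_program_fit"
  )
}
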