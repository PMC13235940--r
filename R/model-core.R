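#' Graph convolution layer
#'
#' One propagation step over the normalized annotation graph:
#' \deqn{H_{out} = ReLU(\tilde A H_{in} W + H_{in} W_{skip})}
#' The convolved term shares `W` across genes; the skip term lets each gene
#' retain influence from its own features.
#'
#' @param H_in p x m node-feature matrix (rows are genes).
#' @param graph a [gene_graph()] over the same ordered genes.
#' @param W,W_skip m x h weight matrices.
#' @return p x h nonnegative matrix.
#' @export
graph_conv <- function(H_in, graph, W, W_skip) {
  if (ncol(H_in) != nrow(W) || ncol(H_in) != nrow(W_skip) ||
      ncol(W) != ncol(W_skip) || nrow(H_in) != length(graph$genes)) {
    abort("Dimension mismatch in graph convolution.", class = "scprogram_argument")
  }
  relu(as.matrix(graph$A_norm %*% H_in %*% W) + H_in %*% W_skip)
}

#' Pool node embeddings into a loading matrix
#'
#' Row-wise softmax of `H %*% W_H`: each gene receives a weight distribution
#' over the `d` gene programs. Rows sum to one.
#'
#' @param H p x h matrix of node embeddings.
#' @param W_H h x d pooling weights.
#' @return p x d loading matrix (rows sum to 1).
#' @export
pool_loadings <- function(H, W_H) {
  if (ncol(H) != nrow(W_H)) {
    abort("Dimension mismatch in pooling.", class = "scprogram_argument")
  }
  S <- row_softmax(H %*% W_H)
  rownames(S) <- rownames(H)
  S
}

#' minCUT-style graph losses
#'
#' The cut term
#' \deqn{L_c = -\mathrm{Tr}(S^\top \tilde A S) / \mathrm{Tr}(S^\top \tilde D S)}
#' (bounded in \[-1, 0\]) rewards grouping strongly connected genes, where
#' \eqn{\tilde D} is the degree matrix of \eqn{\tilde A}. The orthogonality
#' term
#' \deqn{L_o = \| S^\top S / \|S^\top S\|_F - T \|_F}
#' pushes gene loading vectors toward one-hot assignments of comparable
#' program sizes; the target \eqn{T} is \eqn{I_d/\sqrt d} by default
#' (`ortho_target = "scaled"`, attained exactly by balanced one-hot
#' loadings) with plain \eqn{I_d} selectable.
#'
#' @param S p x d loading matrix with unit row sums.
#' @param graph a [gene_graph()] over the same ordered genes.
#' @param ortho_target `"scaled"` for \eqn{I_d/\sqrt d}, `"identity"` for
#'   \eqn{I_d}.
#' @return list with `l_c` and `l_o`.
#' @export
mincut_losses <- function(S, graph, ortho_target = c("scaled", "identity")) {
  ortho_target <- match.arg(ortho_target)
  if (nrow(S) != length(graph$genes)) {
    abort("`S` rows must match the graph's genes.", class = "scprogram_argument")
  }
  d <- ncol(S)
  num <- sum(S * as.matrix(graph$A_norm %*% S))
  den <- sum(graph$deg_norm * rowSums(S^2))
  if (den < 1e-12) {
    abort("Degenerate pooling: Tr(S' D~ S) below tolerance.",
          class = "scprogram_degenerate")
  }
  l_c <- -num / den
  M <- crossprod(S)
  f <- sqrt(sum(M^2))
  target <- if (ortho_target == "scaled") diag(d) / sqrt(d) else diag(d)
  l_o <- sqrt(sum((M / f - target)^2))
  list(l_c = l_c, l_o = l_o)
}

#' Supervised classification loss
#'
#' Mean binary cross-entropy with logits (`task = "binary"`), mean softmax
#' cross-entropy (`"multiclass"`), or mean squared error (`"regression"`).
#'
#' @param logits for binary: numeric vector (or n x 1 matrix) of logits; for
#'   multiclass: n x K logit matrix; for regression: numeric predictions.
#' @param labels for binary: 0/1; for multiclass: integer class index in
#'   1..K; for regression: numeric targets.
#' @param task one of `"binary"`, `"multiclass"`, `"regression"`.
#' @return scalar loss.
#' @export
classification_loss <- function(logits, labels,
                                task = c("binary", "multiclass", "regression")) {
  task <- match.arg(task)
  if (task == "binary") {
    z <- as.numeric(logits)
    y <- as.numeric(labels)
    if (length(z) != length(y) || any(!y %in% c(0, 1))) {
      abort("Binary task needs one logit per 0/1 label.",
            class = "scprogram_argument")
    }
    # numerically stable BCE-with-logits
    mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  } else if (task == "multiclass") {
    z <- as.matrix(logits)
    y <- as.integer(labels)
    if (nrow(z) != length(y) || any(y < 1L | y > ncol(z))) {
      abort("Multiclass labels must index logit columns 1..K.",
            class = "scprogram_argument")
    }
    lse <- logsumexp_rows(z)
    mean(lse - z[cbind(seq_along(y), y)])
  } else {
    z <- as.numeric(logits)
    y <- as.numeric(labels)
    if (length(z) != length(y)) {
      abort("Regression needs one prediction per target.",
            class = "scprogram_argument")
    }
    mean((z - y)^2)
  }
}

#' Combine the loss terms
#'
#' Total objective `l_clf + w * (l_c + l_o)`. With `w = 0` the graph terms
#' contribute nothing and the model reduces to an annotation-free baseline.
#'
#' @param l_clf,l_c,l_o scalar loss components.
#' @param w nonnegative weight on the unsupervised graph terms (default 2).
#' @return a one-row `loss_report` tibble with components and total.
#' @export
total_loss <- function(l_clf, l_c, l_o, w = 2) {
  if (!is.finite(l_clf) || !is.finite(l_c) || !is.finite(l_o)) {
    abort("Loss components must be finite.", class = "scprogram_nonfinite")
  }
  if (w < 0) abort("`w` must be nonnegative.", class = "scprogram_argument")
  structure(tibble(l_clf = l_clf, l_c = l_c, l_o = l_o, w = w,
                   total = l_clf + w * (l_c + l_o)),
            class = c("loss_report", "tbl_df", "tbl", "data.frame"))
}

# ---------------------------------------------------------------------------
# Internal network machinery: initialization, forward, backward, Adam.
# The architecture is: two graph-convolution layers (h units each) over the
# gene graph with gene features = expression across training cells, a
# row-softmax pooling into d programs, projection of cells into program
# space, and an MLP head (three ReLU hidden layers of 64 units, dropout after
# hidden layers only).

# Uniform(-1/sqrt(fan_in), 1/sqrt(fan_in)) init for a fan_in x fan_out matrix.
init_weight <- function(fan_in, fan_out) {
  b <- 1 / sqrt(fan_in)
  matrix(runif(fan_in * fan_out, -b, b), fan_in, fan_out)
}

init_params <- function(n, h, d, head_hidden, n_out) {
  params <- list(
    W1 = init_weight(n, h), W1s = init_weight(n, h),
    W2 = init_weight(h, h), W2s = init_weight(h, h),
    WH = init_weight(h, d)
  )
  dims <- c(d, head_hidden, n_out)
  for (k in seq_len(length(dims) - 1L)) {
    params[[paste0("Hw", k)]] <- init_weight(dims[k], dims[k + 1L])
    params[[paste0("Hb", k)]] <- runif(dims[k + 1L], -1 / sqrt(dims[k]),
                                       1 / sqrt(dims[k]))
  }
  params
}

# Encoder forward: node features -> loading matrix. X, XA are p x n.
encoder_forward <- function(params, X, XA, A_norm) {
  Z1 <- as.matrix(XA %*% params$W1) + X %*% params$W1s
  H1 <- relu(Z1)
  AH1 <- as.matrix(A_norm %*% H1)
  Z2 <- AH1 %*% params$W2 + H1 %*% params$W2s
  H2 <- relu(Z2)
  L <- H2 %*% params$WH
  S <- row_softmax(L)
  list(Z1 = Z1, H1 = H1, AH1 = AH1, Z2 = Z2, H2 = H2, S = S)
}

# MLP head forward. Xr is n x d. In training mode, inverted-dropout masks
# (already scaled by 1/(1-p)) are applied after each hidden activation.
head_forward <- function(params, Xr, n_hidden, dropout_masks = NULL) {
  a <- Xr
  zs <- vector("list", n_hidden)
  as_dropped <- vector("list", n_hidden + 1L)
  as_dropped[[1L]] <- a
  for (k in seq_len(n_hidden)) {
    z <- sweep(as_dropped[[k]] %*% params[[paste0("Hw", k)]], 2L,
               params[[paste0("Hb", k)]], "+")
    a <- relu(z)
    if (!is.null(dropout_masks)) a <- a * dropout_masks[[k]]
    zs[[k]] <- z
    as_dropped[[k + 1L]] <- a
  }
  out_k <- n_hidden + 1L
  out <- sweep(as_dropped[[out_k]] %*% params[[paste0("Hw", out_k)]], 2L,
               params[[paste0("Hb", out_k)]], "+")
  list(zs = zs, acts = as_dropped, out = out)
}

# Gradient of the classification loss w.r.t. the output logits.
clf_output_grad <- function(out, y, task) {
  n <- nrow(out)
  if (task == "binary") {
    matrix((1 / (1 + exp(-out)) - y) / n, ncol = 1L)
  } else if (task == "multiclass") {
    P <- exp(out - logsumexp_rows(out))
    Y <- matrix(0, n, ncol(out))
    Y[cbind(seq_len(n), y)] <- 1
    (P - Y) / n
  } else {
    matrix(2 * (out - y) / n, ncol = 1L)
  }
}

# Gradients of the graph losses w.r.t. S (analytic; verified against finite
# differences in the test suite).
mincut_grad_S <- function(S, graph, ortho_target) {
  d <- ncol(S)
  AS <- as.matrix(graph$A_norm %*% S)
  num <- sum(S * AS)
  den <- sum(graph$deg_norm * rowSums(S^2))
  dLc <- (-2 * AS) / den + (num / den^2) * (2 * graph$deg_norm * S)
  M <- crossprod(S)
  f <- sqrt(sum(M^2))
  target <- if (ortho_target == "scaled") diag(d) / sqrt(d) else diag(d)
  Tm <- M / f - target
  lo <- sqrt(sum(Tm^2))
  if (lo < 1e-12) {
    dLo <- matrix(0, nrow(S), d)
  } else {
    G <- Tm / lo
    dM <- G / f - (sum(G * M) / f^3) * M
    dLo <- 2 * (S %*% dM)
  }
  list(dLc = dLc, dLo = dLo)
}

# Full backward pass; returns gradients for every parameter.
backward_pass <- function(params, enc, head, X, XA, A_norm, Xr, y, task, w,
                          graph, n_hidden, dropout_masks, ortho_target) {
  grads <- list()
  dOut <- clf_output_grad(head$out, y, task)
  out_k <- n_hidden + 1L
  grads[[paste0("Hw", out_k)]] <- crossprod(head$acts[[out_k]], dOut)
  grads[[paste0("Hb", out_k)]] <- colSums(dOut)
  da <- dOut %*% t(params[[paste0("Hw", out_k)]])
  for (k in rev(seq_len(n_hidden))) {
    if (!is.null(dropout_masks)) da <- da * dropout_masks[[k]]
    dz <- da * (head$zs[[k]] > 0)
    grads[[paste0("Hw", k)]] <- crossprod(head$acts[[k]], dz)
    grads[[paste0("Hb", k)]] <- colSums(dz)
    da <- dz %*% t(params[[paste0("Hw", k)]])
  }
  dXr <- da                                    # n x d
  dS <- X %*% dXr                              # p x d, from Xr = X' S
  if (w > 0) {
    g <- mincut_grad_S(enc$S, graph, ortho_target)
    dS <- dS + w * (g$dLc + g$dLo)
  }
  # through the row-wise softmax
  dL <- enc$S * (dS - rowSums(dS * enc$S))
  grads$WH <- crossprod(enc$H2, dL)
  dH2 <- dL %*% t(params$WH)
  dZ2 <- dH2 * (enc$Z2 > 0)
  grads$W2 <- crossprod(enc$AH1, dZ2)
  grads$W2s <- crossprod(enc$H1, dZ2)
  dH1 <- as.matrix(A_norm %*% (dZ2 %*% t(params$W2))) + dZ2 %*% t(params$W2s)
  dZ1 <- dH1 * (enc$Z1 > 0)
  grads$W1 <- crossprod(as.matrix(XA), dZ1)
  grads$W1s <- crossprod(X, dZ1)
  grads
}

# One Adam step with decoupled-from-nothing (classic) L2 weight decay added
# to the gradient, as in the reference optimizer.
adam_step <- function(params, grads, state, lr, wd, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]] + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros)
}
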