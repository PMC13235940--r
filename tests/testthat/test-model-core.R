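relu_ref <- function(x) pmax(x, 0)

test_that("graph convolution matches brute-force matrix arithmetic", {
  set.seed(1)
  p <- 6; m <- 4; h <- 3
  A <- random_adjacency(p)
  g <- gene_graph(A, sprintf("G%d", 1:p), add_self_loops = FALSE)
  H_in <- matrix(rnorm(p * m), p, m)
  W <- matrix(rnorm(m * h), m, h)
  Ws <- matrix(rnorm(m * h), m, h)

  out <- graph_conv(H_in, g, W, Ws)
  An <- as.matrix(g$A_norm)
  expected <- matrix(0, p, h)
  for (i in seq_len(p)) {
    conv_i <- rep(0, m)
    for (k in seq_len(p)) conv_i <- conv_i + An[i, k] * H_in[k, ]
    for (j in seq_len(h)) {
      z <- sum(conv_i * W[, j]) + sum(H_in[i, ] * Ws[, j])
      expected[i, j] <- max(z, 0)
    }
  }
  expect_equal(out, expected, tolerance = 1e-12)
  expect_true(all(out >= 0))

  # identity adjacency with zero skip reduces to ReLU(H W)
  gI <- gene_graph(diag(p), sprintf("G%d", 1:p), add_self_loops = FALSE)
  expect_equal(graph_conv(H_in, gI, W, 0 * Ws), relu_ref(H_in %*% W))
  # zero input stays zero
  expect_equal(graph_conv(0 * H_in, g, W, Ws), matrix(0, p, h))
  expect_error(graph_conv(H_in, g, matrix(0, m + 1, h), Ws),
               class = "scprogram_argument")
})

test_that("pooling produces row-stochastic loadings with softmax behaviour", {
  set.seed(2)
  H <- matrix(rnorm(8 * 5), 8, 5)
  # zero weights: uniform rows
  expect_equal(pool_loadings(H, matrix(0, 5, 4)),
               matrix(0.25, 8, 4), ignore_attr = TRUE)
  # rows always sum to one
  S <- pool_loadings(H, matrix(rnorm(20), 5, 4))
  expect_equal(rowSums(S), rep(1, 8), tolerance = 1e-6)
  expect_true(all(S >= 0 & S <= 1))
  # a dominating logit saturates its row
  H1 <- matrix(1, 1, 2)
  WH <- rbind(c(25, 0, 0), c(0, 0, 0))
  expect_gt(max(pool_loadings(H1, WH)), 0.999)
})

test_that("minCUT losses equal double-loop oracles on random instances", {
  set.seed(3)
  for (i in 1:100) {
    p <- 10; d <- 4
    A <- random_adjacency(p, density = runif(1, 0.2, 0.8))
    g <- gene_graph(A, sprintf("G%02d", 1:p), add_self_loops = FALSE)
    S <- random_S(p, d)
    got <- mincut_losses(S, g)
    want <- oracle_mincut(S, g$A_norm, scaled_target = TRUE)
    expect_equal(got$l_c, want$l_c, tolerance = 1e-8)
    expect_equal(got$l_o, want$l_o, tolerance = 1e-8)
    expect_gte(got$l_c, -1 - 1e-10)
    expect_lte(got$l_c, 0 + 1e-10)
  }
})

test_that("minCUT special cases attain their analytic values", {
  set.seed(4)
  A <- random_adjacency(7, density = 0.5)
  g <- gene_graph(A, sprintf("G%d", 1:7), add_self_loops = FALSE)
  # single all-ones program: Lc = -1 on any graph
  S1 <- matrix(1, 7, 1)
  expect_equal(mincut_losses(S1, g)$l_c, -1, tolerance = 1e-12)

  # two disconnected components with exact indicator pooling: Lc = -1
  A2 <- matrix(0, 6, 6)
  A2[1:3, 1:3] <- 1; A2[4:6, 4:6] <- 1
  g2 <- gene_graph(A2, sprintf("G%d", 1:6), add_self_loops = FALSE)
  Sind <- cbind(rep(c(1, 0), each = 3), rep(c(0, 1), each = 3))
  got <- mincut_losses(Sind, g2)
  expect_equal(got$l_c, -1, tolerance = 1e-12)
  expect_equal(got$l_c, oracle_mincut(Sind, g2$A_norm)$l_c, tolerance = 1e-12)
  # balanced one-hot S: Lo = 0 under the scaled-identity target
  expect_equal(got$l_o, 0, tolerance = 1e-12)
  # under the plain-identity convention it is strictly positive
  expect_gt(mincut_losses(Sind, g2, ortho_target = "identity")$l_o, 0)

  expect_error(mincut_losses(matrix(0, 6, 2), g2),
               class = "scprogram_degenerate")
})

test_that("classification losses match hand-computed formulas", {
  # zero logit is maximally uncertain: loss = log 2 for either label
  expect_equal(classification_loss(0, 1, "binary"), log(2))
  expect_equal(classification_loss(0, 0, "binary"), log(2))
  # confident correct predictions drive the loss to zero
  expect_lt(classification_loss(c(30, -30), c(1, 0), "binary"), 1e-10)

  set.seed(5)
  z <- rnorm(20); y <- rbinom(20, 1, 0.5)
  p1 <- 1 / (1 + exp(-z))
  expect_equal(classification_loss(z, y, "binary"),
               -mean(y * log(p1) + (1 - y) * log(1 - p1)), tolerance = 1e-8)

  Z <- matrix(rnorm(15), 5, 3); yk <- sample(3, 5, replace = TRUE)
  P <- exp(Z) / rowSums(exp(Z))
  expect_equal(classification_loss(Z, yk, "multiclass"),
               -mean(log(P[cbind(1:5, yk)])), tolerance = 1e-8)

  expect_equal(classification_loss(c(1, 2), c(0, 4), "regression"),
               mean(c(1, 4)))
  expect_error(classification_loss(c(0, 0), c(0, 2), "binary"),
               class = "scprogram_argument")
})

test_that("the total objective combines terms as l_clf + w (l_c + l_o)", {
  rep1 <- total_loss(0.5, -0.8, 0.1, w = 2)
  expect_equal(rep1$total, 0.5 + 2 * (-0.7))
  # w = 0 removes the graph contribution entirely
  expect_equal(total_loss(0.37, -0.9, 0.4, w = 0)$total, 0.37)
  # the shipped default weight is 2
  expect_equal(train_config()$w, 2)
  expect_error(total_loss(1, -1, 0, w = -0.5), class = "scprogram_argument")
})

test_that("pooling over the encoder is permutation-equivariant", {
  set.seed(6)
  ds <- simulate_dataset(sim_config(n_genes = 30, n_modules = 2,
                                    module_size = 8, n_donors_per_class = 2,
                                    cells_per_donor = 5, seed = 9))
  norm <- normalize_counts(ds$expression)
  X <- t(as.matrix(norm$values))
  g <- ds$graph
  p <- nrow(X); n <- ncol(X); h <- 8; d <- 3
  set.seed(10)
  params <- scprogram:::init_params(n, h, d, c(4L), 1L)
  XA <- as.matrix(g$A_norm %*% X)
  S <- scprogram:::encoder_forward(params, X, XA, g$A_norm)$S

  perm <- sample(p)
  gp <- gene_graph(g$A[perm, perm], g$genes[perm], add_self_loops = FALSE)
  Xp <- X[perm, , drop = FALSE]
  XAp <- as.matrix(gp$A_norm %*% Xp)
  Sp <- scprogram:::encoder_forward(params, Xp, XAp, gp$A_norm)$S
  expect_equal(Sp, S[perm, , drop = FALSE], tolerance = 1e-10)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(7)
  p <- 12; n <- 9; h <- 5; d <- 3
  A <- random_adjacency(p, density = 0.4)
  g <- gene_graph(A, sprintf("G%02d", 1:p), add_self_loops = FALSE)
  X <- matrix(rnorm(p * n), p, n)
  XA <- as.matrix(g$A_norm %*% X)
  y <- rbinom(n, 1, 0.5)
  w <- 1.7
  set.seed(8)
  params <- scprogram:::init_params(n, h, d, c(4L, 4L), 1L)

  loss_at <- function(par) {
    enc <- scprogram:::encoder_forward(par, X, XA, g$A_norm)
    Xr <- crossprod(X, enc$S)
    hd <- scprogram:::head_forward(par, Xr, 2L, NULL)
    l_clf <- classification_loss(hd$out, y, "binary")
    ml <- mincut_losses(enc$S, g)
    l_clf + w * (ml$l_c + ml$l_o)
  }
  enc <- scprogram:::encoder_forward(params, X, XA, g$A_norm)
  Xr <- crossprod(X, enc$S)
  hd <- scprogram:::head_forward(params, Xr, 2L, NULL)
  grads <- scprogram:::backward_pass(params, enc, hd, X, XA, g$A_norm, Xr, y,
                                     "binary", w, g, 2L, NULL, "scaled")
  eps <- 1e-6
  for (nm in c("W1", "W2s", "WH", "Hw1", "Hb2", "Hw3")) {
    theta <- params[[nm]]
    picks <- sample(length(theta), min(4, length(theta)))
    for (ix in picks) {
      pp <- params; pp[[nm]][ix] <- theta[ix] + eps
      pm <- params; pm[[nm]][ix] <- theta[ix] - eps
      fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(as.numeric(grads[[nm]][ix]), fd, tolerance = 1e-4)
    }
  }
})
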