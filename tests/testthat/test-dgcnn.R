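random_graph <- function(n, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n), n)
  W <- (A + t(A)) / 2
  diag(W) <- 0
  W
}

test_that("Laplacian has zero row sums and is PSD for nonnegative weights", {
  expect_equal(laplacian(matrix(c(0, 1, 1, 0), 2))$L,
               matrix(c(1, -1, -1, 1), 2))
  expect_equal(laplacian(matrix(0, 3, 3))$L, matrix(0, 3, 3))
  W <- random_graph(8, 1)
  L <- laplacian(W)$L
  expect_equal(rowSums(L), rep(0, 8), tolerance = 1e-12)
  expect_gt(min(eigen(L, symmetric = TRUE)$values), -1e-10)
  expect_error(laplacian(matrix(1:4, 2)), "symmetric")
})

test_that("graph Fourier transform round-trips and orders energy by frequency", {
  W <- random_graph(7, 2)
  L <- laplacian(W)$L
  x <- rnorm(7)
  expect_lt(max(abs(inverse_graph_fourier(L, graph_fourier(L, x)) - x)), 1e-10)
  # constant signal on a connected graph lives entirely in the lambda=0 mode
  xh <- graph_fourier(L, rep(1, 7))
  e <- eigen(L, symmetric = TRUE)
  i0 <- which.min(e$values)
  expect_gt(xh[i0]^2 / sum(xh^2), 1 - 1e-10)
  # 2-node path: spectrum {0, 2}
  L2 <- laplacian(matrix(c(0, 1, 1, 0), 2))$L
  expect_equal(sort(eigen(L2, symmetric = TRUE)$values), c(0, 2))
})

test_that("rescaled Laplacian maps the spectrum into [-1, 1]", {
  L2 <- laplacian(matrix(c(0, 1, 1, 0), 2))$L
  r <- rescale_laplacian(L2)
  expect_equal(sort(eigen(r$L_tilde, symmetric = TRUE)$values), c(-1, 1))
  W <- random_graph(12, 3)
  r1 <- rescale_laplacian(laplacian(W)$L)
  r2 <- rescale_laplacian(laplacian(2 * W)$L)
  expect_equal(r1$L_tilde, r2$L_tilde, tolerance = 1e-12)
  ev <- eigen(r1$L_tilde, symmetric = TRUE)$values
  expect_true(all(ev >= -1 - 1e-10 & ev <= 1 + 1e-10))
  expect_error(rescale_laplacian(matrix(0, 3, 3)), "edgeless")
})

test_that("Chebyshev recursion equals identity and L_tilde at low orders", {
  W <- random_graph(5, 4)
  Lt <- rescale_laplacian(laplacian(W)$L)$L_tilde
  x <- rnorm(5)
  expect_equal(chebyshev_filter(x, Lt, cheb_filter_bank(1)), x)
  expect_equal(chebyshev_filter(x, Lt, cheb_filter_bank(c(0, 1))),
               as.numeric(Lt %*% x))
  expect_error(cheb_filter_bank(numeric(0)), "K must be")
})

test_that("Chebyshev filtering matches the dense spectral oracle", {
  for (trial in 1:6) {
    n <- sample(5:30, 1)
    W <- random_graph(n, 100 + trial)
    K <- sample(2:6, 1)
    theta <- rnorm(K)
    x <- rnorm(n)
    Lt <- rescale_laplacian(laplacian(W)$L)$L_tilde
    z_rec <- chebyshev_filter(x, Lt, cheb_filter_bank(theta))
    z_spec <- spectral_filter_oracle(W, theta, x)
    expect_lt(max(abs(z_rec - as.numeric(z_spec))), 1e-9)
  }
})

test_that("forward pass matches a straight-line reimplementation", {
  W <- random_graph(4, 5)
  model <- dgcnn_model(W, input_dim = 6, K = 3, n_filters = 3, n_conv = 2,
                       seed = 8)
  set.seed(9)
  X <- matrix(rnorm(24), 4, 6)
  p <- dgcnn_forward(model, X)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # independent re-implementation with explicit loops
  Lt <- model$L_tilde
  A <- list(diag(4), Lt, 2 * Lt %*% Lt - diag(4))
  Z1 <- matrix(0, 4, 3)
  for (k in 1:3) Z1 <- Z1 + A[[k]] %*% X %*% model$theta[[k]]
  H1 <- ifelse(Z1 > 0, Z1, 0)
  Z2 <- H1 %*% model$conv_W
  for (j in 1:2) Z2[, j] <- Z2[, j] + model$conv_b[j]
  H2 <- ifelse(Z2 > 0, Z2, 0)
  f <- as.numeric(H2)
  logits <- numeric(2)
  for (c in 1:2) logits[c] <- sum(model$dense_W[, c] * f) + model$dense_b[c]
  p_ref <- exp(logits) / sum(exp(logits))
  expect_equal(p, p_ref, tolerance = 1e-12)

  # all-zero weights give uniform class probabilities
  m0 <- model
  m0$theta <- lapply(m0$theta, function(t) t * 0)
  m0$conv_W[] <- 0; m0$dense_W[] <- 0
  expect_equal(dgcnn_forward(m0, X), c(0.5, 0.5))
  expect_error(dgcnn_forward(model, X[, 1:3]), "shape mismatch")
})

test_that("cross-entropy loss matches hand arithmetic", {
  expect_lt(cross_entropy_loss(c(1 - 1e-13, 1e-13), 1L), 1e-10)
  expect_equal(cross_entropy_loss(c(0.5, 0.5), 2L), log(2))
  probs <- rbind(c(0.7, 0.3), c(0.2, 0.8), c(0.5, 0.5))
  hand <- -(log(0.7) + log(0.8) + log(0.5)) / 3
  expect_equal(cross_entropy_loss(probs, c(1L, 2L, 2L)), hand,
               tolerance = 1e-12)
  expect_error(cross_entropy_loss(probs, c(1L, 3L, 2L)), "out of range")
})

test_that("adjacency relaxation respects its limits and stays feasible", {
  W <- random_graph(5, 6)
  G <- matrix(rnorm(25), 5)
  expect_equal(adjacency_update(W, G, rho = 0), W)
  lit <- adjacency_update(W, G, rho = 1, mode = "literal")
  proj <- (G + t(G)) / 2; proj[proj < 0] <- 0
  expect_equal(lit, proj)
  up <- adjacency_update(W, G, rho = 0.3)
  expect_identical(up, t(up))
  expect_true(all(up >= 0))

  # descent mode reduces a quadratic toy loss monotonically
  Wt <- W * 3
  losses <- numeric(50)
  for (i in 1:50) {
    losses[i] <- 0.5 * sum(Wt^2)
    Wt <- adjacency_update(Wt, Wt, rho = 0.05)  # grad of 0.5*||W||^2 is W
  }
  expect_true(all(diff(losses) < 0))
})

test_that("training overfits a small set, is seed-stable, and respects epochs = 0", {
  W <- random_graph(3, 8)
  set.seed(10)
  feats <- lapply(1:8, function(i) {
    lab <- (i %% 2) + 1
    base <- if (lab == 1) sin(2 * pi * (1:32) / 8) else sin(2 * pi * (1:32) / 16)
    rbind(base + rnorm(32, sd = 0.1), rnorm(32, sd = 0.1),
          rnorm(32, sd = 0.1))
  })
  labs <- rep(c(2L, 1L), 4)
  model <- dgcnn_model(W, input_dim = 32, K = 3, n_filters = 8, n_conv = 8,
                       seed = 3)

  same <- train_dgcnn(model, feats, labs, train_config(epochs = 0L))
  expect_identical(same$model$theta, model$theta)
  expect_length(same$loss_history, 0L)

  cfg <- train_config(lr = 5e-3, epochs = 200L, batch_size = 4L, seed = 2)
  tr1 <- train_dgcnn(model, feats, labs, cfg)
  expect_equal(evaluate_accuracy(tr1$model, feats, labs), 1)
  tr2 <- train_dgcnn(model, feats, labs, cfg)
  expect_identical(tr1$loss_history, tr2$loss_history)
  expect_lt(tr1$loss_history[length(tr1$loss_history)], tr1$loss_history[1])

  # adjacency stays symmetric nonnegative through training
  expect_identical(tr1$model$W_star, t(tr1$model$W_star))
  expect_true(all(tr1$model$W_star >= 0))
})

test_that("an untrained model on a balanced set scores near chance", {
  W <- random_graph(4, 9)
  model <- dgcnn_model(W, input_dim = 16, seed = 5)
  set.seed(11)
  feats <- lapply(1:100, function(i) matrix(rnorm(64), 4))
  labs <- rep(1:2, 50)
  acc <- evaluate_accuracy(model, feats, labs)
  expect_gte(acc, 0.35); expect_lte(acc, 0.65)
  expect_true(evaluate_accuracy(model, feats[1], labs[1]) %in% c(0, 1))
  expect_error(evaluate_accuracy(model, list(), integer(0)), "empty")
})
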