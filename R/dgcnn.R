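#' Graph degree matrix and combinatorial Laplacian
#'
#' \eqn{S_{ii} = \sum_j w_{ij}} and \eqn{L = S - W}.  For symmetric
#' nonnegative `W` the Laplacian is positive semidefinite with zero row
#' sums.
#'
#' @param W Square symmetric adjacency matrix.
#' @return List with `S` (diagonal degree matrix) and `L`.
#' @export
laplacian <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-10 * max(1, max(abs(W))))
    stop("W must be symmetric", call. = FALSE)
  S <- diag(rowSums(W), nrow(W))
  list(S = S, L = S - W)
}

#' Graph Fourier transform and its inverse
#'
#' Projects a graph signal onto the orthonormal eigenbasis of the (symmetric)
#' Laplacian, \eqn{\hat{x} = U^T x} with \eqn{L = U \Lambda U^T}; the
#' inverse reconstructs \eqn{x = U \hat{x}}.  The eigenbasis is recomputed
#' from `L` on each call, so a transform/inverse pair on the same `L` is an
#' exact round trip.
#'
#' @param L Symmetric Laplacian matrix.
#' @param x Signal vector or matrix (columns transformed independently).
#' @return Transformed signal of the same shape.
#' @export
graph_fourier <- function(L, x) {
  U <- laplacian_eigenbasis(L)
  crossprod(U, as.matrix(x))
}

#' @rdname graph_fourier
#' @param x_hat Spectral coefficients as produced by [graph_fourier()].
#' @export
inverse_graph_fourier <- function(L, x_hat) {
  U <- laplacian_eigenbasis(L)
  U %*% as.matrix(x_hat)
}

laplacian_eigenbasis <- function(L) {
  L <- as.matrix(L)
  if (max(abs(L - t(L))) > 1e-8 * max(1, max(abs(L))))
    stop("L must be symmetric", call. = FALSE)
  eigen(L, symmetric = TRUE)$vectors
}

#' Rescale a Laplacian to the Chebyshev domain
#'
#' \eqn{\tilde{L} = 2L/\lambda_{max} - I}, mapping the spectrum of `L` from
#' \eqn{[0, \lambda_{max}]} into \eqn{[-1, 1]}, the domain on which the
#' Chebyshev recursion is stable.
#'
#' @param L Symmetric positive semidefinite Laplacian.
#' @return List with `L_tilde` and `lambda_max`.
#' @export
rescale_laplacian <- function(L) {
  L <- as.matrix(L)
  lambda_max <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (lambda_max <= 0)
    stop("lambda_max = 0 (edgeless graph): no spectral structure; ",
         "use an identity filter instead", call. = FALSE)
  list(L_tilde = 2 * L / lambda_max - diag(nrow(L)), lambda_max = lambda_max)
}

#' Chebyshev filter coefficient bank
#'
#' @param theta Either a numeric vector of K scalar coefficients (one filter
#'   applied to all input features) or a list of K matrices
#'   (`F_in x F_out`), one per polynomial order.
#' @export
cheb_filter_bank <- function(theta) {
  if (is.numeric(theta)) theta <- as.list(theta)
  if (length(theta) < 1L) stop("K must be >= 1", call. = FALSE)
  if (!all(vapply(theta, function(t) all(is.finite(t)), logical(1))))
    stop("non-finite filter coefficients", call. = FALSE)
  structure(list(theta = theta, K = length(theta)),
            class = "cheb_filter_bank")
}

#' Chebyshev spectral graph filtering
#'
#' Evaluates \eqn{z = \sum_{k=0}^{K-1} \theta_k T_k(\tilde{L})\, x} with the
#' three-term recursion \eqn{T_0 = I}, \eqn{T_1 = \tilde{L}},
#' \eqn{T_k = 2\tilde{L} T_{k-1} - T_{k-2}} — no eigendecomposition is ever
#' performed on the filtering path.  With matrix coefficients the k-th term
#' is \eqn{T_k(\tilde{L})\, X\, \Theta_k} (node mixing by the polynomial,
#' feature mixing by \eqn{\Theta_k}).
#'
#' @param x Node signal: vector or `M x F_in` matrix.
#' @param L_tilde Rescaled Laplacian from [rescale_laplacian()].
#' @param bank A [cheb_filter_bank()].
#' @return Filtered signal (`M x F_out`, or a vector if `x` was one).
#' @export
chebyshev_filter <- function(x, L_tilde, bank) {
  stopifnot(inherits(bank, "cheb_filter_bank"))
  was_vec <- is.null(dim(x))
  X <- as.matrix(x)
  if (nrow(X) != nrow(L_tilde)) stop("node count mismatch", call. = FALSE)
  P <- cheb_propagate(L_tilde, X, bank$K)
  scalar <- is.null(dim(bank$theta[[1L]]))
  z <- 0
  for (k in seq_len(bank$K)) {
    z <- z + if (scalar) bank$theta[[k]] * P[[k]] else P[[k]] %*% bank$theta[[k]]
  }
  if (was_vec && ncol(as.matrix(z)) == 1L) as.numeric(z) else z
}

# T_k(L_tilde) %*% X for k = 0..K-1 via the three-term recursion.
cheb_propagate <- function(L_tilde, X, K) {
  P <- vector("list", K)
  P[[1L]] <- X
  if (K >= 2L) P[[2L]] <- L_tilde %*% X
  if (K >= 3L) for (k in 3L:K)
    P[[k]] <- 2 * (L_tilde %*% P[[k - 1L]]) - P[[k - 2L]]
  P
}

#' Initialize a DGCNN model
#'
#' The network follows: Chebyshev graph filtering (K orders, `n_filters`
#' output features) -> ReLU -> 1x1 pointwise convolution across feature maps
#' (`n_conv` maps) -> ReLU -> flatten -> dense layer -> softmax.  The
#' adjacency `W_star` is a model parameter: when adjacency updates are
#' enabled during training it is relaxed toward the loss gradient and the
#' rescaled Laplacian is recomputed after every change.
#'
#' @param W Initial symmetric nonnegative adjacency (`M_g x M_g`).
#' @param input_dim Per-node feature dimension (epoch length T for raw
#'   time-course features).
#' @param K Chebyshev order (>= 1), default 3.
#' @param n_filters Graph-filter output features, default 16.
#' @param n_conv Pointwise convolution maps, default 32.
#' @param n_classes Number of output classes, default 2.
#' @param seed Seed for the Gaussian weight initialization.
#' @return Object of class `dgcnn_model`.
#' @export
dgcnn_model <- function(W, input_dim, K = 3L, n_filters = 16L, n_conv = 32L,
                        n_classes = 2L, seed = 1L) {
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  lap <- laplacian(W)
  resc <- rescale_laplacian(lap$L)
  M <- nrow(W)
  withr_seed(seed, {
    theta <- lapply(seq_len(K), function(k)
      matrix(rnorm(input_dim * n_filters, sd = 1 / sqrt(input_dim * K)),
             input_dim, n_filters))
    conv_W <- matrix(rnorm(n_filters * n_conv, sd = 1 / sqrt(n_filters)),
                     n_filters, n_conv)
    dense_W <- matrix(rnorm(M * n_conv * n_classes,
                            sd = 1 / sqrt(M * n_conv)),
                      M * n_conv, n_classes)
    structure(list(W_star = W, L_tilde = resc$L_tilde,
                   lambda_max = resc$lambda_max,
                   theta = theta, K = as.integer(K),
                   conv_W = conv_W, conv_b = numeric(n_conv),
                   dense_W = dense_W, dense_b = numeric(n_classes),
                   input_dim = as.integer(input_dim),
                   n_filters = as.integer(n_filters),
                   n_conv = as.integer(n_conv),
                   n_classes = as.integer(n_classes)),
              class = "dgcnn_model")
  })
}

#' @export
print.dgcnn_model <- function(x, ...) {
  cat(sprintf("<dgcnn_model> %d nodes, K=%d, %d->%d features, %d classes\n",
              nrow(x$W_star), x$K, x$n_filters, x$n_conv, x$n_classes))
  invisible(x)
}

# Forward pass returning every intermediate needed by backprop.
dgcnn_forward_full <- function(model, X) {
  X <- as.matrix(X)
  if (nrow(X) != nrow(model$W_star) || ncol(X) != model$input_dim)
    stop("node-signal shape mismatch: expected ",
         nrow(model$W_star), " x ", model$input_dim, call. = FALSE)
  P <- cheb_propagate(model$L_tilde, X, model$K)
  Z1 <- 0
  for (k in seq_len(model$K)) Z1 <- Z1 + P[[k]] %*% model$theta[[k]]
  H1 <- pmax(Z1, 0)
  Z2 <- sweep(H1 %*% model$conv_W, 2L, model$conv_b, "+")
  H2 <- pmax(Z2, 0)
  f <- as.numeric(H2)
  logits <- as.numeric(crossprod(model$dense_W, f)) + model$dense_b
  m <- max(logits)
  p <- exp(logits - m); p <- p / sum(p)
  list(X = X, P = P, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2, f = f, probs = p)
}

#' DGCNN forward pass
#'
#' @param model A [dgcnn_model()].
#' @param node_signals `M_g x input_dim` feature matrix (rows = graph nodes).
#' @return Numeric vector of class probabilities (sums to 1).
#' @export
dgcnn_forward <- function(model, node_signals) {
  dgcnn_forward_full(model, node_signals)$probs
}

#' Mean cross-entropy loss
#'
#' \eqn{-\mathrm{mean}\log p(\mathrm{true\ class})}, with probabilities
#' floored at 1e-12.
#'
#' @param probs Matrix of row-wise class distributions (or a single vector).
#' @param labels Integer class indices (1-based).
#' @export
cross_entropy_loss <- function(probs, labels) {
  probs <- if (is.null(dim(probs))) matrix(probs, 1L) else as.matrix(probs)
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > ncol(probs)))
    stop("label out of range", call. = FALSE)
  p <- pmax(probs[cbind(seq_along(labels), labels)], 1e-12)
  -mean(log(p))
}

#' Relaxation update of the trainable adjacency
#'
#' Applies \eqn{W^* \leftarrow (1-\rho) W^* + \rho\, G} where `G` is the
#' loss gradient with respect to the adjacency.  As printed, the relaxation
#' moves along the raw gradient; `mode = "descent"` (default) negates the
#' gradient term so that training reduces the loss, while
#' `mode = "literal"` keeps the printed sign.  The result is symmetrized
#' and negative entries are clamped to zero, so the updated adjacency stays
#' a valid nonnegative weight matrix.
#'
#' @param W_star Current adjacency.
#' @param grad Gradient of the loss w.r.t. `W_star` (same shape).
#' @param rho Adjacency learning rate in `[0, 1]`.
#' @param mode `"descent"` or `"literal"`.
#' @export
adjacency_update <- function(W_star, grad, rho,
                             mode = c("descent", "literal")) {
  mode <- match.arg(mode)
  assert_scalar(rho, "rho", 0, 1)
  if (!all(dim(W_star) == dim(grad))) stop("shape mismatch", call. = FALSE)
  g <- if (mode == "descent") -grad else grad
  Wn <- (1 - rho) * W_star + rho * g
  Wn <- (Wn + t(Wn)) / 2
  Wn[Wn < 0] <- 0
  Wn
}

#' Training configuration for the DGCNN
#'
#' @param rho Adjacency learning rate (0 disables adjacency movement even
#'   when `adjacency_updates` is on).
#' @param lr Learning rate for filter, convolution and dense weights.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param seed Seed controlling batch shuffling.
#' @param adjacency_updates Update `W_star` each batch.
#' @param adjacency_mode Sign convention handed to [adjacency_update()].
#' @param weight_decay L2 penalty on filter, convolution and dense weights
#'   (never on the adjacency); discourages memorizing the random phases of
#'   individual epochs instead of class structure.
#' @param augment_shift Circularly shift each epoch's node signals by a
#'   random offset (the same offset for every node, so cross-node
#'   correlations are preserved exactly) at every presentation.  Oscillatory
#'   epochs carry arbitrary phase, so a classifier should be invariant to
#'   time shifts; augmenting enforces that invariance instead of letting
#'   the filters memorize per-epoch phases.
#' @export
train_config <- function(rho = 1e-3, lr = 1e-3, epochs = 100L,
                         batch_size = 16L, seed = 1L,
                         adjacency_updates = TRUE,
                         adjacency_mode = "descent",
                         weight_decay = 0,
                         augment_shift = FALSE) {
  stopifnot(rho >= 0, lr > 0, epochs >= 0L, batch_size >= 1L,
            weight_decay >= 0)
  structure(list(rho = rho, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 adjacency_updates = isTRUE(adjacency_updates),
                 adjacency_mode = adjacency_mode,
                 weight_decay = weight_decay,
                 augment_shift = isTRUE(augment_shift)),
            class = "train_config")
}

# Gradients for one mini-batch; returns parameter grads, the adjacency
# gradient, and the mean batch loss.
dgcnn_batch_gradients <- function(model, features, labels) {
  B <- length(features)
  K <- model$K
  g_theta <- lapply(model$theta, function(t) t * 0)
  g_convW <- model$conv_W * 0; g_convb <- model$conv_b * 0
  g_denseW <- model$dense_W * 0; g_denseb <- model$dense_b * 0
  M <- nrow(model$W_star)
  g_Lt <- matrix(0, M, M)
  loss <- 0
  for (s in seq_len(B)) {
    fw <- dgcnn_forward_full(model, features[[s]])
    y <- labels[s]
    loss <- loss + cross_entropy_loss(fw$probs, y)
    dlogit <- fw$probs
    dlogit[y] <- dlogit[y] - 1
    dlogit <- dlogit / B
    g_denseW <- g_denseW + outer(fw$f, dlogit)
    g_denseb <- g_denseb + dlogit
    dH2 <- matrix(model$dense_W %*% dlogit, M, model$n_conv)
    dZ2 <- dH2 * (fw$Z2 > 0)
    g_convW <- g_convW + crossprod(fw$H1, dZ2)
    g_convb <- g_convb + colSums(dZ2)
    dH1 <- dZ2 %*% t(model$conv_W)
    dZ1 <- dH1 * (fw$Z1 > 0)
    XT <- vector("list", K)
    for (k in seq_len(K)) {
      g_theta[[k]] <- g_theta[[k]] + crossprod(fw$P[[k]], dZ1)
      XT[[k]] <- fw$X %*% model$theta[[k]]          # M x F1
    }
    # adjoint of the Chebyshev recursion w.r.t. L_tilde:
    # A_k = T_k(L_tilde); Z1 = sum_k A_k X theta_k
    A <- cheb_matrices(model$L_tilde, K)
    Bk <- lapply(seq_len(K), function(k) dZ1 %*% t(XT[[k]]))  # dLoss/dA_k
    if (K >= 3L) for (k in K:3L) {
      g_Lt <- g_Lt + 2 * (Bk[[k]] %*% t(A[[k - 1L]]))
      Bk[[k - 1L]] <- Bk[[k - 1L]] + 2 * (t(model$L_tilde) %*% Bk[[k]])
      Bk[[k - 2L]] <- Bk[[k - 2L]] - Bk[[k]]
    }
    if (K >= 2L) g_Lt <- g_Lt + Bk[[2L]]
  }
  loss <- loss / B
  # chain L_tilde -> W (lambda_max held fixed within the batch):
  # dLoss/dL = (2/lambda_max) g_Lt ; L = S - W with S_ii = sum_j w_ij
  dL <- (2 / model$lambda_max) * g_Lt
  g_W <- matrix(diag(dL), M, M) - dL
  list(theta = g_theta, conv_W = g_convW, conv_b = g_convb,
       dense_W = g_denseW, dense_b = g_denseb, W = g_W, loss = loss)
}

# T_k(L_tilde) themselves (square matrices), k = 0..K-1.
cheb_matrices <- function(L_tilde, K) {
  A <- vector("list", K)
  A[[1L]] <- diag(nrow(L_tilde))
  if (K >= 2L) A[[2L]] <- L_tilde
  if (K >= 3L) for (k in 3L:K)
    A[[k]] <- 2 * (L_tilde %*% A[[k - 1L]]) - A[[k - 2L]]
  A
}

#' Train a DGCNN by mini-batch backpropagation
#'
#' Plain SGD on the Chebyshev coefficients, pointwise convolution and dense
#' layer; when `cfg$adjacency_updates` is on, the adjacency is relaxed
#' toward the loss gradient after every batch and the rescaled Laplacian
#' (including its top eigenvalue) is recomputed.  Aborts on a non-finite
#' loss.  Deterministic given the config seed.
#'
#' @param model A [dgcnn_model()].
#' @param features List of `M_g x input_dim` node-signal matrices.
#' @param labels Integer class labels (1-based), one per feature matrix.
#' @param cfg A [train_config()].
#' @return List with the trained `model` and `loss_history` (one mean loss
#'   per epoch).
#' @export
train_dgcnn <- function(model, features, labels, cfg = train_config()) {
  stopifnot(inherits(model, "dgcnn_model"), length(features) >= 1L,
            length(features) == length(labels))
  labels <- as.integer(labels)
  history <- numeric(0)
  withr_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(features))
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        batch <- features[idx]
        if (isTRUE(cfg$augment_shift)) {
          batch <- lapply(batch, function(X) {
            s <- sample.int(ncol(X), 1L)
            if (s == ncol(X)) X else X[, c((s + 1L):ncol(X), 1L:s), drop = FALSE]
          })
        }
        g <- dgcnn_batch_gradients(model, batch, labels[idx])
        if (!is.finite(g$loss))
          stop("training diverged: non-finite loss at epoch ", ep,
               call. = FALSE)
        wd <- cfg$weight_decay %||% 0
        for (k in seq_len(model$K))
          model$theta[[k]] <- model$theta[[k]] -
            cfg$lr * (g$theta[[k]] + wd * model$theta[[k]])
        model$conv_W <- model$conv_W - cfg$lr * (g$conv_W + wd * model$conv_W)
        model$conv_b <- model$conv_b - cfg$lr * g$conv_b
        model$dense_W <- model$dense_W -
          cfg$lr * (g$dense_W + wd * model$dense_W)
        model$dense_b <- model$dense_b - cfg$lr * g$dense_b
        if (cfg$adjacency_updates && cfg$rho > 0) {
          W_new <- adjacency_update(model$W_star, g$W, cfg$rho,
                                    cfg$adjacency_mode)
          if (max(rowSums(W_new)) > 0) {
            model$W_star <- W_new
            resc <- rescale_laplacian(laplacian(W_new)$L)
            model$L_tilde <- resc$L_tilde
            model$lambda_max <- resc$lambda_max
          }
        }
        ep_loss <- ep_loss + g$loss; nb <- nb + 1L
      }
      history <- c(history, ep_loss / nb)
    }
  })
  list(model = model, loss_history = history)
}

#' Predict the class of one epoch
#'
#' @param object A trained `dgcnn_model`.
#' @param node_signals Node-signal matrix for one epoch.
#' @param ... Unused.
#' @return Integer class index (argmax of the forward probabilities).
#' @export
predict.dgcnn_model <- function(object, node_signals, ...) {
  which.max(dgcnn_forward(object, node_signals))
}

#' Classification accuracy over an evaluation set
#'
#' @param model A `dgcnn_model`.
#' @param features List of node-signal matrices.
#' @param labels Integer labels (1-based).
#' @return Fraction of correctly classified epochs.
#' @export
evaluate_accuracy <- function(model, features, labels) {
  if (length(features) == 0L) stop("empty evaluation set", call. = FALSE)
  pred <- vapply(features, function(X) predict(model, X), integer(1))
  mean(pred == as.integer(labels))
}
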