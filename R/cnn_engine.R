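# Internal 1-D CNN engine: im2col-based convolution, average pooling, fully
# connected layers, inverted dropout, Adam. Activations are stored as
# 3-D arrays (batch, length, channels); convolutions reduce to one BLAS
# matrix multiplication per layer via im2col.

# Flat gather indices mapping an (n, L, C) activation array to the
# (n*Lout, K*C) patch matrix (column order (k, c), k fastest). Cached per
# shape: the same few shapes recur for every batch.
.idx_cache <- new.env(parent = emptyenv())

im2col_idx <- function(n, L, C, K, stride) {
  key <- paste(n, L, C, K, stride, sep = "_")
  cached <- .idx_cache[[key]]
  if (!is.null(cached)) return(cached)
  Lout <- (L - K) %/% stride + 1L
  # input position l = (t-1)*stride + k for output position t, offset k;
  # Z element order is (i, t, k, c) with i fastest, matching a
  # (n*Lout) x (K*C) matrix whose columns are ordered (k, c)
  pos <- as.vector(outer(seq.int(0L, by = stride, length.out = Lout),
                         seq_len(K), "+"))        # order (t, k), t fastest
  idx <- rep(seq_len(n), times = Lout * K * C) +
    n * rep(pos - 1L, each = n, times = C) +
    (n * L) * rep(seq_len(C) - 1L, each = n * Lout * K)
  idx <- as.integer(idx)
  out <- list(idx = idx, Lout = Lout)
  .idx_cache[[key]] <- out
  out
}

# (n, L, C) -> (n*Lout, K*C) patch matrix via one flat gather.
im2col <- function(A, K, stride) {
  d <- dim(A)
  ic <- im2col_idx(d[1], d[2], d[3], K, stride)
  Z <- A[ic$idx]
  dim(Z) <- c(d[1] * ic$Lout, K * d[3])
  attr(Z, "Lout") <- ic$Lout
  Z
}

# Scatter-add the patch-matrix gradient back onto the input activations.
# Kernel offsets are scattered one at a time (their target positions are
# disjoint within an offset, so plain indexed addition is safe).
col2im <- function(dZ, dims, K, stride, Lout) {
  n <- dims[1]; L <- dims[2]; C <- dims[3]
  dim(dZ) <- c(n * Lout, K, C)
  dA <- array(0, dims)
  chan_off <- (seq_len(C) - 1L) * (n * L)
  base <- rep(seq_len(n), times = Lout) +
    rep((seq_len(Lout) - 1L) * stride, each = n) * n
  for (k in seq_len(K)) {
    tgt <- rep(base + (k - 1L) * n, times = C) +
      rep(chan_off, each = n * Lout)
    dA[tgt] <- dA[tgt] + as.vector(dZ[, k, ])
  }
  dA
}

conv1d_forward <- function(A, W, b, stride) {
  Z <- im2col(A, nrow(W) / dim(A)[3], stride)
  Lout <- attr(Z, "Lout")
  Y <- Z %*% W
  Y <- Y + rep(b, each = nrow(Y))   # per-column bias
  dim(Y) <- c(dim(A)[1], Lout, ncol(W))
  list(Y = Y, Z = Z, Lout = Lout)
}

conv1d_backward <- function(dY, cache, A_dims, W, stride, need_dA = TRUE) {
  F <- dim(dY)[3]
  dYm <- dY; dim(dYm) <- c(dim(dY)[1] * dim(dY)[2], F)
  dW <- crossprod(cache$Z, dYm)
  db <- colSums(dYm)
  dA <- if (need_dA) {
    col2im(dYm %*% t(W), A_dims, nrow(W) / A_dims[3], stride, cache$Lout)
  } else NULL
  list(dA = dA, dW = dW, db = db)
}

avgpool_forward <- function(A, K, stride) {
  d <- dim(A)
  Lout <- (d[2] - K) %/% stride + 1L
  Y <- array(0, c(d[1], Lout, d[3]))
  for (k in seq_len(K)) {
    idx <- seq.int(k, by = stride, length.out = Lout)
    Y <- Y + A[, idx, , drop = FALSE]
  }
  Y / K
}

avgpool_backward <- function(dY, A_dims, K, stride) {
  Lout <- dim(dY)[2]
  dA <- array(0, A_dims)
  g <- dY / K
  for (k in seq_len(K)) {
    idx <- seq.int(k, by = stride, length.out = Lout)
    dA[, idx, ] <- dA[, idx, ] + g
  }
  dA
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Uniform fan-in-scaled initialization: U(-sqrt(6/fan_in), +sqrt(6/fan_in)).
init_uniform <- function(nr, nc, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Allocate and initialize all trainable parameters for a model config.
cnn_init <- function(config, seed) {
  s <- cnn_shapes(config)
  with_seed(seed, {
    p <- list()
    Cin <- 1L
    for (i in seq_along(config$conv_layers)) {
      cl <- config$conv_layers[[i]]
      fan_in <- cl$kernel * Cin
      p[[paste0("W_conv", i)]] <- init_uniform(fan_in, cl$filters, fan_in)
      p[[paste0("b_conv", i)]] <- numeric(cl$filters)
      Cin <- cl$filters
    }
    n_in <- s$flat
    for (i in seq_along(config$fc_sizes)) {
      n_out <- config$fc_sizes[i]
      p[[paste0("W_fc", i)]] <- init_uniform(n_in, n_out, n_in)
      p[[paste0("b_fc", i)]] <- numeric(n_out)
      n_in <- n_out
    }
    p
  })
}

# Temporal lengths through the network and the flattened feature size.
cnn_shapes <- function(config) {
  L <- config$input_length
  cl <- config$conv_layers
  L1 <- conv_output_length(L, cl[[1]]$kernel, cl[[1]]$stride)
  L2 <- conv_output_length(L1, cl[[2]]$kernel, cl[[2]]$stride)
  L3 <- conv_output_length(L2, config$pool_kernel, config$pool_stride)
  L4 <- conv_output_length(L3, cl[[3]]$kernel, cl[[3]]$stride)
  L5 <- conv_output_length(L4, config$pool_kernel, config$pool_stride)
  list(lengths = c(L1, L2, L3, L4, L5), flat = L5 * cl[[3]]$filters)
}

# Forward pass. X: (n x input_length) matrix. Returns sigmoid probabilities
# and, when `training`, the caches needed for the backward pass (dropout
# masks are drawn from the current RNG stream).
cnn_forward <- function(params, X, config, training = FALSE) {
  n <- nrow(X)
  A0 <- array(X, c(n, ncol(X), 1L))
  cl <- config$conv_layers

  c1 <- conv1d_forward(A0, params$W_conv1, params$b_conv1, cl[[1]]$stride)
  A1 <- relu(c1$Y)
  c2 <- conv1d_forward(A1, params$W_conv2, params$b_conv2, cl[[2]]$stride)
  A2 <- relu(c2$Y)
  P2 <- avgpool_forward(A2, config$pool_kernel, config$pool_stride)
  c3 <- conv1d_forward(P2, params$W_conv3, params$b_conv3, cl[[3]]$stride)
  A3 <- relu(c3$Y)
  P3 <- avgpool_forward(A3, config$pool_kernel, config$pool_stride)
  Fl <- P3; dim(Fl) <- c(n, prod(dim(P3)[2:3]))

  Z1 <- sweep(Fl %*% params$W_fc1, 2, params$b_fc1, "+")
  H1 <- relu(Z1)
  if (training && config$dropout[1] > 0) {
    m1 <- matrix(stats::runif(length(H1)) >= config$dropout[1],
                 nrow(H1), ncol(H1)) / (1 - config$dropout[1])
    H1d <- H1 * m1
  } else { m1 <- NULL; H1d <- H1 }
  Z2 <- sweep(H1d %*% params$W_fc2, 2, params$b_fc2, "+")
  H2 <- relu(Z2)
  if (training && config$dropout[2] > 0) {
    m2 <- matrix(stats::runif(length(H2)) >= config$dropout[2],
                 nrow(H2), ncol(H2)) / (1 - config$dropout[2])
    H2d <- H2 * m2
  } else { m2 <- NULL; H2d <- H2 }
  Z3 <- sweep(H2d %*% params$W_fc3, 2, params$b_fc3, "+")
  prob <- 1 / (1 + exp(-as.numeric(Z3)))

  out <- list(prob = prob)
  if (training) {
    out$cache <- list(A0 = A0, c1 = c1, A1 = A1, c2 = c2, A2 = A2, P2 = P2,
                      c3 = c3, A3 = A3, P3 = P3, Fl = Fl,
                      Z1 = Z1, H1 = H1, m1 = m1, H1d = H1d,
                      Z2 = Z2, H2 = H2, m2 = m2, H2d = H2d)
  }
  out
}

# Backward pass for the weighted binary cross entropy (mean over the batch)
# with L2 penalty on the first convolutional layer's weights.
cnn_backward <- function(params, cache, y, prob, weights, config) {
  n <- length(y)
  cl <- config$conv_layers
  # d(loss)/d(logit) for sigmoid + weighted BCE
  dz <- (weights$w1 * y * (prob - 1) + weights$w0 * (1 - y) * prob) / n
  dZ3 <- matrix(dz, n, 1)

  g <- list()
  g$W_fc3 <- crossprod(cache$H2d, dZ3)
  g$b_fc3 <- colSums(dZ3)
  dH2d <- dZ3 %*% t(params$W_fc3)
  if (!is.null(cache$m2)) dH2d <- dH2d * cache$m2
  dZ2 <- dH2d * (cache$Z2 > 0)
  g$W_fc2 <- crossprod(cache$H1d, dZ2)
  g$b_fc2 <- colSums(dZ2)
  dH1d <- dZ2 %*% t(params$W_fc2)
  if (!is.null(cache$m1)) dH1d <- dH1d * cache$m1
  dZ1 <- dH1d * (cache$Z1 > 0)
  g$W_fc1 <- crossprod(cache$Fl, dZ1)
  g$b_fc1 <- colSums(dZ1)
  dFl <- dZ1 %*% t(params$W_fc1)

  dP3 <- dFl; dim(dP3) <- dim(cache$P3)
  dA3 <- avgpool_backward(dP3, dim(cache$A3), config$pool_kernel,
                          config$pool_stride)
  dY3 <- dA3 * (cache$c3$Y > 0)
  b3 <- conv1d_backward(dY3, cache$c3, dim(cache$P2), params$W_conv3,
                        cl[[3]]$stride)
  g$W_conv3 <- b3$dW; g$b_conv3 <- b3$db
  dA2 <- avgpool_backward(b3$dA, dim(cache$A2), config$pool_kernel,
                          config$pool_stride)
  dY2 <- dA2 * (cache$c2$Y > 0)
  b2 <- conv1d_backward(dY2, cache$c2, dim(cache$A1), params$W_conv2,
                        cl[[2]]$stride)
  g$W_conv2 <- b2$dW; g$b_conv2 <- b2$db
  dY1 <- b2$dA * (cache$c1$Y > 0)
  b1 <- conv1d_backward(dY1, cache$c1, dim(cache$A0), params$W_conv1,
                        cl[[1]]$stride, need_dA = FALSE)
  g$W_conv1 <- b1$dW + 2 * config$l2_conv1 * params$W_conv1
  g$b_conv1 <- b1$db
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
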