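# Internal neural-network layer engine.
#
# Activations flow through the network as a matrix [features x batch]; an
# image tensor (H, W, C) is flattened column-major with the row index
# fastest, so "flatten" between the convolutional stack and the fully
# connected stack is a no-op. Each convolution block (im2col convolution,
# optional batch normalization, rectifier, optional 2x2 max pool) is a
# fused compiled kernel pair (src/nn_kernels.cpp) whose backward pass
# recomputes block intermediates from the cached block input, so no
# multi-megabyte tensors cross the R heap per mini-batch. The fully
# connected stack runs as ordinary R matrix products plus compiled
# batch-norm/rectifier element-wise kernels. Every gradient is exact
# (verified against finite differences in the test suite).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# ---- fused convolution block ----
# stride-1 "same" zero-padded convolution with an odd kernel

conv_im2col_index <- function(H, W, C, k) {
  off <- (k - 1L) %/% 2L
  da <- rep(seq.int(-off, off), times = k * C)
  db <- rep(rep(seq.int(-off, off), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  iv <- rep(seq_len(H), times = W)
  jv <- rep(seq_len(W), each = H)
  I <- outer(da, iv, "+")                       # (k*k*C) x (H*W)
  J <- outer(db, jv, "+")
  flat <- I + (J - 1L) * H + (cc - 1L) * (H * W)
  flat[I < 1L | I > H | J < 1L | J > W] <- H * W * C + 1L  # sentinel: zero pad
  storage.mode(flat) <- "integer"
  flat
}

pool_block_index <- function(H, W, C) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  bi <- 2L * rep(seq_len(Ho), times = Wo) - 1L
  bj <- 2L * rep(seq_len(Wo), each = Ho) - 1L
  vapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(d) {
    ch1 <- (bi + d[1L]) + (bj + d[2L] - 1L) * H
    as.integer(outer(ch1, (seq_len(C) - 1L) * H * W, "+"))
  }, integer(Ho * Wo * C))
}

layer_conv_block <- function(in_shape, filters, kernel, use_bn) {
  H <- in_shape[1L]; W <- in_shape[2L]; C <- in_shape[3L]
  if (kernel %% 2L != 1L) stop("kernel size must be odd")
  if (kernel > H || kernel > W) stop("kernel larger than input")
  kkC <- kernel * kernel * C
  use_pool <- (H %% 2L == 0L) && (W %% 2L == 0L)
  params <- list(W = matrix(stats::rnorm(filters * kkC, sd = sqrt(2 / kkC)),
                            filters, kkC),
                 b = numeric(filters))
  if (use_bn) {
    params$gamma <- rep(1, filters)
    params$beta <- numeric(filters)
  }
  list(type = "conv_block", in_shape = in_shape,
       conv_shape = c(H, W, filters),
       out_shape = if (use_pool) c(H %/% 2L, W %/% 2L, filters)
                   else c(H, W, filters),
       kernel = kernel, kkC = kkC, idx = conv_im2col_index(H, W, C, kernel),
       use_bn = use_bn, use_pool = use_pool,
       Q = if (use_pool) pool_block_index(H, W, filters)
           else matrix(integer(0), 0L, 4L),
       run_mean = numeric(if (use_bn) filters else 0L),
       run_var = rep(1, if (use_bn) filters else 0L),
       params = params)
}

block_forward <- function(layer, X, training) {
  p <- layer$params
  r <- block_fwd_cpp(X, layer$idx, p$W, p$b,
                     layer$use_bn, p$gamma %||% numeric(0),
                     p$beta %||% numeric(0), BN_EPS, training,
                     layer$run_mean, layer$run_var,
                     layer$use_pool, layer$Q)
  if (training && layer$use_bn) {
    layer$run_mean <- BN_MOMENTUM * layer$run_mean +
      (1 - BN_MOMENTUM) * as.vector(r$mu)
    layer$run_var <- BN_MOMENTUM * layer$run_var +
      (1 - BN_MOMENTUM) * as.vector(r$var)
  }
  list(out = r$out,
       cache = if (training) list(X = X, mu = r$mu, var = r$var,
                                  amax = r$amax),
       layer = layer)
}

block_backward <- function(layer, cache, dOut) {
  p <- layer$params
  r <- block_bwd_cpp(cache$X, dOut, layer$idx, p$W, p$b,
                     layer$use_bn, p$gamma %||% numeric(0),
                     p$beta %||% numeric(0), BN_EPS,
                     cache$mu, cache$var, layer$use_pool, layer$Q,
                     cache$amax)
  grads <- list(W = r$dW, b = as.vector(r$db))
  if (layer$use_bn) {
    grads$gamma <- as.vector(r$dgamma)
    grads$beta <- as.vector(r$dbeta)
  }
  list(dX = r$dX, grads = grads)
}

# ---- batch normalization (fully connected stack; one row per neuron) ----

layer_bn <- function(channels, group = 1L) {
  list(type = "bn", channels = channels, group = group,
       params = list(gamma = rep(1, channels), beta = numeric(channels)),
       run_mean = numeric(channels), run_var = rep(1, channels))
}

bn_forward <- function(layer, X, training) {
  r <- bn_fwd_cpp(X, layer$channels, layer$group, layer$params$gamma,
                  layer$params$beta, BN_EPS, training,
                  layer$run_mean, layer$run_var)
  if (training) {
    layer$run_mean <- BN_MOMENTUM * layer$run_mean +
      (1 - BN_MOMENTUM) * as.vector(r$mu)
    layer$run_var <- BN_MOMENTUM * layer$run_var +
      (1 - BN_MOMENTUM) * as.vector(r$var)
  }
  list(out = r$out,
       cache = if (training) list(X = X, mu = r$mu, invstd = r$invstd),
       layer = layer)
}

bn_backward <- function(layer, cache, dOut) {
  r <- bn_bwd_cpp(dOut, cache$X, cache$mu, cache$invstd,
                  layer$params$gamma, layer$group)
  list(dX = r$dX, grads = list(gamma = as.vector(r$dgamma),
                               beta = as.vector(r$dbeta)))
}

# ---- rectifier / fully connected ----

layer_relu <- function(n) list(type = "relu", n = n, params = list())

layer_dense <- function(in_dim, out_dim) {
  list(type = "dense", in_dim = in_dim, out_dim = out_dim,
       params = list(W = matrix(stats::rnorm(out_dim * in_dim,
                                             sd = sqrt(2 / in_dim)),
                                out_dim, in_dim),
                     b = numeric(out_dim)))
}

# ---- network-level forward / backward ----

nn_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    lay <- layers[[l]]
    r <- switch(lay$type,
      conv_block = {
        rr <- block_forward(lay, X, training)
        if (training) layers[[l]] <- rr$layer  # running stats updated
        rr
      },
      bn = {
        rr <- bn_forward(lay, X, training)
        if (training) layers[[l]] <- rr$layer
        rr
      },
      relu = {
        out <- relu_fwd_cpp(X)
        list(out = out, cache = out)
      },
      dense = list(out = lay$params$W %*% X + lay$params$b, cache = X),
      stop("unknown layer type"))
    caches[[l]] <- r$cache
    X <- r$out
  }
  list(out = X, caches = caches, layers = layers)
}

nn_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    lay <- layers[[l]]
    r <- switch(lay$type,
      conv_block = block_backward(lay, caches[[l]], dOut),
      bn = bn_backward(lay, caches[[l]], dOut),
      relu = list(dX = relu_bwd_cpp(dOut, caches[[l]]), grads = list()),
      dense = list(dX = crossprod(lay$params$W, dOut),
                   grads = list(W = tcrossprod(dOut, caches[[l]]),
                                b = rowSums(dOut))),
      stop("unknown layer type"))
    grads[[l]] <- r$grads
    dOut <- r$dX
  }
  list(dX = dOut, grads = grads)
}
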