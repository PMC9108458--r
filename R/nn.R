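# Minimal CPU backprop engine used by the GAN and U-Net modules.
#
# Batch tensors are 4-D arrays with dim = (H, W, C, N) so that R's
# column-major layout keeps spatial positions contiguous. Convolutions are
# evaluated through im2col + one matrix multiply; the backward pass scatters
# gradients back with k*k vectorized slice additions. No batch-coupling
# layers exist anywhere (a requirement for per-sample DP gradients).
#
# A network is a list of layer lists; each layer carries its type, its
# parameters (`W`, `b` where applicable), and static geometry. The engine is
# internal; the GAN/U-Net constructors are the public surface.

nn_conv <- function(in_ch, out_ch, kernel, stride = 1L, pad = 0L,
                    init_gain = 1) {
  fan_in <- in_ch * kernel * kernel
  W <- matrix(stats::rnorm(fan_in * out_ch, sd = init_gain * sqrt(2 / fan_in)),
              fan_in, out_ch)
  list(type = "conv", W = W, b = numeric(out_ch),
       in_ch = in_ch, out_ch = out_ch, kernel = as.integer(kernel),
       stride = as.integer(stride), pad = as.integer(pad))
}

nn_dense <- function(in_dim, out_dim, init_gain = 1) {
  W <- matrix(stats::rnorm(in_dim * out_dim, sd = init_gain * sqrt(2 / in_dim)),
              in_dim, out_dim)
  list(type = "dense", W = W, b = numeric(out_dim),
       in_dim = as.integer(in_dim), out_dim = as.integer(out_dim))
}

nn_act <- function(kind, slope = 0.2) {
  list(type = "act", kind = kind, slope = slope)
}

nn_upsample2 <- function() list(type = "upsample2")

nn_reshape <- function(shape) list(type = "reshape", shape = as.integer(shape))

nn_flatten <- function() list(type = "flatten")

# geometry-keyed cache: im2col index vectors are identical across steps for
# a fixed layer/input shape, so build them once per session
.nn_geom_cache <- new.env(parent = emptyenv())

im2col_index_cached <- function(Hp, Wp, C, k, stride, N) {
  key <- paste(Hp, Wp, C, k, stride, N, sep = "_")
  hit <- .nn_geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  ii <- im2col_index(Hp, Wp, C, k, stride)
  per <- Hp * Wp * C
  ii$batch_idx <- rep(ii$idx, times = N) +
    rep((0:(N - 1L)) * per, each = length(ii$idx))
  .nn_geom_cache[[key]] <- ii
  ii
}

# gather-index vector for im2col on a padded (Hp, Wp, C) image; columns are
# output positions (oh fastest), rows are (a, b, c) kernel offsets
im2col_index <- function(Hp, Wp, C, k, stride) {
  oH <- (Hp - k) %/% stride + 1L
  oW <- (Wp - k) %/% stride + 1L
  a <- 1:k
  off <- as.vector(outer(outer(a, (a - 1L) * Hp, `+`), (0:(C - 1L)) * Hp * Wp, `+`))
  oh <- (0:(oH - 1L)) * stride
  ow <- (0:(oW - 1L)) * stride * Hp
  base <- as.vector(outer(oh, ow, `+`))
  list(idx = rep(base, each = length(off)) + off, oH = oH, oW = oW,
       rows = length(off), cols = length(base))
}

pad_input <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), , ] <- x
  xp
}

conv_forward <- function(layer, x) {
  d <- dim(x)
  N <- d[4]
  xp <- pad_input(x, layer$pad)
  dp <- dim(xp)
  ii <- im2col_index_cached(dp[1], dp[2], dp[3], layer$kernel, layer$stride, N)
  cols <- matrix(xp[ii$batch_idx], nrow = ii$rows)
  y <- crossprod(layer$W, cols) + layer$b          # C_out x (oH*oW*N)
  out <- aperm(array(y, c(layer$out_ch, ii$oH, ii$oW, N)), c(2, 3, 1, 4))
  list(out = out, cache = list(cols = cols, dims_pad = dp, ii = ii, N = N,
                               dims_in = d))
}

conv_backward <- function(layer, cache, dout) {
  ii <- cache$ii
  N <- cache$N
  dy <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = layer$out_ch)
  dW <- cache$cols %*% t(dy)
  db <- rowSums(dy)
  dcols <- layer$W %*% dy                           # rows x (oH*oW*N)
  dp <- cache$dims_pad
  k <- layer$kernel
  s <- layer$stride
  dxp <- array(0, dp)
  dc6 <- array(dcols, c(k, k, layer$in_ch, ii$oH, ii$oW, N))
  ridx <- (0:(ii$oH - 1L)) * s
  cidx <- (0:(ii$oW - 1L)) * s
  for (a in 1:k) for (b in 1:k) {
    sl <- dc6[a, b, , , , , drop = FALSE]
    dim(sl) <- dim(sl)[3:6]                       # (C_in, oH, oW, N)
    dxp[ridx + a, cidx + b, , ] <- dxp[ridx + a, cidx + b, , , drop = FALSE] +
      aperm(sl, c(2, 3, 1, 4))
  }
  p <- layer$pad
  d <- cache$dims_in
  dx <- if (p == 0L) dxp else dxp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ,
                                  drop = FALSE]
  dim(dx) <- d
  list(dx = dx, grads = list(W = dW, b = db))
}

dense_forward <- function(layer, x) {
  # x: matrix (in_dim x N)
  list(out = crossprod(layer$W, x) + layer$b, cache = list(x = x))
}

dense_backward <- function(layer, cache, dout) {
  list(dx = layer$W %*% dout,
       grads = list(W = cache$x %*% t(dout), b = rowSums(dout)))
}

act_forward <- function(layer, x) {
  out <- switch(layer$kind,
    leaky_relu = pmax(x, 0) + layer$slope * pmin(x, 0),
    relu = pmax(x, 0),
    tanh = tanh(x),
    sigmoid = 1 / (1 + exp(-x)),
    stop("unknown activation ", layer$kind))
  list(out = out, cache = list(x = x, out = out))
}

act_backward <- function(layer, cache, dout) {
  g <- switch(layer$kind,
    leaky_relu = (cache$x > 0) + layer$slope * (cache$x <= 0),
    relu = as.numeric(cache$x > 0),
    tanh = 1 - cache$out^2,
    sigmoid = cache$out * (1 - cache$out))
  list(dx = dout * g, grads = NULL)
}

upsample2_forward <- function(layer, x) {
  d <- dim(x)
  out <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
           drop = FALSE]
  list(out = out, cache = list(dims_in = d))
}

upsample2_backward <- function(layer, cache, dout) {
  d <- cache$dims_in
  o <- seq_len(d[1]) * 2L
  p <- seq_len(d[2]) * 2L
  dx <- dout[o - 1L, p - 1L, , , drop = FALSE] +
    dout[o - 1L, p, , , drop = FALSE] +
    dout[o, p - 1L, , , drop = FALSE] +
    dout[o, p, , , drop = FALSE]
  list(dx = dx, grads = NULL)
}

reshape_forward <- function(layer, x) {
  d_in <- dim2(x)
  N <- if (is.matrix(x)) ncol(x) else d_in[length(d_in)]
  out <- x
  dim(out) <- c(layer$shape, N)
  list(out = out, cache = list(dims_in = dim2(x)))
}

reshape_backward <- function(layer, cache, dout) {
  dx <- dout
  dim(dx) <- cache$dims_in
  list(dx = dx, grads = NULL)
}

flatten_forward <- function(layer, x) {
  d <- dim(x)
  out <- x
  dim(out) <- c(prod(d[-length(d)]), d[length(d)])
  list(out = out, cache = list(dims_in = d))
}

flatten_backward <- function(layer, cache, dout) {
  dx <- dout
  dim(dx) <- cache$dims_in
  list(dx = dx, grads = NULL)
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = conv_forward(layer, x),
    dense = dense_forward(layer, x),
    act = act_forward(layer, x),
    upsample2 = upsample2_forward(layer, x),
    reshape = reshape_forward(layer, x),
    flatten = flatten_forward(layer, x),
    stop("unknown layer type ", layer$type))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = conv_backward(layer, cache, dout),
    dense = dense_backward(layer, cache, dout),
    act = act_backward(layer, cache, dout),
    upsample2 = upsample2_backward(layer, cache, dout),
    reshape = reshape_backward(layer, cache, dout),
    flatten = flatten_backward(layer, cache, dout))
}

net_forward <- function(net, x, keep_cache = TRUE) {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    fw <- layer_forward(net$layers[[i]], x)
    x <- fw$out
    if (keep_cache) caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches)
}

# returns list(grads = per-layer list(W, b) or NULL, dx = grad wrt input)
net_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    bw <- layer_backward(net$layers[[i]], caches[[i]], dout)
    dout <- bw$dx
    grads[i] <- list(bw$grads)   # keep NULL slots for parameter-free layers
  }
  list(grads = grads, dx = dout)
}

# ---- parameter plumbing -----------------------------------------------------

net_param_layers <- function(net) {
  which(vapply(net$layers, function(l) !is.null(l$W), logical(1)))
}

net_flatten_params <- function(net) {
  unlist(lapply(net_param_layers(net), function(i) {
    c(as.numeric(net$layers[[i]]$W), net$layers[[i]]$b)
  }))
}

net_set_params <- function(net, theta) {
  pos <- 0L
  for (i in net_param_layers(net)) {
    nw <- length(net$layers[[i]]$W)
    nb <- length(net$layers[[i]]$b)
    net$layers[[i]]$W[] <- theta[(pos + 1L):(pos + nw)]
    net$layers[[i]]$b <- theta[(pos + nw + 1L):(pos + nw + nb)]
    pos <- pos + nw + nb
  }
  stopifnot(pos == length(theta))
  net
}

grads_flatten <- function(net, grads) {
  unlist(lapply(net_param_layers(net), function(i) {
    c(as.numeric(grads[[i]]$W), grads[[i]]$b)
  }))
}

net_clip_weights <- function(net, clip) {
  for (i in net_param_layers(net)) {
    net$layers[[i]]$W[] <- pmin(pmax(net$layers[[i]]$W, -clip), clip)
    net$layers[[i]]$b <- pmin(pmax(net$layers[[i]]$b, -clip), clip)
  }
  net
}

net_max_abs_weight <- function(net) {
  max(vapply(net_param_layers(net), function(i) {
    max(abs(net$layers[[i]]$W), if (length(net$layers[[i]]$b)) abs(net$layers[[i]]$b) else 0)
  }, numeric(1)))
}

# ---- RMSprop ---------------------------------------------------------------

rmsprop_state <- function(n_params) list(v = numeric(n_params))

# returns list(theta, state); plain RMSprop, no momentum, matching the
# common deep-learning default (alpha = 0.99, eps = 1e-8)
rmsprop_step <- function(theta, grad, state, lr, alpha = 0.99, eps = 1e-8) {
  state$v <- alpha * state$v + (1 - alpha) * grad^2
  theta <- theta - lr * grad / (sqrt(state$v) + eps)
  list(theta = theta, state = state)
}
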