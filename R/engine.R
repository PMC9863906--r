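# Volumetric network engine: building blocks, forward/backward passes and
# the Adam update.  Tensors are plain R arrays with dim = (X, Y, Z, C),
# channels last; the convolution kernels live in src/conv3d.cpp and are
# driven from here.  Transposed convolution is the adjoint of a strided
# convolution, so it reuses the same compiled primitives with the data /
# gradient roles swapped.

IN_EPS <- 1e-5

#' Create one network block
#'
#' A block is a (transposed) 3D convolution optionally followed by instance
#' normalisation, a pointwise activation, dropout, and a residual skip.
#' Weights are initialised from N(0, 0.02^2) using the current RNG state.
#'
#' @param type `"conv"` (strided convolution) or `"tconv"` (transposed
#'   convolution, spatial upsampling by `stride`).
#' @param in_ch,out_ch channel counts.
#' @param k cubic kernel side.
#' @param stride stride (1 keeps the grid, 2 halves or doubles it).
#' @param norm apply instance normalisation after the convolution?
#' @param act one of `"lrelu"`, `"relu"`, `"sigmoid"`, `"softmax"`, `"none"`.
#' @param dropout dropout probability applied after the activation
#'   (training mode only).
#' @param residual add the block input to its output (requires matching
#'   shape, i.e. stride 1 and `in_ch == out_ch`).
#' @param lrelu_slope negative-side slope of the leaky ReLU.
#' @return a list describing the block, with initialised parameters.
#' @keywords internal
new_block <- function(type = c("conv", "tconv"), in_ch, out_ch, k = 4L,
                      stride = 2L, norm = TRUE, act = "lrelu",
                      dropout = 0, residual = FALSE, lrelu_slope = 0.2) {
  type <- match.arg(type)
  if (residual && (stride != 1L || in_ch != out_ch))
    stop("residual blocks require stride 1 and matching channel counts")
  # weight matrix rows follow the kernel layout of the compiled primitives;
  # for tconv the underlying convolution maps out_ch -> in_ch
  ci <- if (type == "conv") in_ch else out_ch
  co <- if (type == "conv") out_ch else in_ch
  W <- matrix(stats::rnorm(k^3 * ci * co, sd = 0.02), nrow = k^3 * ci, ncol = co)
  blk <- list(
    type = type, in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
    k = as.integer(k), stride = as.integer(stride), padlo = 1L,
    norm = isTRUE(norm), act = act, dropout = dropout,
    residual = isTRUE(residual), lrelu_slope = lrelu_slope,
    W = W, b = numeric(out_ch)
  )
  if (blk$norm) {
    blk$gamma <- rep(1, out_ch)
    blk$beta <- numeric(out_ch)
  }
  blk
}

block_param_names <- function(blk) {
  c("W", "b", if (blk$norm) c("gamma", "beta"))
}

# ---- pointwise activations --------------------------------------------------

act_forward <- function(act, z, slope) {
  switch(act,
    none    = z,
    relu    = pmax(z, 0),
    lrelu   = ifelse(z > 0, z, slope * z),
    sigmoid = 1 / (1 + exp(-z)),
    softmax = {
      C <- dim(z)[4]
      m <- matrix(z, ncol = C)
      m <- exp(m - apply(m, 1L, max))
      m <- m / rowSums(m)
      array(m, dim(z))
    },
    stop("unknown activation: ", act)
  )
}

act_backward <- function(act, y, z, gy, slope) {
  switch(act,
    none    = gy,
    relu    = gy * (z > 0),
    lrelu   = gy * ifelse(z > 0, 1, slope),
    sigmoid = gy * y * (1 - y),
    softmax = {
      C <- dim(y)[4]
      s <- matrix(y, ncol = C)
      g <- matrix(gy, ncol = C)
      dot <- rowSums(g * s)
      array(s * (g - dot), dim(y))
    },
    stop("unknown activation: ", act)
  )
}

# ---- instance normalisation -------------------------------------------------

inorm_forward <- function(z, gamma, beta) {
  dm <- dim(z)
  C <- dm[4]
  m <- matrix(z, ncol = C)
  mu <- colMeans(m)
  v <- colMeans(m * m) - mu^2
  istd <- 1 / sqrt(pmax(v, 0) + IN_EPS)
  xhat <- sweep(m, 2L, mu) * rep(istd, each = nrow(m))
  y <- sweep(xhat * rep(gamma, each = nrow(m)), 2L, beta, "+")
  list(y = array(y, dm), xhat = xhat, istd = istd)
}

inorm_backward <- function(cache, gamma, gy) {
  dm <- dim(gy)
  C <- dm[4]
  g <- matrix(gy, ncol = C)
  n <- nrow(g)
  xhat <- cache$xhat
  dgamma <- colSums(g * xhat)
  dbeta <- colSums(g)
  dxh <- g * rep(gamma, each = n)
  s1 <- colSums(dxh)
  s2 <- colSums(dxh * xhat)
  dx <- rep(cache$istd / n, each = n) *
    (n * dxh - rep(s1, each = n) - xhat * rep(s2, each = n))
  list(gx = array(dx, dm), dgamma = dgamma, dbeta = dbeta)
}

# ---- block forward / backward ----------------------------------------------

block_forward <- function(blk, x, training = FALSE) {
  dmx <- dim(x)
  if (dmx[4] != blk$in_ch)
    stop(sprintf("block expects %d input channels, got %d", blk$in_ch, dmx[4]))
  cache <- list(xdim = dmx)
  if (blk$type == "conv") {
    z <- cpp_conv3d_fwd(x, dmx, blk$W, blk$b, blk$k, blk$stride, blk$padlo)
  } else {
    bigdim <- c(dmx[1:3] * blk$stride, blk$out_ch)
    z <- cpp_conv3d_bwd_data(x, blk$W, blk$k, blk$stride, blk$padlo,
                             as.integer(bigdim))
    z <- z + rep(blk$b, each = prod(bigdim[1:3]))
    dim(z) <- bigdim
  }
  if (blk$norm) {
    nf <- inorm_forward(z, blk$gamma, blk$beta)
    cache$norm <- nf[c("xhat", "istd")]
    h <- nf$y
  } else {
    h <- z
  }
  cache$z <- if (blk$act %in% c("relu", "lrelu")) h else NULL
  a <- act_forward(blk$act, h, blk$lrelu_slope)
  cache$y_act <- if (blk$act %in% c("sigmoid", "softmax")) a else NULL
  if (training && blk$dropout > 0) {
    keep <- 1 - blk$dropout
    mask <- (stats::runif(length(a)) < keep) / keep
    cache$drop_mask <- mask
    a <- a * mask
  }
  if (blk$residual) a <- a + x
  cache$xin <- x  # retained for the filter gradient
  list(out = a, cache = cache)
}

block_backward <- function(blk, cache, gy) {
  g_res <- if (blk$residual) gy else NULL
  g <- gy
  if (!is.null(cache$drop_mask)) g <- g * cache$drop_mask
  g <- act_backward(blk$act, cache$y_act, cache$z, g, blk$lrelu_slope)
  dim(g) <- out_dims_of(blk, cache$xdim)
  grads <- list()
  if (blk$norm) {
    nb <- inorm_backward(cache$norm, blk$gamma, g)
    grads$gamma <- nb$dgamma
    grads$beta <- nb$dbeta
    g <- nb$gx
  }
  x <- cache$xin
  if (blk$type == "conv") {
    bf <- cpp_conv3d_bwd_filter(x, cache$xdim, g, blk$out_ch,
                                blk$k, blk$stride, blk$padlo)
    grads$W <- bf$W
    grads$b <- bf$b
    gx <- cpp_conv3d_bwd_data(g, blk$W, blk$k, blk$stride, blk$padlo,
                              as.integer(cache$xdim))
  } else {
    # adjoint roles: filter gradient pairs the big tensor (g) with the small
    # one (x); data gradient is a plain strided convolution of g
    bigdim <- c(cache$xdim[1:3] * blk$stride, blk$out_ch)
    Cm <- matrix(g, ncol = blk$out_ch)
    grads$b <- colSums(Cm)
    bf <- cpp_conv3d_bwd_filter(g, as.integer(bigdim), x, blk$in_ch,
                                blk$k, blk$stride, blk$padlo)
    grads$W <- bf$W
    gx <- cpp_conv3d_fwd(g, as.integer(bigdim), blk$W,
                         numeric(blk$in_ch), blk$k, blk$stride, blk$padlo)
  }
  if (blk$residual) gx <- gx + g_res
  list(gx = gx, grads = grads)
}

out_dims_of <- function(blk, xdim) {
  sp <- if (blk$type == "conv") ceiling(xdim[1:3] / blk$stride)
        else xdim[1:3] * blk$stride
  as.integer(c(sp, blk$out_ch))
}

# ---- whole-network passes ---------------------------------------------------

# Blocks may declare `skip_from = j`: the output of block j is concatenated
# (channel-wise) to the running activation before the block is applied —
# the encoder-decoder skip connections of the U-net-style generator.

net_forward <- function(net, x, training = FALSE, keep_cache = TRUE) {
  n <- length(net$blocks)
  caches <- if (keep_cache) vector("list", n)
  has_skips <- any(vapply(net$blocks, function(b) !is.null(b$skip_from),
                          logical(1)))
  outs <- if (has_skips) vector("list", n)
  for (i in seq_len(n)) {
    blk <- net$blocks[[i]]
    if (!is.null(blk$skip_from))
      x <- concat_channels(x, outs[[blk$skip_from]])
    fw <- block_forward(blk, x, training = training)
    x <- fw$out
    if (keep_cache) caches[[i]] <- fw$cache
    if (has_skips) outs[[i]] <- x
  }
  list(out = x, caches = caches)
}

net_backward <- function(net, caches, gout, want_input_grad = FALSE) {
  n <- length(net$blocks)
  grads <- vector("list", n)
  skip_g <- vector("list", n)  # gradients arriving via skip connections
  g <- gout
  for (i in rev(seq_len(n))) {
    blk <- net$blocks[[i]]
    if (!is.null(skip_g[[i]])) g <- g + skip_g[[i]]
    bb <- block_backward(blk, caches[[i]], g)
    grads[[i]] <- bb$grads
    g <- bb$gx
    if (!is.null(blk$skip_from)) {
      ch_main <- blk$in_ch - net$blocks[[blk$skip_from]]$out_ch
      gskip <- g[, , , (ch_main + 1L):blk$in_ch, drop = FALSE]
      sf <- blk$skip_from
      skip_g[[sf]] <- if (is.null(skip_g[[sf]])) gskip else
        skip_g[[sf]] + gskip
      g <- g[, , , seq_len(ch_main), drop = FALSE]
    }
  }
  list(gx = if (want_input_grad) g else NULL, grads = grads)
}

# Gradient of the network output w.r.t. its input only (weights untouched,
# no filter gradients computed).  Used when the generator is updated through
# a frozen discriminator.
net_input_grad <- function(net, caches, gout) {
  g <- gout
  for (i in rev(seq_along(net$blocks))) {
    blk <- net$blocks[[i]]
    cache <- caches[[i]]
    g_res <- if (blk$residual) g else NULL
    if (!is.null(cache$drop_mask)) g <- g * cache$drop_mask
    g <- act_backward(blk$act, cache$y_act, cache$z, g, blk$lrelu_slope)
    dim(g) <- out_dims_of(blk, cache$xdim)
    if (blk$norm) g <- inorm_backward(cache$norm, blk$gamma, g)$gx
    if (blk$type == "conv") {
      g <- cpp_conv3d_bwd_data(g, blk$W, blk$k, blk$stride, blk$padlo,
                               as.integer(cache$xdim))
    } else {
      bigdim <- c(cache$xdim[1:3] * blk$stride, blk$out_ch)
      g <- cpp_conv3d_fwd(g, as.integer(bigdim), blk$W,
                          numeric(blk$in_ch), blk$k, blk$stride, blk$padlo)
    }
    if (blk$residual) g <- g + g_res
  }
  g
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(net) {
  states <- lapply(net$blocks, function(blk) {
    lapply(stats::setNames(nm = block_param_names(blk)), function(p) {
      list(m = blk[[p]] * 0, v = blk[[p]] * 0)
    })
  })
  list(t = 0L, states = states)
}

adam_step <- function(net, grads, lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(net$opt)) net$opt <- adam_init(net)
  net$opt$t <- net$opt$t + 1L
  t <- net$opt$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(net$blocks)) {
    for (p in block_param_names(net$blocks[[i]])) {
      g <- grads[[i]][[p]]
      if (is.null(g)) next
      st <- net$opt$states[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      net$opt$states[[i]][[p]] <- st
      net$blocks[[i]][[p]] <- net$blocks[[i]][[p]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  net
}
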