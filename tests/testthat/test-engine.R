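# The compiled convolution primitives and the backpropagation machinery.

eng <- asNamespace("tumorgan")

test_that("compiled 3D convolution matches a direct loop implementation", {
  set.seed(11)
  cases <- list(list(d = c(6, 6, 6, 2), co = 3, s = 2),
                list(d = c(5, 4, 6, 1), co = 2, s = 2),
                list(d = c(5, 5, 5, 2), co = 2, s = 1))
  for (cs in cases) {
    x <- array(rnorm(prod(cs$d)), cs$d)
    Wm <- matrix(rnorm(64 * cs$d[4] * cs$co, sd = 0.1), 64 * cs$d[4], cs$co)
    b <- rnorm(cs$co)
    got <- eng$cpp_conv3d_fwd(x, dim(x), Wm, b, 4L, cs$s, 1L)
    want <- oracle_conv3d(x, Wm, b, 4L, cs$s, 1L)
    expect_equal(as.vector(got), as.vector(want), tolerance = 1e-12)
    expect_identical(dim(got), dim(want))
  }
})

test_that("convolution backward passes agree with central differences", {
  set.seed(12)
  for (s in c(1L, 2L)) {
    d <- c(6, 6, 6, 2)
    co <- 2L
    x <- array(rnorm(prod(d)), d)
    Wm <- matrix(rnorm(64 * d[4] * co, sd = 0.2), 64 * d[4], co)
    b <- rnorm(co)
    gdim <- c(ceiling(d[1:3] / s), co)
    g <- array(rnorm(prod(gdim)), gdim)
    loss <- function(xx, WW, bb)
      sum(eng$cpp_conv3d_fwd(xx, d, WW, bb, 4L, s, 1L) * g)
    gx <- eng$cpp_conv3d_bwd_data(g, Wm, 4L, s, 1L, as.integer(d))
    bf <- eng$cpp_conv3d_bwd_filter(x, as.integer(d), g, co, 4L, s, 1L)
    eps <- 1e-6
    for (i in sample(length(x), 8)) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      expect_equal(gx[i], (loss(xp, Wm, b) - loss(xm, Wm, b)) / (2 * eps),
                   tolerance = 1e-5)
    }
    for (i in sample(length(Wm), 8)) {
      Wp <- Wm; Wp[i] <- Wp[i] + eps
      Wn <- Wm; Wn[i] <- Wn[i] - eps
      expect_equal(bf$W[i], (loss(x, Wp, b) - loss(x, Wn, b)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("transposed convolution is the exact adjoint of the strided one", {
  # <conv(v), u> == <v, tconv(u)> for all v, u
  set.seed(13)
  blk <- eng$new_block("tconv", in_ch = 3, out_ch = 2, stride = 2L,
                       norm = FALSE, act = "none")
  v <- array(rnorm(8^3 * 2), c(8, 8, 8, 2))
  u <- array(rnorm(4^3 * 3), c(4, 4, 4, 3))
  blk$b[] <- 0  # pure linear map on both sides
  conv_v <- eng$cpp_conv3d_fwd(v, dim(v), blk$W, numeric(3), 4L, 2L, 1L)
  tconv_u <- eng$block_forward(blk, u)$out
  expect_equal(sum(conv_v * u), sum(v * tconv_u), tolerance = 1e-10)
})

test_that("end-to-end generator parameter gradients match finite differences", {
  gen <- build_generator(generator_spec(base_filters = 2, dropout = 0),
                         seed = 7)
  set.seed(2)
  x <- array(rnorm(32^3 * 4), c(32, 32, 32, 4))
  set.seed(3)
  gt <- array(rnorm(32^3 * 4), c(32, 32, 32, 4))
  fobj <- function(net)
    sum(eng$net_forward(net, x, keep_cache = FALSE)$out * gt)
  fw <- eng$net_forward(gen, x)
  bb <- eng$net_backward(gen, fw$caches, gt)
  eps <- 1e-5
  set.seed(4)
  # one weight and one scale parameter from a down, residual, up and head
  # block each
  for (bi in c(2L, 6L, 10L, 12L)) {
    for (p in intersect(c("W", "gamma"),
                        eng$block_param_names(gen$blocks[[bi]]))) {
      i <- sample(length(gen$blocks[[bi]][[p]]), 1)
      gp <- gen; gp$blocks[[bi]][[p]][i] <- gp$blocks[[bi]][[p]][i] + eps
      gm <- gen; gm$blocks[[bi]][[p]][i] <- gm$blocks[[bi]][[p]][i] - eps
      num <- (fobj(gp) - fobj(gm)) / (2 * eps)
      expect_equal(bb$grads[[bi]][[p]][i], num, tolerance = 5e-3)
    }
  }
})

test_that("discriminator input gradients match finite differences", {
  disc <- build_discriminator(discriminator_spec(base_filters = 2), seed = 9)
  set.seed(5)
  x <- array(rnorm(32^3 * 8), c(32, 32, 32, 8))
  fw <- eng$net_forward(disc, x)
  gset <- array(rnorm(length(fw$out)), dim(fw$out))
  gin <- eng$net_input_grad(disc, fw$caches, gset)
  fobj <- function(xx)
    sum(eng$net_forward(disc, xx, keep_cache = FALSE)$out * gset)
  eps <- 1e-5
  for (i in sample(length(x), 6)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal(gin[i], (fobj(xp) - fobj(xm)) / (2 * eps),
                 tolerance = 5e-3)
  }
})

test_that("instance norm output has zero mean and unit variance per channel", {
  set.seed(6)
  z <- array(rnorm(10^3 * 3, mean = 4, sd = 9), c(10, 10, 10, 3))
  y <- eng$inorm_forward(z, gamma = rep(1, 3), beta = rep(0, 3))$y
  m <- matrix(y, ncol = 3)
  expect_lt(max(abs(colMeans(m))), 1e-10)
  expect_lt(max(abs(colMeans(m^2) - 1)), 1e-4)
})
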