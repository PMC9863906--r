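# Generator and discriminator construction.
#
# Generator: 4 stride-2 down-sampling conv blocks (leaky ReLU, filters
# doubling from `base_filters`), 4 stride-1 residual blocks with dropout at
# the bottleneck, 3 stride-2 transposed-conv up-sampling blocks (ReLU), and
# a final stride-2 transposed-conv head with a per-voxel softmax over the
# four tissue classes.  For a 128-cube patch and base 64 the flow is
# 128^3x4 -> 64^3x64 -> 32^3x128 -> 16^3x256 -> 8^3x512 -> (residuals)
# 8^3x512 -> 16^3x512 -> 32^3x256 -> 64^3x128 -> 128^3x4.
#
# Discriminator: the image patch concatenated with a 4-channel segmentation
# (one-hot truth or generator softmax) runs through 4 stride-2 conv blocks
# to 8^3x512, then a stride-1 single-filter conv with sigmoid yields an
# 8^3x1 patch of realness scores.

#' Generator architecture description
#'
#' @param in_channels number of image modalities (4: T1, T1gd, T2, FLAIR).
#' @param base_filters filters of the first down-sampling block; doubled
#'   after every subsequent one.
#' @param n_down_blocks stride-2 down-sampling blocks.
#' @param n_residual_blocks stride-1 residual blocks at the bottleneck.
#' @param n_up_blocks stride-2 up-sampling blocks before the head.
#' @param kernel_size cubic kernel side used throughout.
#' @param dropout dropout probability inside residual blocks.
#' @param out_channels segmentation classes emitted by the softmax head.
#' @param lrelu_slope negative slope of the leaky ReLU in the down path.
#' @param skip_connections concatenate each encoder resolution's features
#'   to the matching decoder stage (the U-net-style design of the
#'   volumetric image-to-image family this generator follows).  Block
#'   *output* channels are unchanged; only decoder input widths grow.
#'   `FALSE` gives a plain encoder-decoder chain.
#' @return an object of class `"generator_spec"`.
#' @export
generator_spec <- function(in_channels = 4L, base_filters = 64L,
                           n_down_blocks = 4L, n_residual_blocks = 4L,
                           n_up_blocks = 3L, kernel_size = 4L,
                           dropout = 0.2, out_channels = 4L,
                           lrelu_slope = 0.2, skip_connections = TRUE) {
  spec <- list(in_channels = as.integer(in_channels),
               base_filters = as.integer(base_filters),
               n_down_blocks = as.integer(n_down_blocks),
               n_residual_blocks = as.integer(n_residual_blocks),
               n_up_blocks = as.integer(n_up_blocks),
               kernel_size = as.integer(kernel_size),
               dropout = dropout,
               out_channels = as.integer(out_channels),
               lrelu_slope = lrelu_slope,
               skip_connections = isTRUE(skip_connections))
  stopifnot(spec$base_filters >= 1L, spec$n_down_blocks >= 1L,
            spec$dropout >= 0, spec$dropout < 1)
  structure(spec, class = "generator_spec")
}

#' Discriminator architecture description
#'
#' @param in_channels image channels plus segmentation channels (4 + 4).
#' @param base_filters filters of the first block, doubled per block.
#' @param n_down_blocks stride-2 down-sampling blocks.
#' @param kernel_size cubic kernel side.
#' @param lrelu_slope negative slope of the leaky ReLU.
#' @return an object of class `"discriminator_spec"`.
#' @export
discriminator_spec <- function(in_channels = 8L, base_filters = 64L,
                               n_down_blocks = 4L, kernel_size = 4L,
                               lrelu_slope = 0.2) {
  spec <- list(in_channels = as.integer(in_channels),
               base_filters = as.integer(base_filters),
               n_down_blocks = as.integer(n_down_blocks),
               kernel_size = as.integer(kernel_size),
               lrelu_slope = lrelu_slope)
  stopifnot(spec$base_filters >= 1L, spec$n_down_blocks >= 1L)
  structure(spec, class = "discriminator_spec")
}

#' Build the segmentation generator
#'
#' Instantiates the encoder-residual-decoder generator with freshly
#' initialised weights (zero-mean Gaussians, sd 0.02).  The returned network
#' maps a `(P, P, P, in_channels)` patch to a `(P, P, P, out_channels)`
#' per-voxel class-probability field; `P` must be divisible by
#' `2^(n_down_blocks)`.
#'
#' @param spec a [generator_spec()].
#' @param seed optional integer; when given, weight initialisation is run
#'   under this seed without disturbing the caller's RNG stream.
#' @return an object of class `c("tumorgan_generator", "tumorgan_net")`.
#' @export
build_generator <- function(spec = generator_spec(), seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  build <- function() {
    f <- spec$base_filters
    k <- spec$kernel_size
    blocks <- list()
    ch <- spec$in_channels
    for (i in seq_len(spec$n_down_blocks)) {
      out <- f * 2^(i - 1)
      blocks[[length(blocks) + 1L]] <-
        new_block("conv", ch, out, k = k, stride = 2L, norm = i > 1L,
                  act = "lrelu", lrelu_slope = spec$lrelu_slope)
      ch <- out
    }
    for (i in seq_len(spec$n_residual_blocks)) {
      blocks[[length(blocks) + 1L]] <-
        new_block("conv", ch, ch, k = k, stride = 1L, norm = TRUE,
                  act = "lrelu", dropout = spec$dropout, residual = TRUE,
                  lrelu_slope = spec$lrelu_slope)
    }
    # encoder block index whose features feed decoder stage i (i = 2 ..
    # n_up + 1, the head being the last stage); stage 1 sees only the
    # residual bottleneck
    skip_src <- function(i) {
      j <- spec$n_down_blocks - i + 1L
      if (j >= 1L) j else NULL
    }
    for (i in seq_len(spec$n_up_blocks)) {
      # decoder channels 8f, 4f, 2f so the head sees 2f (128 at base 64)
      out <- if (i == 1L) f * 2^(spec$n_down_blocks - 1L)
             else f * 2^(spec$n_down_blocks - i)
      skip <- if (spec$skip_connections && i > 1L) skip_src(i) else NULL
      in_ch <- ch + if (is.null(skip)) 0L else blocks[[skip]]$out_ch
      blk <- new_block("tconv", in_ch, out, k = k, stride = 2L, norm = TRUE,
                       act = "relu")
      blk$skip_from <- skip
      blocks[[length(blocks) + 1L]] <- blk
      ch <- out
    }
    skip <- if (spec$skip_connections) skip_src(spec$n_up_blocks + 1L)
            else NULL
    in_ch <- ch + if (is.null(skip)) 0L else blocks[[skip]]$out_ch
    blk <- new_block("tconv", in_ch, spec$out_channels, k = k, stride = 2L,
                     norm = FALSE, act = "softmax")
    blk$skip_from <- skip
    blocks[[length(blocks) + 1L]] <- blk
    structure(list(blocks = blocks, spec = spec, opt = NULL),
              class = c("tumorgan_generator", "tumorgan_net"))
  }
  if (is.null(seed)) build() else with_preserved_seed(seed, build())
}

#' Build the patch discriminator
#'
#' The discriminator scores (image, segmentation) pairs: the 4 image
#' channels are concatenated with a 4-channel segmentation (one-hot ground
#' truth or generator softmax) and mapped to a `(P/2^n, P/2^n, P/2^n, 1)`
#' patch of realness scores in (0, 1).
#'
#' @param spec a [discriminator_spec()].
#' @param seed optional initialisation seed, as in [build_generator()].
#' @return an object of class `c("tumorgan_discriminator", "tumorgan_net")`.
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = NULL) {
  stopifnot(inherits(spec, "discriminator_spec"))
  build <- function() {
    f <- spec$base_filters
    k <- spec$kernel_size
    blocks <- list()
    ch <- spec$in_channels
    for (i in seq_len(spec$n_down_blocks)) {
      out <- f * 2^(i - 1)
      blocks[[length(blocks) + 1L]] <-
        new_block("conv", ch, out, k = k, stride = 2L, norm = i > 1L,
                  act = "lrelu", lrelu_slope = spec$lrelu_slope)
      ch <- out
    }
    blocks[[length(blocks) + 1L]] <-
      new_block("conv", ch, 1L, k = k, stride = 1L, norm = FALSE,
                act = "sigmoid")
    structure(list(blocks = blocks, spec = spec, opt = NULL),
              class = c("tumorgan_discriminator", "tumorgan_net"))
  }
  if (is.null(seed)) build() else with_preserved_seed(seed, build())
}

# run expr under a temporary seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Apply a built network to an input tensor
#'
#' @param net a network from [build_generator()] or [build_discriminator()].
#' @param x array of dim `(X, Y, Z, C)`; for the discriminator, image and
#'   segmentation already concatenated along the channel axis.
#' @param training evaluate in training mode (dropout active)?
#' @return the output array.
#' @export
net_apply <- function(net, x, training = FALSE) {
  stopifnot(inherits(net, "tumorgan_net"))
  check_input_side(net, dim(x))
  net_forward(net, x, training = training, keep_cache = FALSE)$out
}

check_input_side <- function(net, dm) {
  if (length(dm) != 4L)
    stop("input must be a 4-d array (X, Y, Z, channels)")
  n_halvings <- sum(vapply(net$blocks, function(b)
    b$type == "conv" && b$stride == 2L, logical(1)))
  div <- 2L^n_halvings
  # the generator must also climb back up: it needs the same divisibility
  if (inherits(net, "tumorgan_generator")) div <- 2L^net$spec$n_down_blocks
  if (any(dm[1:3] %% div != 0L))
    stop(sprintf("input side (%s) must be divisible by %d",
                 paste(dm[1:3], collapse = "x"), div))
  if (dm[4] != net$blocks[[1L]]$in_ch)
    stop(sprintf("input has %d channels, network expects %d",
                 dm[4], net$blocks[[1L]]$in_ch))
  invisible(TRUE)
}

#' Analytic shape flow of a network
#'
#' Computes, without building or running the network, the output dimensions
#' of every block for a cubic input of side `patch_size`.  Useful for
#' verifying the architecture against its printed shape flow (e.g. a
#' 128-cube generator bottleneck of 8x8x8x512 and a discriminator output of
#' 8x8x8x1 at base 64).
#'
#' @param spec a [generator_spec()] or [discriminator_spec()].
#' @param patch_size input cube side.
#' @return data.frame with columns `block`, `side`, `channels`.
#' @export
network_shapes <- function(spec, patch_size) {
  P <- as.integer(patch_size)
  rows <- list()
  add <- function(name, side, ch)
    rows[[length(rows) + 1L]] <<- data.frame(block = name, side = side,
                                             channels = ch)
  if (inherits(spec, "generator_spec")) {
    if (P %% 2L^spec$n_down_blocks != 0L)
      stop("patch_size must be divisible by 2^n_down_blocks")
    add("input", P, spec$in_channels)
    side <- P
    for (i in seq_len(spec$n_down_blocks)) {
      side <- side %/% 2L
      add(paste0("down", i), side, spec$base_filters * 2L^(i - 1L))
    }
    bott_ch <- spec$base_filters * 2L^(spec$n_down_blocks - 1L)
    for (i in seq_len(spec$n_residual_blocks))
      add(paste0("residual", i), side, bott_ch)
    ch <- bott_ch
    for (i in seq_len(spec$n_up_blocks)) {
      side <- side * 2L
      ch <- if (i == 1L) bott_ch else ch %/% 2L
      add(paste0("up", i), side, ch)
    }
    add("head", side * 2L, spec$out_channels)
  } else if (inherits(spec, "discriminator_spec")) {
    add("input", P, spec$in_channels)
    side <- P
    for (i in seq_len(spec$n_down_blocks)) {
      side <- side %/% 2L
      add(paste0("down", i), side, spec$base_filters * 2L^(i - 1L))
    }
    add("final", side, 1L)
  } else {
    stop("spec must be a generator_spec or discriminator_spec")
  }
  do.call(rbind, rows)
}

#' Count network parameters
#'
#' @param net a built network.
#' @return named numeric vector with elements `trainable`, `non_trainable`
#'   and `total`.  All parameters of this engine (convolution weights and
#'   biases, instance-norm scales and shifts) are trainable.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "tumorgan_net"))
  trainable <- sum(vapply(net$blocks, function(blk) {
    sum(vapply(block_param_names(blk), function(p) length(blk[[p]]),
               numeric(1)))
  }, numeric(1)))
  c(trainable = trainable, non_trainable = 0, total = trainable)
}
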