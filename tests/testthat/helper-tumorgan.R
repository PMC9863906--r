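# Shared fixtures and independent brute-force oracles.  Oracles are kept
# deliberately naive (explicit loops, direct formula transcription) so they
# are independent of the vectorised / compiled implementation paths they
# check.

# small deterministic phantom configuration for fast tests
tiny_phantom_config <- function(n_cases = 2L, seed = 7L, grid = 32L,
                                noise_sigma = 5) {
  phantom_config(grid_size = grid, tumour_radius_range = c(5, 9),
                 noise_sigma = noise_sigma, n_cases = n_cases, seed = seed)
}

# direct seven-loop 3D convolution (same padding, zero fill)
oracle_conv3d <- function(x, Wm, b, k, stride, padlo) {
  d <- dim(x)
  X <- d[1]; Y <- d[2]; Z <- d[3]; Ci <- d[4]
  Co <- ncol(Wm)
  os <- function(n) ceiling(n / stride)
  out <- array(0, c(os(X), os(Y), os(Z), Co))
  for (co in 1:Co) for (zo in 1:os(Z)) for (yo in 1:os(Y)) for (xo in 1:os(X)) {
    acc <- b[co]
    for (ci in 1:Ci) for (kz in 1:k) for (ky in 1:k) for (kx in 1:k) {
      xi <- (xo - 1) * stride - padlo + kx
      yi <- (yo - 1) * stride - padlo + ky
      zi <- (zo - 1) * stride - padlo + kz
      if (xi >= 1 && xi <= X && yi >= 1 && yi <= Y && zi >= 1 && zi <= Z) {
        row <- (kx - 1) + k * ((ky - 1) + k * ((kz - 1) + k * (ci - 1))) + 1
        acc <- acc + x[xi, yi, zi, ci] * Wm[row, co]
      }
    }
    out[xo, yo, zo, co] <- acc
  }
  out
}

# brute-force voxel-counting dice on binarised masks
oracle_dice_whole <- function(pred, truth) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(pred)) {
    a <- pred[i] > 0
    b <- truth[i] > 0
    if (a && b) inter <- inter + 1
    if (a) na <- na + 1
    if (b) nb <- nb + 1
  }
  if (na + nb == 0) 1 else 2 * inter / (na + nb)
}

# direct windowed SSIM on a 2-d slice: explicit loops over window corners,
# population moments, standard stabilisation constants
oracle_ssim_2d <- function(x, y, w = 7L, L = 1) {
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  nx <- nrow(x) - w + 1L
  ny <- ncol(x) - w + 1L
  vals <- numeric(0)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    px <- x[i:(i + w - 1L), j:(j + w - 1L)]
    py <- y[i:(i + w - 1L), j:(j + w - 1L)]
    mx <- mean(px); my <- mean(py)
    vx <- mean((px - mx)^2); vy <- mean((py - my)^2)
    cxy <- mean((px - mx) * (py - my))
    vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  mean(vals)
}

# scalar transcription of the generalized dice loss formula for tiny inputs
oracle_gdl <- function(yt, yp, weights, eps = 1e-6) {
  num <- 0; den <- 0
  for (cl in seq_len(ncol(yt))) {
    num <- num + weights[cl] * sum(yt[, cl] * yp[, cl])
    den <- den + weights[cl] * (sum(yt[, cl]) + sum(yp[, cl]))
  }
  1 - (2 * num + eps) / (den + eps)
}

# the package's documented desk-scale training recipe: 20 single-patch
# phantoms at 32^3, base 8 filters, 30 epochs; returns held-out scores and
# the per-epoch generator-loss trend
desk_scale_run <- function(seed = 42L) {
  pcfg <- phantom_config(grid_size = 32L, tumour_radius_range = c(5, 9),
                         n_cases = 23L, seed = seed)
  cases <- lapply(1:20, function(i)
    normalize_intensity(generate_phantom(pcfg, i)))
  patches <- unlist(lapply(cases, extract_patches, patch_size = 32L),
                    recursive = FALSE)
  fit <- tumorgan_fit(
    patches,
    gen_spec = generator_spec(base_filters = 8L),
    disc_spec = discriminator_spec(base_filters = 8L),
    loss_cfg = loss_config(),
    config = train_config(epochs = 30L, batch_size = 4L, patch_size = 32L,
                          learning_rate = 1e-3, augment = FALSE,
                          seed = seed))
  dsc <- vapply(21:23, function(i) {
    ho <- normalize_intensity(generate_phantom(pcfg, i))
    dice_coefficient(predict(fit, ho, patch_size = 32L), ho$labels)
  }, numeric(1))
  per_epoch_gl <- tapply(fit$history$GL, fit$history$epoch, mean)
  ne <- length(per_epoch_gl)
  list(fit = fit, holdout_dsc = dsc, holdout_mean_dsc = mean(dsc),
       gl_first5 = mean(per_epoch_gl[1:5]),
       gl_last5 = mean(per_epoch_gl[(ne - 4L):ne]))
}

# the per-image metric rows of the reference evaluation shipped with the
# package
reference_metrics <- function() {
  read.csv(system.file("extdata", "reference_case_metrics.csv",
                       package = "tumorgan"), comment.char = "#")
}
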