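# Alternating adversarial training and sliding-window prediction.
#
# Each step takes one batch: (1) the discriminator is updated to push
# D(x, y) towards 1 and D(x, yhat) towards 0 with the generator's output
# treated as a constant; (2) the generator is updated through the frozen,
# freshly-updated discriminator to push D(x, yhat) towards 1 while
# minimising the weighted generalized dice loss against the ground truth.
# The whole loop is a pure function of (config, dataset order, seed).

#' Training configuration
#'
#' @param epochs passes over the patch set.
#' @param batch_size patches per optimisation step.
#' @param patch_size cube side the networks are trained on (divisible
#'   by 16).
#' @param learning_rate Adam step size for both networks.
#' @param beta1,beta2 Adam moment decays (`beta1 = 0.5` is the customary
#'   choice for this GAN family).
#' @param seed integer seed controlling initialisation, shuffling,
#'   augmentation and dropout.
#' @param augment apply a random label-preserving flip/rotation to each
#'   patch every time it is drawn (the patch-augmentation step of the
#'   preprocessing pipeline).
#' @param checkpoint_every write a checkpoint every this many epochs
#'   (0 disables).
#' @param checkpoint_dir directory for checkpoints.
#' @return an object of class `"train_config"`.
#' @export
train_config <- function(epochs = 100L, batch_size = 4L, patch_size = 128L,
                         learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                         seed = 1L, augment = TRUE, checkpoint_every = 0L,
                         checkpoint_dir = NULL) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              patch_size = as.integer(patch_size),
              learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
              seed = as.integer(seed), augment = isTRUE(augment),
              checkpoint_every = as.integer(checkpoint_every),
              checkpoint_dir = checkpoint_dir)
  if (cfg$epochs < 0L) stop("epochs must be >= 0")
  if (cfg$batch_size < 1L) stop("batch_size must be >= 1")
  if (cfg$patch_size %% 16L != 0L)
    stop("patch_size must be divisible by 16")
  structure(cfg, class = "train_config")
}

grads_add <- function(a, b) {
  for (i in seq_along(a)) for (p in names(b[[i]]))
    a[[i]][[p]] <- a[[i]][[p]] + b[[i]][[p]]
  a
}
grads_scale <- function(a, s) rapply(a, function(x) x * s, how = "replace")

concat_channels <- function(image, seg) {
  dm <- dim(image)
  out <- array(0, c(dm[1:3], dm[4] + dim(seg)[4]))
  out[, , , seq_len(dm[4])] <- image
  out[, , , dm[4] + seq_len(dim(seg)[4])] <- seg
  out
}

#' Fit the adversarial segmentation model
#'
#' Trains a generator/discriminator pair on a set of patches and returns a
#' fitted model object with the full per-step loss history.
#'
#' @param patches list of [segmentation_patch()] (normalise intensities
#'   before extraction).
#' @param gen_spec,disc_spec architecture descriptions; base filters and
#'   block counts must agree on the shared down-sampling factor.
#' @param loss_cfg a [loss_config()].
#' @param config a [train_config()].
#' @param verbose print one line per epoch to stderr.
#' @return an object of class `"tumorgan"` with elements `generator`,
#'   `discriminator`, `history` (data.frame with one row per step:
#'   `epoch`, `step`, `GL`, `adv_term`, `dice_term`, `DL`, `accuracy`),
#'   and the configurations used.
#' @export
tumorgan_fit <- function(patches,
                         gen_spec = generator_spec(),
                         disc_spec = discriminator_spec(
                           base_filters = gen_spec$base_filters),
                         loss_cfg = loss_config(),
                         config = train_config(),
                         verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (config$epochs > 0L && length(patches) == 0L)
    stop("training with epochs > 0 requires a non-empty patch set")
  set.seed(config$seed)
  gen <- build_generator(gen_spec)
  disc <- build_discriminator(disc_spec)

  n <- length(patches)
  steps_per_epoch <- if (n > 0) ceiling(n / config$batch_size) else 0L
  hist_rows <- vector("list", config$epochs * steps_per_epoch)
  step_global <- 0L

  for (epoch in seq_len(config$epochs)) {
    order_idx <- sample.int(n)
    for (s in seq_len(steps_per_epoch)) {
      idx <- order_idx[((s - 1L) * config$batch_size + 1L):
                         min(s * config$batch_size, n)]
      nb <- length(idx)
      gdD <- NULL
      gdG <- NULL
      gl_sum <- adv_sum <- dice_sum <- dl_sum <- acc_sum <- 0

      # ---- pass 1: generator forward + discriminator update ----
      gen_out <- vector("list", nb)
      batch <- lapply(idx, function(i)
        if (config$augment) augment_patch(patches[[i]]) else patches[[i]])
      for (j in seq_len(nb)) {
        pt <- batch[[j]]
        fwd <- net_forward(gen, pt$image, training = TRUE)
        gen_out[[j]] <- fwd
        yhat <- fwd$out
        d_real_in <- concat_channels(pt$image, pt$labels_onehot)
        d_fake_in <- concat_channels(pt$image, yhat)
        fr <- net_forward(disc, d_real_in)
        ff <- net_forward(disc, d_fake_in)
        dl <- discriminator_loss(fr$out, ff$out)
        dl_sum <- dl_sum + dl$DL
        br <- net_backward(disc, fr$caches, l1_to_constant_grad(fr$out, 1))
        bf <- net_backward(disc, ff$caches, l1_to_constant_grad(ff$out, 0))
        g <- grads_add(br$grads, bf$grads)
        gdD <- if (is.null(gdD)) g else grads_add(gdD, g)
      }
      disc <- adam_step(disc, grads_scale(gdD, 1 / nb),
                        lr = config$learning_rate, beta1 = config$beta1,
                        beta2 = config$beta2)

      # ---- pass 2: generator update through the frozen discriminator ----
      for (j in seq_len(nb)) {
        pt <- batch[[j]]
        yhat <- gen_out[[j]]$out
        d_fake_in <- concat_channels(pt$image, yhat)
        ff <- net_forward(disc, d_fake_in)
        gl <- generator_loss(ff$out, pt$labels_onehot, yhat, loss_cfg)
        gl_sum <- gl_sum + gl$GL
        adv_sum <- adv_sum + gl$adv_term
        dice_sum <- dice_sum + gl$dice_term
        acc_sum <- acc_sum +
          mean(onehot_to_labels(yhat) == onehot_to_labels(pt$labels_onehot))
        gin <- net_input_grad(disc, ff$caches,
                              l1_to_constant_grad(ff$out, 1))
        n_img <- dim(pt$image)[4]
        g_yhat <- gin[, , , n_img + seq_len(dim(yhat)[4]), drop = FALSE] +
          loss_cfg$alpha *
            generalized_dice_loss_grad(pt$labels_onehot, yhat, loss_cfg)
        bg <- net_backward(gen, gen_out[[j]]$caches, g_yhat)
        gdG <- if (is.null(gdG)) bg$grads else grads_add(gdG, bg$grads)
      }
      gen <- adam_step(gen, grads_scale(gdG, 1 / nb),
                       lr = config$learning_rate, beta1 = config$beta1,
                       beta2 = config$beta2)

      step_global <- step_global + 1L
      hist_rows[[step_global]] <- data.frame(
        epoch = epoch, step = step_global,
        GL = gl_sum / nb, adv_term = adv_sum / nb,
        dice_term = dice_sum / nb, DL = dl_sum / nb,
        accuracy = acc_sum / nb)
    }
    if (verbose && steps_per_epoch > 0) {
      last <- hist_rows[[step_global]]
      message(sprintf("epoch %3d/%d  GL %.4f (adv %.4f, dice %.4f)  DL %.4f  acc %.3f",
                      epoch, config$epochs, last$GL, last$adv_term,
                      last$dice_term, last$DL, last$accuracy))
    }
    if (config$checkpoint_every > 0L && !is.null(config$checkpoint_dir) &&
        epoch %% config$checkpoint_every == 0L) {
      model <- new_tumorgan(gen, disc, loss_cfg, config,
                            do.call(rbind, hist_rows[seq_len(step_global)]))
      save_checkpoint(model,
                      file.path(config$checkpoint_dir,
                                sprintf("checkpoint_epoch%04d.rds", epoch)))
    }
  }

  history <- if (step_global > 0) do.call(rbind, hist_rows) else
    data.frame(epoch = integer(), step = integer(), GL = numeric(),
               adv_term = numeric(), dice_term = numeric(), DL = numeric(),
               accuracy = numeric())
  new_tumorgan(gen, disc, loss_cfg, config, history)
}

new_tumorgan <- function(gen, disc, loss_cfg, config, history) {
  structure(list(generator = gen, discriminator = disc,
                 loss_config = loss_cfg, train_config = config,
                 history = history),
            class = "tumorgan")
}

#' Segment a full volume with a generator
#'
#' Runs the generator over a covering tiling of the volume, averages the
#' per-class probabilities where patches overlap, and takes the per-voxel
#' argmax.  The output grid equals the input grid.
#'
#' @param gen a built generator (or a fitted `"tumorgan"` model, whose
#'   generator is used).
#' @param case a [multimodal_case()], already intensity-normalised the
#'   same way as the training data.
#' @param patch_size cube side for tiling; every axis of the volume must
#'   be at least this.
#' @param stride tiling step (defaults to `patch_size`).
#' @param return_prob also return the averaged probability field?
#' @return integer label volume, or (with `return_prob`) a list with
#'   `labels` and `prob`.
#' @export
predict_case <- function(gen, case, patch_size, stride = patch_size,
                         return_prob = FALSE) {
  if (inherits(gen, "tumorgan")) gen <- gen$generator
  stopifnot(inherits(gen, "tumorgan_generator"),
            inherits(case, "multimodal_case"))
  dims <- dim(case$labels)
  P <- as.integer(patch_size)
  if (any(dims < P))
    stop(sprintf("volume %s smaller than patch size %d on some axis",
                 paste(dims, collapse = "x"), P))
  starts <- lapply(dims, patch_starts, P = P, S = as.integer(stride))
  C <- gen$spec$out_channels
  prob_sum <- array(0, c(dims, C))
  count <- array(0, dims)
  for (z0 in starts[[3]]) for (y0 in starts[[2]]) for (x0 in starts[[1]]) {
    ix <- x0 + seq_len(P)
    iy <- y0 + seq_len(P)
    iz <- z0 + seq_len(P)
    p <- net_forward(gen, case$image[ix, iy, iz, , drop = FALSE],
                     training = FALSE, keep_cache = FALSE)$out
    prob_sum[ix, iy, iz, ] <- prob_sum[ix, iy, iz, , drop = FALSE] + p
    count[ix, iy, iz] <- count[ix, iy, iz] + 1
  }
  prob <- prob_sum / as.vector(count)
  labels <- onehot_to_labels(prob)
  if (return_prob) list(labels = labels, prob = prob) else labels
}

#' Save / load a self-describing checkpoint
#'
#' The checkpoint carries both network specs and weights, the loss and
#' training configurations, the history so far, and the RNG state, so a
#' run can be inspected or resumed from the file alone.
#'
#' @param model a fitted `"tumorgan"` object.
#' @param path file path (`.rds`).
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   returns the `"tumorgan"` object.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "tumorgan"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  payload <- list(model = model,
                  rng_state = if (exists(".Random.seed", envir = globalenv()))
                    get(".Random.seed", envir = globalenv()) else NULL,
                  package_version = as.character(utils::packageVersion("tumorgan")))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  if (!inherits(payload$model, "tumorgan"))
    stop("not a tumorgan checkpoint: ", path)
  if (!is.null(payload$rng_state))
    assign(".Random.seed", payload$rng_state, envir = globalenv())
  payload$model
}
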