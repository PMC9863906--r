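# Training loop contracts: no-op fits, determinism, history bookkeeping,
# parameter isolation, sliding-window prediction.

make_tiny_patches <- function(n_cases = 2L, seed = 31L) {
  cfg <- tiny_phantom_config(n_cases = n_cases, seed = seed)
  cases <- lapply(seq_len(n_cases), function(i)
    normalize_intensity(generate_phantom(cfg, i)))
  unlist(lapply(cases, extract_patches, patch_size = 32),
         recursive = FALSE)
}

tiny_fit <- function(patches, epochs = 2L, seed = 1L) {
  tumorgan_fit(patches,
               gen_spec = generator_spec(base_filters = 4),
               disc_spec = discriminator_spec(base_filters = 4),
               loss_cfg = loss_config(),
               config = train_config(epochs = epochs, batch_size = 2,
                                     patch_size = 32, seed = seed))
}

test_that("zero epochs returns untouched networks and an empty history", {
  patches <- make_tiny_patches(1L)
  fit <- tiny_fit(patches, epochs = 0L)
  expect_s3_class(fit, "tumorgan")
  expect_equal(nrow(fit$history), 0)
  # weights equal a fresh build under the same seed (no update happened)
  set.seed(1L)
  ref_gen <- build_generator(generator_spec(base_filters = 4))
  expect_equal(fit$generator$blocks[[1]]$W, ref_gen$blocks[[1]]$W)
})

test_that("training is bit-reproducible under a fixed seed", {
  patches <- make_tiny_patches(2L)
  f1 <- tiny_fit(patches, epochs = 2L, seed = 7L)
  f2 <- tiny_fit(patches, epochs = 2L, seed = 7L)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
  f3 <- tiny_fit(patches, epochs = 2L, seed = 8L)
  expect_false(identical(f1$history$GL, f3$history$GL))
})

test_that("history has epochs x steps_per_epoch rows with finite losses", {
  patches <- make_tiny_patches(2L)  # 2 patches, batch 2 -> 1 step/epoch
  fit <- tiny_fit(patches, epochs = 3L)
  expect_equal(nrow(fit$history), 3)
  expect_true(all(is.finite(fit$history$GL)))
  expect_true(all(fit$history$DL >= 0 & fit$history$DL <= 2))
  expect_equal(fit$history$GL,
               fit$history$adv_term + 5 * fit$history$dice_term,
               tolerance = 1e-12)
  expect_error(tiny_fit(list(), epochs = 1L), "non-empty")
})

test_that("each update touches only its own network", {
  # freezing is structural (separate optimisers); observable consequence:
  # discriminator weights after a fit differ from init, and so do the
  # generator's, but a 0-epoch fit changes neither
  patches <- make_tiny_patches(1L)
  fit0 <- tiny_fit(patches, epochs = 0L)
  fit1 <- tiny_fit(patches, epochs = 1L)
  expect_false(identical(fit1$generator$blocks[[1]]$W,
                         fit0$generator$blocks[[1]]$W))
  expect_false(identical(fit1$discriminator$blocks[[1]]$W,
                         fit0$discriminator$blocks[[1]]$W))
})

test_that("prediction tiles, averages overlaps and returns the input grid", {
  cfg <- phantom_config(grid_size = 48L, tumour_radius_range = c(6, 10),
                        n_cases = 1L, seed = 17L)
  case <- normalize_intensity(generate_phantom(cfg, 1))
  gen <- build_generator(generator_spec(base_filters = 2), seed = 5)
  labels <- predict_case(gen, case, patch_size = 32, stride = 16)
  expect_identical(dim(labels), dim(case$labels))
  expect_true(all(labels %in% 0:3))

  # overlap averaging: with corners 0/16 per axis, the region x in 17:32,
  # y,z in 1:16 is covered by exactly the patches at x0 = 0 and x0 = 16;
  # the stitched probabilities there must be their mean, and singly
  # covered corners must equal the lone patch's output
  stitched <- predict_case(gen, case, patch_size = 32, stride = 16,
                           return_prob = TRUE)
  p000 <- net_apply(gen, case$image[1:32, 1:32, 1:32, , drop = FALSE])
  p100 <- net_apply(gen, case$image[17:48, 1:32, 1:32, , drop = FALSE])
  expect_equal(stitched$prob[1:16, 1:16, 1:16, ],
               p000[1:16, 1:16, 1:16, ], tolerance = 1e-12)
  expect_equal(stitched$prob[17:32, 1:16, 1:16, ],
               (p000[17:32, 1:16, 1:16, ] + p100[1:16, 1:16, 1:16, ]) / 2,
               tolerance = 1e-12)
  sums <- rowSums(matrix(stitched$prob, ncol = 4))
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_error(predict_case(gen, case, patch_size = 64), "smaller")
})

test_that("checkpoints round-trip the whole fitted model", {
  patches <- make_tiny_patches(1L)
  fit <- tiny_fit(patches, epochs = 1L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_identical(coef(back), coef(fit))
  expect_identical(back$history, fit$history)
  expect_identical(back$train_config, fit$train_config)
})

test_that("model methods print, summarise and plot without error", {
  patches <- make_tiny_patches(1L)
  fit <- tiny_fit(patches, epochs = 2L)
  expect_output(print(fit), "Adversarial 3D segmentation")
  s <- summary(fit)
  expect_s3_class(s, "summary.tumorgan")
  expect_equal(nrow(s$per_epoch), 2)
  expect_output(print(s), "per-epoch mean losses")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off(), add = TRUE)
  expect_silent(plot(fit))
})
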