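# Composite loss identities, hand examples and invariants.

test_that("l1_to_constant matches hand-computed means", {
  expect_equal(l1_to_constant(array(1, c(2, 2, 2, 1)), 1), 0)
  expect_equal(l1_to_constant(array(0, c(2, 2, 2, 1)), 1), 1)
  expect_equal(l1_to_constant(c(0.2, 0.6), 1), (0.8 + 0.4) / 2)
  expect_error(l1_to_constant(c(0.5), 0.3))
})

test_that("generalized dice loss is 0 for perfect and ~1 for disjoint predictions", {
  set.seed(21)
  labels <- array(sample(0:3, 6^3, replace = TRUE), c(6, 6, 6))
  yt <- one_hot_labels(labels)
  expect_equal(generalized_dice_loss(yt, yt), 0, tolerance = 1e-9)
  # every voxel predicted as a wrong class with certainty
  wrong <- one_hot_labels((labels + 1L) %% 4L)
  expect_equal(generalized_dice_loss(yt, wrong), 1, tolerance = 1e-3)
  expect_error(generalized_dice_loss(yt, wrong[1:5, , , , drop = FALSE]),
               "mismatch")
})

test_that("generalized dice loss matches a scalar transcription of its formula", {
  # 2-voxel toy under uniform weights: truth classes (0, 1), prediction
  # puts all mass on class 0 at both voxels
  yt <- array(0, c(2, 1, 1, 4)); yt[1, 1, 1, 1] <- 1; yt[2, 1, 1, 2] <- 1
  yp <- array(0, c(2, 1, 1, 4)); yp[, 1, 1, 1] <- 1
  cfg <- loss_config(dice_class_weighting = "uniform")
  got <- generalized_dice_loss(yt, yp, cfg)
  want <- oracle_gdl(matrix(yt, ncol = 4), matrix(yp, ncol = 4),
                     weights = rep(1, 4))
  expect_equal(got, want, tolerance = 1e-9)
  expect_equal(want, 1 - 2 * 1 / (2 + 2), tolerance = 1e-6)

  # random soft predictions, both weightings, against the same oracle
  set.seed(22)
  for (wgt in c("uniform", "inverse-square-volume")) {
    cfg <- loss_config(dice_class_weighting = wgt)
    labels <- array(sample(0:3, 4^3, replace = TRUE), c(4, 4, 4))
    yt <- one_hot_labels(labels)
    raw <- matrix(rexp(4^3 * 4), ncol = 4)
    yp <- array(raw / rowSums(raw), c(4, 4, 4, 4))
    w <- if (wgt == "uniform") rep(1, 4) else
      1 / (colSums(matrix(yt, ncol = 4)) + cfg$epsilon)^2
    expect_equal(generalized_dice_loss(yt, yp, cfg),
                 oracle_gdl(matrix(yt, ncol = 4), matrix(yp, ncol = 4), w),
                 tolerance = 1e-9)
  }
})

test_that("GDL is invariant under a common voxel permutation", {
  set.seed(23)
  labels <- array(sample(0:3, 4^3, replace = TRUE), c(4, 4, 4))
  yt <- one_hot_labels(labels)
  raw <- matrix(rexp(4^3 * 4), ncol = 4)
  yp <- array(raw / rowSums(raw), c(4, 4, 4, 4))
  perm <- sample(4^3)
  ytp <- array(matrix(yt, ncol = 4)[perm, ], dim(yt))
  ypp <- array(matrix(yp, ncol = 4)[perm, ], dim(yp))
  expect_equal(generalized_dice_loss(yt, yp),
               generalized_dice_loss(ytp, ypp), tolerance = 1e-12)
})

test_that("inverse-square-volume weights grow as a class shrinks", {
  eng <- asNamespace("tumorgan")
  cfg <- loss_config()
  vols <- c(1000, 100, 10, 1)
  w <- eng$gdl_weights(vols, cfg)
  expect_true(all(diff(w) > 0))
})

test_that("GDL gradient matches finite differences", {
  eng <- asNamespace("tumorgan")
  set.seed(24)
  labels <- array(sample(0:3, 4^3, replace = TRUE), c(4, 4, 4))
  yt <- one_hot_labels(labels)
  raw <- matrix(rexp(4^3 * 4), ncol = 4)
  yp <- array(raw / rowSums(raw), c(4, 4, 4, 4))
  cfg <- loss_config()
  g <- eng$generalized_dice_loss_grad(yt, yp, cfg)
  eps <- 1e-7
  for (i in sample(length(yp), 10)) {
    yp1 <- yp; yp1[i] <- yp1[i] + eps
    yp2 <- yp; yp2[i] <- yp2[i] - eps
    num <- (generalized_dice_loss(yt, yp1, cfg) -
              generalized_dice_loss(yt, yp2, cfg)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("generator loss composes its terms linearly in alpha", {
  set.seed(25)
  labels <- array(sample(0:3, 4^3, replace = TRUE), c(4, 4, 4))
  yt <- one_hot_labels(labels)
  raw <- matrix(rexp(4^3 * 4), ncol = 4)
  yp <- array(raw / rowSums(raw), c(4, 4, 4, 4))
  d <- array(runif(8), c(2, 2, 2, 1))

  gl0 <- generator_loss(d, yt, yp, loss_config(alpha = 0))
  expect_equal(gl0$GL, gl0$adv_term)
  gl5 <- generator_loss(d, yt, yp, loss_config(alpha = 5))
  expect_equal(gl5$GL, gl5$adv_term + 5 * gl5$dice_term)

  # perfect prediction, discriminator fully convinced -> zero loss
  glp <- generator_loss(array(1, c(2, 2, 2, 1)), yt, yt, loss_config())
  expect_equal(glp$GL, 0, tolerance = 1e-9)

  # components (0.6, 0.3) with alpha 5 -> 0.6 + 1.5
  expect_equal(0.6 + 5 * 0.3, 2.1)
  expect_equal(generator_loss(array(0.4, c(1, 1, 1, 1)), yt, yt,
                              loss_config(alpha = 5))$GL,
               0.6 + 5 * 0, tolerance = 1e-9)
})

test_that("discriminator loss spans 0 (perfect) to 2 (maximally fooled)", {
  ones <- array(1, c(2, 2, 2, 1))
  zeros <- array(0, c(2, 2, 2, 1))
  half <- array(0.5, c(2, 2, 2, 1))
  expect_equal(discriminator_loss(ones, zeros)$DL, 0)
  expect_equal(discriminator_loss(zeros, ones)$DL, 2)
  expect_equal(discriminator_loss(half, half)$DL, 1)
  expect_error(discriminator_loss(ones, array(1, c(1, 1, 1, 1))), "shape")
})

test_that("loss_config validates its domain", {
  expect_error(loss_config(alpha = -1), "alpha")
  expect_error(loss_config(epsilon = 0), "epsilon")
})
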