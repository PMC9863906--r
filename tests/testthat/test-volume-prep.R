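# Preprocessing: I/O validation, normalisation, one-hot codec, patch
# tiling, augmentation.

test_that("read_case validates labels and grids", {
  dir <- withr::local_tempdir()
  cfg <- tiny_phantom_config(n_cases = 1L, seed = 4L)
  manifest <- generate_cohort(cfg, dir)
  paths <- manifest[1, c("t1", "t1gd", "t2", "flair", "seg")]

  # label value outside the class set
  bad <- as.array(RNifti::readNifti(paths[["seg"]]))
  bad[1, 1, 1] <- 4
  RNifti::writeNifti(RNifti::asNifti(bad), paths[["seg"]],
                     datatype = "int16")
  expect_error(read_case(paths), "outside \\{0, 1, 2, 3\\}")

  # grid mismatch between a modality and the label volume
  manifest2 <- generate_cohort(cfg, dir)  # restore seg
  small <- array(0, c(16, 16, 16))
  RNifti::writeNifti(RNifti::asNifti(small), paths[["t2"]])
  expect_error(read_case(paths), "grid mismatch")

  expect_error(read_case(list(t1 = "nope.nii.gz")), "named")
})

test_that("z-score normalisation hits mean 0 / sd 1 on brain voxels and is idempotent", {
  # hand example: brain values {2, 4} -> {-1, +1}
  img <- array(0, c(16, 16, 16, 4))
  img[1, 1, 1, ] <- 2; img[2, 1, 1, ] <- 4
  case <- multimodal_case("toy", img, array(0L, c(16, 16, 16)))
  norm <- normalize_intensity(case)
  expect_equal(norm$image[1, 1, 1, 1], -1)
  expect_equal(norm$image[2, 1, 1, 1], 1)

  cfg <- tiny_phantom_config(n_cases = 1L, seed = 12L)
  case <- normalize_intensity(generate_phantom(cfg, 1))
  for (m in 1:4) {
    ch <- case$image[, , , m]
    v <- ch[ch != 0]
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-6)
  }
  again <- normalize_intensity(case)
  expect_equal(again$image, case$image, tolerance = 1e-6)
})

test_that("constant channels normalise to all zeros; minmax maps to [0,1]", {
  img <- array(0, c(16, 16, 16, 4))
  img[1:4, 1, 1, 1] <- 7                      # constant nonzero channel
  img[1:4, 1, 1, 2] <- c(1, 2, 3, 4)
  case <- multimodal_case("toy", img, array(0L, c(16, 16, 16)))
  z <- normalize_intensity(case)
  expect_true(all(z$image[, , , 1] == 0))
  mm <- normalize_intensity(case, method = "minmax")
  expect_true(all(mm$image[, , , 1] == 0))
  expect_equal(sort(unique(as.vector(mm$image[, , , 2]))),
               c(0, 1 / 3, 2 / 3, 1))
})

test_that("one-hot and argmax round trip exactly", {
  set.seed(41)
  labels <- array(sample(0:3, 8^3, replace = TRUE), c(8, 8, 8))
  oh <- one_hot_labels(labels)
  expect_true(all(apply(matrix(oh, ncol = 4), 1, sum) == 1))
  expect_identical(onehot_to_labels(oh), labels)
})

test_that("patch tiling covers the volume with flush final corners", {
  cfg <- phantom_config(grid_size = 64L, tumour_radius_range = c(8, 14),
                        n_cases = 1L, seed = 13L)
  case <- generate_phantom(cfg, 1)
  # side 64, P 32, S 32 -> 2 corners per axis -> 8 patches
  patches <- extract_patches(case, 32, 32)
  expect_length(patches, 8)
  # overlapping stride still covers every voxel
  patches <- extract_patches(case, 32, 24)
  cover <- array(0L, dim(case$labels))
  for (p in patches) {
    idx <- lapply(p$origin, function(o) o + 1:32)
    cover[idx[[1]], idx[[2]], idx[[3]]] <-
      cover[idx[[1]], idx[[2]], idx[[3]]] + 1L
    # one-hot content matches the source labels at that window
    expect_identical(onehot_to_labels(p$labels_onehot),
                     case$labels[idx[[1]], idx[[2]], idx[[3]]])
  }
  expect_true(all(cover >= 1L))

  # volume of exactly the patch size -> one patch, the whole volume
  small <- tiny_phantom_config(n_cases = 1L, seed = 14L)
  case32 <- generate_phantom(small, 1)
  one <- extract_patches(case32, 32)
  expect_length(one, 1)
  expect_equal(one[[1]]$image, case32$image)
  expect_error(extract_patches(case32, 48), "pad")
})

test_that("pad_case zero-pads up to the next multiple", {
  img <- array(1, c(20, 20, 20, 4))
  case <- multimodal_case("p", img, array(0L, c(20, 20, 20)))
  padded <- pad_case(case, 16)
  expect_identical(dim(padded$labels), c(32L, 32L, 32L))
  expect_true(all(padded$image[21:32, , , ] == 0))
  expect_equal(padded$image[1:20, 1:20, 1:20, ], img)
})

test_that("augmentation preserves image/label correspondence and class counts", {
  cfg <- tiny_phantom_config(n_cases = 1L, seed = 15L)
  case <- generate_phantom(cfg, 1)
  patch <- extract_patches(case, 32)[[1]]

  # identity draw leaves the patch unchanged
  id <- augment_patch(patch, flips = c(FALSE, FALSE, FALSE), rot_k = 0L)
  expect_identical(id$image, patch$image)
  expect_identical(id$labels_onehot, patch$labels_onehot)

  # a flip is an involution
  once <- augment_patch(patch, flips = c(TRUE, FALSE, FALSE), rot_k = 0L)
  twice <- augment_patch(once, flips = c(TRUE, FALSE, FALSE), rot_k = 0L)
  expect_identical(twice$image, patch$image)

  # four quarter-turns restore the patch
  r <- patch
  for (i in 1:4) r <- augment_patch(r, flips = c(FALSE, FALSE, FALSE),
                                    rot_k = 1L)
  expect_identical(r$labels_onehot, patch$labels_onehot)

  set.seed(42)
  counts0 <- colSums(matrix(patch$labels_onehot, ncol = 4))
  eng <- asNamespace("tumorgan")
  for (i in 1:5) {
    flips <- runif(3) < 0.5
    rot_k <- sample(0:3, 1)
    aug <- augment_patch(patch, flips = flips, rot_k = rot_k)
    expect_identical(colSums(matrix(aug$labels_onehot, ncol = 4)), counts0)
    # image and labels undergo the same voxel permutation
    expect_identical(aug$image,
                     eng$apply_augmentation(patch$image, flips, rot_k))
    expect_identical(onehot_to_labels(aug$labels_onehot),
                     onehot_to_labels(eng$apply_augmentation(
                       patch$labels_onehot, flips, rot_k)))
  }
})

test_that("patches enforce the cube and divisibility contracts", {
  expect_error(segmentation_patch(array(0, c(8, 8, 8, 4)),
                                  array(0, c(8, 8, 8, 4))), "divisible")
  expect_error(segmentation_patch(array(0, c(16, 16, 32, 4)),
                                  array(0, c(16, 16, 32, 4))), "cubic")
})
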