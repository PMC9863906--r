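# NIfTI reading/writing, intensity normalisation, patch extraction and
# label-preserving augmentation.  All coordinates are 0-based voxel
# indices, axis order (x, y, z), channels last.

#' Write a case to NIfTI files
#'
#' One file per modality (`<case_id>_<modality>.nii.gz`) plus the label
#' volume (`<case_id>_seg.nii.gz`).
#'
#' @param case a [multimodal_case()].
#' @param out_dir destination directory (must exist).
#' @return named character vector of the five paths (t1, t1gd, t2, flair,
#'   seg).
#' @export
write_case <- function(case, out_dir) {
  stopifnot(inherits(case, "multimodal_case"))
  if (!dir.exists(out_dir)) stop("output directory does not exist: ", out_dir)
  paths <- c()
  for (m in seq_along(MODALITIES)) {
    p <- file.path(out_dir, sprintf("%s_%s.nii.gz", case$case_id,
                                    MODALITIES[m]))
    img <- RNifti::asNifti(case$image[, , , m])
    RNifti::pixdim(img) <- case$spacing
    RNifti::writeNifti(img, p)
    paths[MODALITIES[m]] <- p
  }
  p <- file.path(out_dir, sprintf("%s_seg.nii.gz", case$case_id))
  seg <- RNifti::asNifti(case$labels)
  RNifti::pixdim(seg) <- case$spacing
  RNifti::writeNifti(seg, p, datatype = "int16")
  paths["seg"] <- p
  paths
}

#' Read a case from NIfTI files
#'
#' @param paths named character vector or list with entries `t1`, `t1gd`,
#'   `t2`, `flair` and `seg`.  All five grids must match; labels must lie
#'   in `{0, 1, 2, 3}`.
#' @param case_id identifier for the returned case; by default derived
#'   from the seg file name.
#' @return a [multimodal_case()] with channels in the fixed order T1,
#'   T1gd, T2, FLAIR.
#' @export
read_case <- function(paths, case_id = NULL) {
  paths <- unlist(paths)
  need <- c(MODALITIES, "seg")
  if (!all(need %in% names(paths)))
    stop("paths must be named with: ", paste(need, collapse = ", "))
  missing <- paths[need][!file.exists(paths[need])]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  seg_img <- RNifti::readNifti(paths[["seg"]])
  seg <- as.array(seg_img)
  dims <- dim(seg)
  image <- array(0, c(dims, 4L))
  for (m in seq_along(MODALITIES)) {
    vol <- as.array(RNifti::readNifti(paths[[MODALITIES[m]]]))
    if (!identical(dim(vol), dims))
      stop(sprintf("grid mismatch: %s is %s but seg is %s",
                   MODALITIES[m], paste(dim(vol), collapse = "x"),
                   paste(dims, collapse = "x")))
    image[, , , m] <- vol
  }
  labels <- round(seg)
  if (!all(labels %in% 0:3))
    stop("label file contains values outside {0, 1, 2, 3}")
  if (is.null(case_id))
    case_id <- sub("_seg\\.nii(\\.gz)?$", "", basename(paths[["seg"]]))
  spacing <- RNifti::pixdim(seg_img)[seq_along(dims)]
  multimodal_case(case_id, image, labels, spacing)
}

#' Intensity-normalise a case
#'
#' Each modality channel is normalised independently over its nonzero
#' (brain) voxels; zero background voxels stay zero.  `"zscore"` (the
#' default) centres to mean 0 and scales to population standard deviation
#' 1; `"minmax"` rescales the brain intensities to `[0, 1]`.  A constant
#' channel maps to all zeros under either method.
#'
#' @param case a [multimodal_case()].
#' @param method `"zscore"` or `"minmax"`.
#' @return the case with normalised image channels.
#' @export
normalize_intensity <- function(case, method = c("zscore", "minmax")) {
  stopifnot(inherits(case, "multimodal_case"))
  method <- match.arg(method)
  img <- case$image
  for (m in seq_len(dim(img)[4])) {
    ch <- img[, , , m]
    mask <- ch != 0
    v <- ch[mask]
    if (length(v) == 0) next
    if (method == "zscore") {
      mu <- mean(v)
      sdv <- sqrt(mean((v - mu)^2))
      ch[mask] <- if (sdv > 0) (v - mu) / sdv else 0
    } else {
      rng <- range(v)
      ch[mask] <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else 0
    }
    img[, , , m] <- ch
  }
  case$image <- img
  case
}

#' One-hot encode an integer label volume
#'
#' @param labels integer array with values in `0:(n_classes - 1)`.
#' @param n_classes number of classes (channels of the result).
#' @return array of dim `c(dim(labels), n_classes)` with exactly one 1 per
#'   voxel.
#' @export
one_hot_labels <- function(labels, n_classes = 4L) {
  lv <- as.integer(labels)
  if (any(lv < 0L | lv >= n_classes))
    stop("labels outside 0:(n_classes-1)")
  n <- length(lv)
  oh <- matrix(0, n, n_classes)
  oh[cbind(seq_len(n), lv + 1L)] <- 1
  array(oh, c(dim(labels), n_classes))
}

#' Collapse a one-hot (or soft) class field to integer labels
#'
#' @param onehot array of dim `(X, Y, Z, C)`.
#' @return integer array of labels `0:(C-1)` (argmax over the class axis;
#'   ties resolve to the lowest class index).
#' @export
onehot_to_labels <- function(onehot) {
  C <- dim(onehot)[4]
  m <- matrix(onehot, ncol = C)
  array(max.col(m, ties.method = "first") - 1L, dim(onehot)[1:3])
}

#' A training patch
#'
#' @param image `(P, P, P, 4)` image cube.
#' @param labels_onehot `(P, P, P, 4)` one-hot label cube.
#' @param origin 0-based corner of the patch in its source volume.
#' @return an object of class `"segmentation_patch"`.
#' @export
segmentation_patch <- function(image, labels_onehot, origin = c(0L, 0L, 0L)) {
  if (!identical(dim(image), dim(labels_onehot)))
    stop("image and one-hot label cubes must share dimensions")
  P <- dim(image)[1]
  if (!all(dim(image)[1:3] == P))
    stop("patches must be cubic")
  if (P %% 16L != 0L)
    stop("patch side must be divisible by 16 (four stride-2 halvings)")
  structure(list(image = image, labels_onehot = labels_onehot,
                 origin = as.integer(origin)),
            class = "segmentation_patch")
}

# tiling corner positions 0, S, 2S, ... with a final patch flush to the end
patch_starts <- function(n, P, S) {
  s <- seq(0L, n - P, by = S)
  if (s[length(s)] != n - P) s <- c(s, n - P)
  as.integer(s)
}

#' Extract covering patches from a case
#'
#' Tiles the volume with corners at `0, stride, 2*stride, ...` plus a final
#' corner flush with each axis end, so every voxel is covered by at least
#' one patch.
#'
#' @param case a [multimodal_case()] (normalise first for training).
#' @param patch_size cube side `P`, divisible by 16.
#' @param stride corner step; defaults to `patch_size` (non-overlapping
#'   tiling).
#' @return list of [segmentation_patch()] in lexicographic corner order.
#' @export
extract_patches <- function(case, patch_size, stride = patch_size) {
  stopifnot(inherits(case, "multimodal_case"))
  P <- as.integer(patch_size)
  S <- as.integer(stride)
  dims <- dim(case$labels)
  if (any(dims < P))
    stop(sprintf(
      "volume %s is smaller than the patch size %d on some axis; pad the volume to at least %d (see pad_case())",
      paste(dims, collapse = "x"), P, P))
  if (S < 1L) stop("stride must be >= 1")
  onehot <- one_hot_labels(case$labels)
  starts <- lapply(dims, patch_starts, P = P, S = S)
  out <- list()
  for (z0 in starts[[3]]) for (y0 in starts[[2]]) for (x0 in starts[[1]]) {
    ix <- x0 + seq_len(P)
    iy <- y0 + seq_len(P)
    iz <- z0 + seq_len(P)
    out[[length(out) + 1L]] <- segmentation_patch(
      image = case$image[ix, iy, iz, , drop = FALSE],
      labels_onehot = onehot[ix, iy, iz, , drop = FALSE],
      origin = c(x0, y0, z0))
  }
  out
}

#' Zero-pad a case to a side multiple
#'
#' Pads image and labels with zeros (background) at the high end of each
#' axis up to the next multiple of `multiple`.
#'
#' @param case a [multimodal_case()].
#' @param multiple target divisor of every axis (default 16).
#' @return the padded case.
#' @export
pad_case <- function(case, multiple = 16L) {
  dims <- dim(case$labels)
  target <- as.integer(ceiling(dims / multiple) * multiple)
  if (all(target == dims)) return(case)
  img <- array(0, c(target, 4L))
  img[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), ] <- case$image
  lab <- array(0L, target)
  lab[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- case$labels
  multimodal_case(case$case_id, img, lab, case$spacing)
}

# apply flips (logical length 3) and k axial 90-degree rotations to a
# channels-last 4-d array
apply_augmentation <- function(arr, flips, rot_k) {
  dm <- dim(arr)
  idx <- lapply(dm[1:3], seq_len)
  for (a in 1:3) if (flips[a]) idx[[a]] <- rev(idx[[a]])
  arr <- arr[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  rot_k <- rot_k %% 4L
  for (r in seq_len(rot_k)) {
    arr <- aperm(arr, c(2L, 1L, 3L, 4L))          # transpose x-y
    arr <- arr[rev(seq_len(dim(arr)[1])), , , , drop = FALSE]  # then flip x
  }
  arr
}

#' Randomly flip/rotate a patch
#'
#' Applies an axis flip with probability 0.5 per axis and a uniformly drawn
#' number of 90-degree rotations in the axial (x-y) plane, identically to
#' the image and one-hot label channels, so voxel-wise correspondence and
#' per-class voxel counts are preserved.  Draws come from R's RNG; seed the
#' session for reproducibility.  Pass explicit `flips`/`rot_k` for a
#' deterministic transform (all-`FALSE`/0 is the identity).
#'
#' @param patch a [segmentation_patch()].
#' @param flips logical length-3 vector, or `NULL` to draw randomly.
#' @param rot_k integer 0-3 axial rotations, or `NULL` to draw randomly.
#' @return the transformed patch (origin is kept from the input).
#' @export
augment_patch <- function(patch, flips = NULL, rot_k = NULL) {
  stopifnot(inherits(patch, "segmentation_patch"))
  if (is.null(flips)) flips <- stats::runif(3) < 0.5
  if (is.null(rot_k)) rot_k <- sample(0:3, 1)
  stopifnot(length(flips) == 3L)
  segmentation_patch(
    image = apply_augmentation(patch$image, flips, rot_k),
    labels_onehot = apply_augmentation(patch$labels_onehot, flips, rot_k),
    origin = patch$origin)
}
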