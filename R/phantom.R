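# Seeded simulator of BraTS-like multimodal phantoms.
#
# A phantom is a brain-shaped ellipsoid of healthy tissue containing a
# nested three-shell tumour (enhancing core inside non-enhancing core
# inside edema), imaged in four modality channels whose per-class mean
# intensities mimic the qualitative contrast pattern of T1 / T1gd / T2 /
# FLAIR (FLAIR-bright edema, gadolinium-bright enhancing core, ...), with
# additive Gaussian noise inside the brain.  Air outside the brain is
# exactly zero, the convention the nonzero-mask intensity normalisation
# relies on.  Class frequencies are strongly imbalanced by construction:
# background dwarfs the tumour shells, which is the condition the weighted
# dice loss is designed for.

MODALITIES <- c("t1", "t1gd", "t2", "flair")

#' Default per-(modality, class) mean intensities
#'
#' Rows are modalities (T1, T1gd, T2, FLAIR), columns the classes
#' background/healthy tissue (0), edema (1), non-enhancing core (2) and
#' enhancing core (3), in arbitrary units on a 0-100 scale.  The pattern
#' keeps the four classes separable but overlapping once noise is added.
#'
#' @return a 4x4 numeric matrix with dimnames.
#' @export
default_intensity_table <- function() {
  m <- rbind(
    t1    = c(70, 55, 45, 60),
    t1gd  = c(70, 55, 40, 95),
    t2    = c(50, 80, 70, 65),
    flair = c(45, 90, 65, 70)
  )
  colnames(m) <- c("background", "edema", "net", "et")
  m
}

#' Phantom cohort configuration
#'
#' @param grid_size voxels per axis (cubic volume).
#' @param brain_radius_frac fraction of the half-grid occupied by the brain
#'   ellipsoid's largest semi-axis.
#' @param tumour_radius_range min/max edema radius in voxels; the core
#'   shells scale with it.  `c(0, 0)` produces tumour-free phantoms.
#' @param class_intensity_table 4 modalities x 4 classes matrix of mean
#'   intensities, as in [default_intensity_table()].
#' @param noise_sigma standard deviation of the additive Gaussian noise
#'   (same arbitrary units as the table).
#' @param n_cases number of phantoms in the cohort.
#' @param seed integer; together with the case index it fully determines
#'   every phantom.
#' @param spacing voxel size in mm per axis.
#' @return an object of class `"phantom_config"`.
#' @export
phantom_config <- function(grid_size = 64L, brain_radius_frac = 0.85,
                           tumour_radius_range = c(6, 12),
                           class_intensity_table = default_intensity_table(),
                           noise_sigma = 5, n_cases = 10L, seed = 1L,
                           spacing = c(1, 1, 1)) {
  cfg <- list(grid_size = as.integer(grid_size),
              brain_radius_frac = brain_radius_frac,
              tumour_radius_range = as.numeric(tumour_radius_range),
              class_intensity_table = class_intensity_table,
              noise_sigma = noise_sigma,
              n_cases = as.integer(n_cases),
              seed = as.integer(seed),
              spacing = as.numeric(spacing))
  if (length(cfg$tumour_radius_range) != 2L ||
      diff(cfg$tumour_radius_range) < 0)
    stop("tumour_radius_range must be c(min, max) with min <= max")
  if (max(cfg$tumour_radius_range) >= cfg$grid_size / 2)
    stop(sprintf(
      "tumour_radius_range max (%g) must be below grid_size/2 (%g)",
      max(cfg$tumour_radius_range), cfg$grid_size / 2))
  # the edema shell (with up to 1.2x per-axis stretch) must fit inside the
  # smallest brain semi-axis, or no tumour centre can be placed
  brain_min <- cfg$brain_radius_frac * (cfg$grid_size / 2) * 0.85
  if (max(cfg$tumour_radius_range) * 1.2 >= brain_min)
    stop(sprintf(
      "tumour_radius_range incompatible with grid: max radius %g (x1.2 stretch) must stay below the smallest brain semi-axis %.1f",
      max(cfg$tumour_radius_range), brain_min))
  if (!is.matrix(cfg$class_intensity_table) ||
      !all(dim(cfg$class_intensity_table) == c(4L, 4L)))
    stop("class_intensity_table must be a 4 modality x 4 class matrix")
  if (cfg$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (cfg$n_cases < 0) stop("n_cases must be >= 0")
  if (cfg$brain_radius_frac <= 0 || cfg$brain_radius_frac > 1)
    stop("brain_radius_frac must be in (0, 1]")
  structure(cfg, class = "phantom_config")
}

#' A multimodal segmentation case
#'
#' Container for four co-registered modality volumes, an integer label
#' volume with classes 0 (background), 1 (edema), 2 (non-enhancing core)
#' and 3 (enhancing core), and the voxel spacing.
#'
#' @param case_id character identifier.
#' @param image array of dim `(X, Y, Z, 4)`, channel order T1, T1gd, T2,
#'   FLAIR.
#' @param labels integer array of dim `(X, Y, Z)` with values in 0:3.
#' @param spacing mm per voxel per axis.
#' @return an object of class `"multimodal_case"`.
#' @export
multimodal_case <- function(case_id, image, labels, spacing = c(1, 1, 1)) {
  if (length(dim(image)) != 4L || dim(image)[4] != 4L)
    stop("image must have dim (X, Y, Z, 4)")
  if (!identical(as.integer(dim(image)[1:3]), as.integer(dim(labels))))
    stop(sprintf("image grid %s does not match label grid %s",
                 paste(dim(image)[1:3], collapse = "x"),
                 paste(dim(labels), collapse = "x")))
  lv <- unique(as.integer(labels))
  if (!all(lv %in% 0:3))
    stop("label values outside {0, 1, 2, 3}: ",
         paste(setdiff(lv, 0:3), collapse = ", "))
  structure(list(case_id = as.character(case_id), image = image,
                 labels = array(as.integer(labels), dim(labels)),
                 spacing = as.numeric(spacing)),
            class = "multimodal_case")
}

#' @export
print.multimodal_case <- function(x, ...) {
  counts <- tabulate(as.integer(x$labels) + 1L, nbins = 4L)
  cat(sprintf("<multimodal_case> %s  grid %s  spacing %s mm\n", x$case_id,
              paste(dim(x$labels), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  cat(sprintf("  voxels: background %d | edema %d | NET %d | ET %d\n",
              counts[1], counts[2], counts[3], counts[4]))
  invisible(x)
}

# per-case RNG seed, kept within 32-bit integer range
case_seed <- function(seed, case_index) {
  as.integer((as.double(seed) * 2654435 + case_index * 97 + 13) %% 2147483647)
}

#' Generate one phantom case
#'
#' Fully determined by `(config$seed, case_index)`: calling it twice with
#' the same arguments yields bit-identical volumes, and it does not disturb
#' the caller's RNG stream.
#'
#' @param config a [phantom_config()].
#' @param case_index 1-based index, `<= config$n_cases`.
#' @return a [multimodal_case()].
#' @export
generate_phantom <- function(config, case_index) {
  stopifnot(inherits(config, "phantom_config"))
  if (case_index < 1L || case_index > config$n_cases)
    stop("case_index must be in 1..n_cases")
  with_preserved_seed(case_seed(config$seed, case_index), {
    N <- config$grid_size
    centre <- (N - 1) / 2
    # mildly anisotropic brain ellipsoid
    brain_ax <- config$brain_radius_frac * (N / 2) * c(1.0, 0.85, 0.92)
    ax <- seq_len(N) - 1
    gx <- array(ax, c(N, N, N))
    gy <- aperm(gx, c(2, 1, 3))
    gz <- aperm(gx, c(3, 2, 1))
    rho_brain <- sqrt(((gx - centre) / brain_ax[1])^2 +
                      ((gy - centre) / brain_ax[2])^2 +
                      ((gz - centre) / brain_ax[3])^2)
    brain <- rho_brain <= 1

    labels <- array(0L, c(N, N, N))
    r_max <- max(config$tumour_radius_range)
    if (r_max > 0) {
      r_ed <- stats::runif(1, config$tumour_radius_range[1],
                           config$tumour_radius_range[2])
      stretch <- stats::runif(3, 0.8, 1.2)
      tum_ax <- r_ed * stretch
      if (any(brain_ax <= tum_ax))
        stop("tumour_radius_range incompatible with grid/brain size")
      # rejection-sample a centre such that the edema ellipsoid sits fully
      # inside the brain (conservative per-axis margin)
      ok <- FALSE
      for (try in 1:1000) {
        cand <- centre + (stats::runif(3) * 2 - 1) * (brain_ax - tum_ax)
        if (sqrt(sum(((cand - centre) / (brain_ax - tum_ax))^2)) <= 1) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place tumour inside the brain")
      rho_t <- sqrt(((gx - cand[1]) / tum_ax[1])^2 +
                    ((gy - cand[2]) / tum_ax[2])^2 +
                    ((gz - cand[3]) / tum_ax[3])^2)
      labels[rho_t <= 1] <- 1L    # edema shell
      labels[rho_t <= 0.6] <- 2L  # non-enhancing core
      labels[rho_t <= 0.3] <- 3L  # enhancing core
    }

    image <- array(0, c(N, N, N, 4L))
    tab <- config$class_intensity_table
    nb <- sum(brain)
    for (m in 1:4) {
      ch <- array(0, c(N, N, N))
      ch[brain] <- tab[m, as.integer(labels[brain]) + 1L]
      if (config$noise_sigma > 0)
        ch[brain] <- ch[brain] + stats::rnorm(nb, sd = config$noise_sigma)
      image[, , , m] <- ch
    }
    multimodal_case(sprintf("phantom_%03d", case_index), image, labels,
                    config$spacing)
  })
}

#' Generate and write a phantom cohort
#'
#' Writes each case as five NIfTI-1 files (`<case_id>_<modality>.nii.gz`
#' for t1, t1gd, t2, flair plus `<case_id>_seg.nii.gz`) and a
#' `manifest.csv` with one row per case.
#'
#' @param config a [phantom_config()].
#' @param out_dir output directory, created if missing.
#' @return invisibly, the manifest data.frame (columns `case_id`, one path
#'   column per file, `seed`), in case order.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "phantom_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    case <- generate_phantom(config, i)
    paths <- write_case(case, out_dir)
    rows[[i]] <- data.frame(case_id = case$case_id, t(paths),
                            seed = config$seed, stringsAsFactors = FALSE)
  }
  manifest <- if (config$n_cases > 0) do.call(rbind, rows) else
    data.frame(case_id = character(), t1 = character(), t1gd = character(),
               t2 = character(), flair = character(), seg = character(),
               seed = integer(), stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest)
}
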