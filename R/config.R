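# Structured run configuration: one YAML file with nested sections for the
# phantom simulator, preprocessing, network specs, losses, training and
# evaluation.  Unknown keys are rejected with their full path; omitted keys
# fall back to defaults.

#' Default run configuration
#'
#' The defaults mirror the full-scale study conditions (128-cube patches,
#' base 64 filters, 100 epochs, batch size 4); desk-scale runs override
#' them via a YAML file or CLI flags.
#'
#' @return nested list of class `"run_config"`.
#' @export
default_run_config <- function() {
  structure(list(
    phantom = list(grid_size = 64L, brain_radius_frac = 0.85,
                   tumour_radius_range = c(6, 12), noise_sigma = 5,
                   n_cases = 10L, seed = 1L, spacing = c(1, 1, 1)),
    preprocess = list(normalization = "zscore", pad_multiple = 16L),
    networks = list(base_filters = 64L, n_down_blocks = 4L,
                    n_residual_blocks = 4L, n_up_blocks = 3L,
                    kernel_size = 4L, dropout = 0.2, lrelu_slope = 0.2),
    loss = list(alpha = 5, dice_class_weighting = "inverse-square-volume",
                epsilon = 1e-6),
    train = list(epochs = 100L, batch_size = 4L, patch_size = 128L,
                 stride = 128L, learning_rate = 2e-4, beta1 = 0.5,
                 beta2 = 0.999, seed = 1L, checkpoint_every = 0L),
    evaluate = list(ssim_window = 7L)
  ), class = "run_config")
}

#' Validate and complete a run configuration
#'
#' Checks every key against the schema of [default_run_config()]; unknown
#' keys raise an error naming their full path, and missing keys are filled
#' from the defaults.
#'
#' @param cfg nested list (e.g. from YAML).
#' @return completed `"run_config"`.
#' @export
validate_run_config <- function(cfg) {
  ref <- unclass(default_run_config())
  if (!is.list(cfg)) stop("config must be a named list")
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad))
    stop("unknown config key: ", paste(bad, collapse = ", "))
  out <- ref
  for (sec in names(cfg)) {
    if (!is.list(cfg[[sec]]))
      stop("config section '", sec, "' must be a mapping")
    badk <- setdiff(names(cfg[[sec]]), names(ref[[sec]]))
    if (length(badk))
      stop("unknown config key: ",
           paste(paste0(sec, ".", badk), collapse = ", "))
    for (k in names(cfg[[sec]])) out[[sec]][[k]] <- cfg[[sec]][[k]]
  }
  # type/value checks delegated to the constructors they feed
  structure(out, class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @return `read_run_config` returns a validated `"run_config"`;
#'   `write_run_config` invisibly returns `path`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param cfg a `"run_config"` (or compatible nested list).
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(validate_run_config(cfg)), path)
  invisible(path)
}

# constructors from a validated run config ----------------------------------

phantom_config_from <- function(cfg) {
  p <- cfg$phantom
  phantom_config(grid_size = p$grid_size,
                 brain_radius_frac = p$brain_radius_frac,
                 tumour_radius_range = p$tumour_radius_range,
                 noise_sigma = p$noise_sigma, n_cases = p$n_cases,
                 seed = p$seed, spacing = p$spacing)
}

gen_spec_from <- function(cfg) {
  n <- cfg$networks
  generator_spec(base_filters = n$base_filters,
                 n_down_blocks = n$n_down_blocks,
                 n_residual_blocks = n$n_residual_blocks,
                 n_up_blocks = n$n_up_blocks, kernel_size = n$kernel_size,
                 dropout = n$dropout, lrelu_slope = n$lrelu_slope)
}

disc_spec_from <- function(cfg) {
  n <- cfg$networks
  discriminator_spec(base_filters = n$base_filters,
                     n_down_blocks = n$n_down_blocks,
                     kernel_size = n$kernel_size,
                     lrelu_slope = n$lrelu_slope)
}

loss_config_from <- function(cfg) {
  l <- cfg$loss
  loss_config(alpha = l$alpha, dice_class_weighting = l$dice_class_weighting,
              epsilon = l$epsilon)
}

train_config_from <- function(cfg, checkpoint_dir = NULL) {
  t <- cfg$train
  train_config(epochs = t$epochs, batch_size = t$batch_size,
               patch_size = t$patch_size, learning_rate = t$learning_rate,
               beta1 = t$beta1, beta2 = t$beta2, seed = t$seed,
               checkpoint_every = t$checkpoint_every,
               checkpoint_dir = checkpoint_dir)
}
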