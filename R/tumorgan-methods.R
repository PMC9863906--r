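# S3 methods for the fitted model object.

#' @export
print.tumorgan <- function(x, ...) {
  gs <- x$generator$spec
  cat("Adversarial 3D segmentation model (generator + patch discriminator)\n")
  cat(sprintf("  generator: base %d filters, %d down / %d residual / %d up blocks, %d classes\n",
              gs$base_filters, gs$n_down_blocks, gs$n_residual_blocks,
              gs$n_up_blocks, gs$out_channels))
  cat(sprintf("  parameters: generator %s, discriminator %s\n",
              format(count_parameters(x$generator)[["total"]], big.mark = ","),
              format(count_parameters(x$discriminator)[["total"]], big.mark = ",")))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epoch(s), %d step(s); final GL %.4f, DL %.4f, voxel accuracy %.3f\n",
                max(x$history$epoch), nrow(x$history), last$GL, last$DL,
                last$accuracy))
  } else {
    cat("  untrained (0 epochs)\n")
  }
  invisible(x)
}

#' Summarise a fitted model
#'
#' @param object a `"tumorgan"` fit.
#' @param ... unused.
#' @return an object of class `"summary.tumorgan"`: per-epoch mean losses
#'   and parameter counts.
#' @export
summary.tumorgan <- function(object, ...) {
  h <- object$history
  per_epoch <- if (nrow(h)) {
    do.call(rbind, lapply(split(h, h$epoch), function(d) data.frame(
      epoch = d$epoch[1], GL = mean(d$GL), adv_term = mean(d$adv_term),
      dice_term = mean(d$dice_term), DL = mean(d$DL),
      accuracy = mean(d$accuracy))))
  } else h
  structure(list(per_epoch = per_epoch,
                 params_generator = count_parameters(object$generator),
                 params_discriminator = count_parameters(object$discriminator),
                 alpha = object$loss_config$alpha,
                 config = object$train_config),
            class = "summary.tumorgan")
}

#' @export
print.summary.tumorgan <- function(x, ...) {
  cat(sprintf("Adversarial segmentation fit: %d epoch(s), alpha = %g\n",
              nrow(x$per_epoch), x$alpha))
  cat(sprintf("  generator parameters:     %s\n",
              format(x$params_generator[["total"]], big.mark = ",")))
  cat(sprintf("  discriminator parameters: %s\n",
              format(x$params_discriminator[["total"]], big.mark = ",")))
  if (nrow(x$per_epoch)) {
    show <- x$per_epoch
    if (nrow(show) > 10)
      show <- show[unique(round(seq(1, nrow(show), length.out = 10))), ]
    cat("per-epoch mean losses:\n")
    print(show, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Extract model weights
#'
#' @param object a `"tumorgan"` fit.
#' @param ... unused.
#' @return named list with `generator` and `discriminator`, each a list of
#'   per-block parameter lists (`W`, `b`, and `gamma`/`beta` where the
#'   block is normalised).
#' @export
coef.tumorgan <- function(object, ...) {
  pull <- function(net) lapply(net$blocks, function(blk)
    lapply(stats::setNames(nm = block_param_names(blk)), function(p) blk[[p]]))
  list(generator = pull(object$generator),
       discriminator = pull(object$discriminator))
}

#' Predict segmentation labels for a case
#'
#' Sliding-window generator inference with overlap averaging; see
#' [predict_case()].
#'
#' @param object a `"tumorgan"` fit.
#' @param case a [multimodal_case()], intensity-normalised like the
#'   training data (set `normalize = TRUE` to apply the default z-score
#'   here).
#' @param patch_size,stride tiling geometry; default to the training
#'   patch size.
#' @param normalize apply [normalize_intensity()] before inference.
#' @param return_prob also return averaged class probabilities.
#' @param ... unused.
#' @return integer label volume (or list with `labels` and `prob`).
#' @export
predict.tumorgan <- function(object, case,
                             patch_size = object$train_config$patch_size,
                             stride = patch_size, normalize = FALSE,
                             return_prob = FALSE, ...) {
  if (normalize) case <- normalize_intensity(case)
  predict_case(object$generator, case, patch_size, stride,
               return_prob = return_prob)
}

#' Plot training loss traces
#'
#' Generator loss (total, adversarial and dice components) and
#' discriminator loss against the training step.
#'
#' @param x a `"tumorgan"` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tumorgan <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  graphics::matplot(h$step, cbind(h$GL, h$dice_term * x$loss_config$alpha,
                                  h$adv_term, h$DL),
                    type = "l", lty = 1, col = c("black", "firebrick",
                                                 "steelblue", "darkgreen"),
                    xlab = "step", ylab = "loss", ...)
  graphics::legend("topright",
                   legend = c("GL", "alpha * dice", "adversarial", "DL"),
                   col = c("black", "firebrick", "steelblue", "darkgreen"),
                   lty = 1, bty = "n")
  invisible(x)
}
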