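# Composite adversarial objectives.
#
# Generator loss      GL = L1(D(x, yhat), 1) + alpha * GDL(y, yhat)
# Discriminator loss  DL = L1(D(x, y), 1) + L1(D(x, yhat), 0)
#
# L1 terms are mean absolute deviations from a constant tensor, so the
# losses do not scale with the realness-patch size.  GDL is the generalized
# dice loss with inverse-square-volume class weights by default, which
# up-weights small tumour sub-regions against the overwhelming background
# class.

#' Loss configuration
#'
#' @param alpha non-negative weight on the dice term of the generator loss.
#' @param dice_class_weighting `"inverse-square-volume"` (weights
#'   `1 / (class volume + epsilon)^2`, the class-imbalance-countering
#'   default) or `"uniform"`.
#' @param epsilon smoothing constant protecting empty-class weights and the
#'   dice denominator.
#' @return an object of class `"loss_config"`.
#' @export
loss_config <- function(alpha = 5,
                        dice_class_weighting = c("inverse-square-volume",
                                                 "uniform"),
                        epsilon = 1e-6) {
  dice_class_weighting <- match.arg(dice_class_weighting)
  if (alpha < 0) stop("alpha must be >= 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(alpha = alpha,
                 dice_class_weighting = dice_class_weighting,
                 epsilon = epsilon),
            class = "loss_config")
}

#' Mean absolute deviation from a constant target
#'
#' The adversarial building block: the discriminator's realness patch is
#' compared against a same-shaped tensor of ones (real target) or zeros
#' (fake target), reduced by the mean.
#'
#' @param d_output numeric array of realness scores.
#' @param target_constant 0 or 1.
#' @return scalar loss.
#' @export
l1_to_constant <- function(d_output, target_constant) {
  stopifnot(target_constant %in% c(0, 1))
  mean(abs(d_output - target_constant))
}

# gradient of l1_to_constant w.r.t. d_output
l1_to_constant_grad <- function(d_output, target_constant) {
  sign(d_output - target_constant) / length(d_output)
}

#' Generalized dice loss
#'
#' `1 - (2 * sum_c w_c sum_v y_cv yhat_cv + eps) /
#' (sum_c w_c sum_v (y_cv + yhat_cv) + eps)` with
#' `w_c = 1 / (sum_v y_cv + eps)^2` under inverse-square-volume weighting.
#' Exactly zero for a perfect prediction; close to one for a prediction
#' with no overlap on any class.
#'
#' @param y_true_onehot one-hot label array, dim `(X, Y, Z, C)`.
#' @param y_pred_soft soft prediction of the same dim, rows summing to 1
#'   over the class axis.
#' @param config a [loss_config()].
#' @return scalar in `[0, 1]` (up to epsilon effects).
#' @export
generalized_dice_loss <- function(y_true_onehot, y_pred_soft,
                                  config = loss_config()) {
  if (!identical(dim(y_true_onehot), dim(y_pred_soft)))
    stop(sprintf("grid mismatch: truth %s vs prediction %s",
                 paste(dim(y_true_onehot), collapse = "x"),
                 paste(dim(y_pred_soft), collapse = "x")))
  C <- dim(y_true_onehot)[4]
  yt <- matrix(y_true_onehot, ncol = C)
  yp <- matrix(y_pred_soft, ncol = C)
  w <- gdl_weights(colSums(yt), config)
  num <- sum(w * colSums(yt * yp))
  den <- sum(w * (colSums(yt) + colSums(yp)))
  # epsilon on both sides keeps GDL(y, y) = 0 exactly and guards 0/0
  1 - (2 * num + config$epsilon) / (den + config$epsilon)
}

gdl_weights <- function(class_volumes, config) {
  if (config$dice_class_weighting == "uniform") rep(1, length(class_volumes))
  else 1 / (class_volumes + config$epsilon)^2
}

# gradient of the GDL w.r.t. y_pred_soft (weights treated as constants of
# y_true only, which they are)
generalized_dice_loss_grad <- function(y_true_onehot, y_pred_soft, config) {
  dm <- dim(y_true_onehot)
  C <- dm[4]
  yt <- matrix(y_true_onehot, ncol = C)
  yp <- matrix(y_pred_soft, ncol = C)
  w <- gdl_weights(colSums(yt), config)
  num2 <- 2 * sum(w * colSums(yt * yp)) + config$epsilon
  den <- sum(w * (colSums(yt) + colSums(yp))) + config$epsilon
  # d/dyp_cv [1 - num2/den] = -(2 w_c yt_cv den - num2 w_c) / den^2
  g <- -(2 * sweep(yt, 2L, w, "*") * den -
           num2 * rep(w, each = nrow(yt))) / den^2
  array(g, dm)
}

#' Generator loss
#'
#' Adversarial term (mean absolute deviation of the discriminator's score
#' on the generated segmentation from 1) plus `alpha` times the generalized
#' dice loss.
#'
#' @param d_on_fake discriminator realness patch for `(x, yhat)`.
#' @param y_true_onehot,y_pred_soft as in [generalized_dice_loss()].
#' @param config a [loss_config()].
#' @return list with `GL`, `adv_term` and `dice_term`.
#' @export
generator_loss <- function(d_on_fake, y_true_onehot, y_pred_soft,
                           config = loss_config()) {
  adv <- l1_to_constant(d_on_fake, 1)
  gdl <- generalized_dice_loss(y_true_onehot, y_pred_soft, config)
  list(GL = adv + config$alpha * gdl, adv_term = adv, dice_term = gdl)
}

#' Discriminator loss
#'
#' Mean absolute deviation of the real pair's scores from 1 plus that of
#' the fake pair's scores from 0; 0 for a perfect discriminator, 2 for a
#' maximally fooled one.
#'
#' @param d_on_real realness patch for `(x, y)`.
#' @param d_on_fake realness patch for `(x, yhat)`.
#' @return list with `DL`, `real_term` and `fake_term`.
#' @export
discriminator_loss <- function(d_on_real, d_on_fake) {
  if (!identical(dim(d_on_real), dim(d_on_fake)))
    stop("realness patches must share a shape")
  real <- l1_to_constant(d_on_real, 1)
  fake <- l1_to_constant(d_on_fake, 0)
  list(DL = real + fake, real_term = real, fake_term = fake)
}
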