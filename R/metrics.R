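# Per-case evaluation (DSC / PSNR / SSIM) and cohort aggregation.
#
# PSNR and SSIM are computed between predicted and ground-truth label maps
# linearly rescaled to [0, 1] (labels / 3, dynamic range 1), since they are
# signal-fidelity measures and need a common intensity scale.

#' Dice score coefficient
#'
#' `2|A intersect B| / (|A| + |B|)` between binary masks.  With
#' `region = "whole"` the masks are `label > 0` (whole tumour); with
#' `region = "per-class"` one score per tumour class (edema, non-enhancing
#' core, enhancing core) is returned.  If both masks are empty the score
#' is 1 by convention.
#'
#' @param pred_labels,true_labels integer label volumes with values in
#'   `{0, 1, 2, 3}`, same grid.
#' @param region `"whole"` or `"per-class"`.
#' @return scalar, or named vector `c(edema=, net=, et=)`.
#' @export
dice_coefficient <- function(pred_labels, true_labels,
                             region = c("whole", "per-class")) {
  region <- match.arg(region)
  if (!identical(dim(pred_labels), dim(true_labels)))
    stop(sprintf("grid mismatch: prediction %s vs truth %s",
                 paste(dim(pred_labels), collapse = "x"),
                 paste(dim(true_labels), collapse = "x")))
  binary_dice <- function(a, b) {
    sa <- sum(a)
    sb <- sum(b)
    if (sa + sb == 0) return(1)
    2 * sum(a & b) / (sa + sb)
  }
  if (region == "whole")
    return(binary_dice(pred_labels > 0, true_labels > 0))
  out <- vapply(1:3, function(cl)
    binary_dice(pred_labels == cl, true_labels == cl), numeric(1))
  names(out) <- c("edema", "net", "et")
  out
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_value^2 / MSE)` in decibels; `Inf` when the maps are
#' identical (zero MSE).
#'
#' @param pred_map,true_map numeric arrays on the same grid.
#' @param max_value dynamic range of the signal.
#' @return PSNR in dB.
#' @export
psnr <- function(pred_map, true_map, max_value = 1) {
  if (!identical(dim(pred_map), dim(true_map)))
    stop("grid mismatch between maps")
  mse <- mean((pred_map - true_map)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

# windowed box sums via cumulative sums along each axis; returns the
# "valid" region (windows fully inside the array)
box_sum <- function(a, w) {
  d <- dim(a)
  nd <- length(d)
  for (axis in seq_len(nd)) {
    perm <- c(axis, setdiff(seq_len(nd), axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    cs <- apply(m, 2L, cumsum)
    n_out <- dp[1] - w + 1L
    sums <- cs[seq(w, dp[1]), , drop = FALSE]
    if (n_out > 1L)
      sums[-1L, ] <- sums[-1L, , drop = FALSE] -
        cs[seq_len(n_out - 1L), , drop = FALSE]
    dim(sums) <- c(n_out, dp[-1L])
    a <- aperm(sums, order(perm))
    d <- dim(a)
  }
  a
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard luminance/contrast/structure form,
#' uniform cubic (or square) window, population local moments, and
#' stabilisation constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for
#' dynamic range `L`.  Works on 2-d slices and 3-d volumes.
#'
#' @param pred_map,true_map numeric arrays on the same grid.
#' @param window window side (default 7); must not exceed any grid side.
#' @param dynamic_range value range `L` of the signals.
#' @return scalar in `[-1, 1]`; 1 for identical maps.
#' @export
ssim <- function(pred_map, true_map, window = 7L, dynamic_range = 1) {
  if (!identical(dim(pred_map), dim(true_map)))
    stop("grid mismatch between maps")
  d <- dim(pred_map)
  if (any(window > d))
    stop(sprintf("window (%d) larger than grid (%s)", window,
                 paste(d, collapse = "x")))
  n <- as.numeric(window)^length(d)
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  mx <- box_sum(pred_map, window) / n
  my <- box_sum(true_map, window) / n
  vx <- box_sum(pred_map^2, window) / n - mx^2
  vy <- box_sum(true_map^2, window) / n - my^2
  cxy <- box_sum(pred_map * true_map, window) / n - mx * my
  map <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(map)
}

#' Evaluate one case
#'
#' Whole-tumour DSC plus PSNR and SSIM between the label maps rescaled to
#' `[0, 1]`.  Per-class dice scores are included alongside.
#'
#' @param pred_labels,true_labels integer label volumes in `{0, 1, 2, 3}`.
#' @param case_id identifier for the report row.
#' @param ssim_window SSIM window side.
#' @return one-row data.frame with columns `case_id`, `ssim`, `psnr`,
#'   `dsc`, `dsc_edema`, `dsc_net`, `dsc_et`.
#' @export
evaluate_case <- function(pred_labels, true_labels, case_id = "case",
                          ssim_window = 7L) {
  pc <- dice_coefficient(pred_labels, true_labels, region = "per-class")
  data.frame(
    case_id = case_id,
    ssim = ssim(pred_labels / 3, true_labels / 3, window = ssim_window),
    psnr = psnr(pred_labels / 3, true_labels / 3, max_value = 1),
    dsc = dice_coefficient(pred_labels, true_labels),
    dsc_edema = pc[["edema"]], dsc_net = pc[["net"]], dsc_et = pc[["et"]],
    stringsAsFactors = FALSE)
}

#' Aggregate per-case metrics into a cohort report
#'
#' @param rows data.frame with at least the columns `case_id`, `ssim`,
#'   `psnr`, `dsc` (one row per case).
#' @return an object of class `"cohort_report"`: the rows plus the
#'   arithmetic column means `mean_ssim`, `mean_psnr`, `mean_dsc`.
#' @export
aggregate_report <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("rows must be a non-empty data.frame of per-case metrics")
  need <- c("case_id", "ssim", "psnr", "dsc")
  if (!all(need %in% names(rows)))
    stop("rows must have columns: ", paste(need, collapse = ", "))
  structure(list(rows = rows,
                 mean_ssim = mean(rows$ssim),
                 mean_psnr = mean(rows$psnr),
                 mean_dsc = mean(rows$dsc)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d case(s)\n", nrow(x$rows)))
  print(x$rows[, intersect(c("case_id", "ssim", "psnr", "dsc"),
                           names(x$rows))], row.names = FALSE)
  cat(sprintf("mean: SSIM %.5f | PSNR %.3f dB | DSC %.3f\n",
              x$mean_ssim, x$mean_psnr, x$mean_dsc))
  invisible(x)
}

#' Write a cohort report as CSV
#'
#' Per-case rows followed by a summary row (`case_id = "mean"`), mirroring
#' the per-image metric tables used for this model family.
#'
#' @param report a [aggregate_report()] result.
#' @param path output CSV path.
#' @return invisibly, the data.frame written.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  df <- report$rows[, c("case_id", "ssim", "psnr", "dsc")]
  df <- rbind(df, data.frame(case_id = "mean", ssim = report$mean_ssim,
                             psnr = report$mean_psnr, dsc = report$mean_dsc))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
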