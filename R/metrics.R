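#' Pixel confusion counts between two binary masks
#'
#' Tallies true/false positives/negatives between a predicted and a
#' ground-truth mask over all pixels (foreground = 1).
#'
#' @param pred,gt binary arrays of identical shape (values 0/1 only).
#' @return list with `tp`, `fp`, `tn`, `fn`, class `confusion_counts`.
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim0(pred), dim0(gt)))
    stop("confusion_counts: shape mismatch")
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop("confusion_counts: masks must be binary (0/1)")
  p <- as.vector(pred) > 0; g <- as.vector(gt) > 0
  structure(list(tp = sum(p & g), fp = sum(p & !g),
                 tn = sum(!p & !g), fn = sum(!p & g)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Segmentation metrics from confusion counts
#'
#' `dice_score` = 2TP / (2TP + FN + FP); `sensitivity` = TP / (TP + FN);
#' `specificity` = TN / (TN + FP); `accuracy` = (TP + TN) / all pixels.
#' A metric whose denominator is zero is undefined and returned as `NA`
#' (excluded from aggregation, with the exclusion counted, by
#' [evaluate_models()]).
#'
#' @param c a [confusion_counts()].
#' @return scalar in \[0, 1\], or `NA_real_` if undefined.
#' @export
dice_score <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  den <- 2 * c$tp + c$fn + c$fp
  if (den == 0) NA_real_ else 2 * c$tp / den
}

#' @rdname dice_score
#' @export
sensitivity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  den <- c$tp + c$fn
  if (den == 0) NA_real_ else c$tp / den
}

#' @rdname dice_score
#' @export
specificity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  den <- c$tn + c$fp
  if (den == 0) NA_real_ else c$tn / den
}

#' @rdname dice_score
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  n <- c$tp + c$fp + c$tn + c$fn
  if (n == 0) NA_real_ else (c$tp + c$tn) / n
}

#' Hausdorff distance between two binary masks
#'
#' Computes the (percentile) Hausdorff distance between the foreground
#' pixel coordinate sets of a prediction and a ground truth: the directed
#' distance `d(A, B)` at percentile p is the p-th percentile (linear
#' interpolation) over `a` in A of `min_b ||a - b||_2`, with coordinates
#' scaled by `pixel_spacing` (mm); the returned value is
#' `max(d(A, B), d(B, A))`.  `percentile = 100` is the classical Hausdorff
#' distance; 95 is the robust variant usually reported for segmentation.
#' If either mask is empty the distance is undefined and `NA` is returned.
#'
#' @param pred,gt binary arrays of identical shape.
#' @param percentile percentile of the directed distances (default 95).
#' @param pixel_spacing length-2 (row, col) physical pixel size (default
#'   `c(1, 1)`, i.e. pixel units).
#' @return scalar distance (mm), or `NA_real_`.
#' @export
hausdorff_distance <- function(pred, gt, percentile = 95,
                               pixel_spacing = c(1, 1)) {
  if (!identical(dim0(pred), dim0(gt)))
    stop("hausdorff_distance: shape mismatch")
  stopifnot(percentile > 0, percentile <= 100, length(pixel_spacing) == 2)
  A <- mask_coords(pred, pixel_spacing)
  B <- mask_coords(gt, pixel_spacing)
  if (nrow(A) == 0 || nrow(B) == 0) return(NA_real_)
  max(directed_hd(A, B, percentile), directed_hd(B, A, percentile))
}

mask_coords <- function(m, spacing) {
  idx <- which(m > 0, arr.ind = TRUE)
  if (length(idx) == 0) return(matrix(0, 0, 2))
  cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2])
}

directed_hd <- function(A, B, percentile) {
  rB2 <- rowSums(B^2)
  n <- nrow(A)
  mins <- numeric(n)
  chunk <- max(1L, floor(2e7 / nrow(B)))
  for (lo in seq(1, n, by = chunk)) {
    hi <- min(lo + chunk - 1, n)
    Ab <- A[lo:hi, , drop = FALSE]
    D2 <- outer(rowSums(Ab^2), rB2, `+`) - 2 * tcrossprod(Ab, B)
    mins[lo:hi] <- sqrt(pmax(apply(D2, 1, min), 0))
  }
  stats::quantile(mins, percentile / 100, names = FALSE, type = 7)
}
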