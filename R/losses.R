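# Optimization objective (Tversky + cross-entropy) and evaluation metric
# (Dice similarity coefficient) with pixel-wise confusion counting.

#' Tversky loss parameters
#'
#' @param alpha false-positive weight (>= 0).
#' @param beta false-negative weight (>= 0). At `alpha = beta = 0.5` the
#'   Tversky loss reduces to one minus a smoothed Dice coefficient.
#' @param smooth additive smoothing constant (>= 0) protecting the empty/empty
#'   case and stabilizing gradients.
#' @return object of class `tversky_params`.
#' @export
tversky_params <- function(alpha = 0.5, beta = 0.5, smooth = 1.0) {
  stopifnot(alpha >= 0, beta >= 0, smooth >= 0)
  structure(list(alpha = alpha, beta = beta, smooth = smooth),
            class = "tversky_params")
}

#' Pixel-wise confusion counts
#'
#' For hard masks the counts are exact pixel tallies. For a soft prediction
#' `p` in `[0, 1]` the probabilistic counts are `TP = sum(p * t)`,
#' `FP = sum(p * (1 - t))`, `FN = sum((1 - p) * t)`, which is what makes the
#' Tversky loss differentiable.
#'
#' @param pred binary mask or foreground-probability matrix/array.
#' @param truth binary mask of identical spatial dimensions.
#' @return object of class `confusion_counts` with fields `TP`, `FP`, `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- drop(pred); truth <- drop(truth)
  if (!all(dim(pred) == dim(truth)) && length(pred) != length(truth))
    stop("confusion_counts: prediction and truth dimensions differ")
  if (is.array(pred) && is.array(truth) && !all(dim(pred) == dim(truth)))
    stop("confusion_counts: prediction and truth dimensions differ")
  p <- as.numeric(pred); t <- as.numeric(truth)
  stopifnot(all(p >= 0 & p <= 1), all(t %in% c(0, 1)))
  structure(list(TP = sum(p * t), FP = sum(p * (1 - t)),
                 FN = sum((1 - p) * t)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP = %g, FP = %g, FN = %g\n",
              x$TP, x$FP, x$FN))
  invisible(x)
}

#' Dice similarity coefficient
#'
#' `2 TP / (2 TP + FP + FN)`, computed pixel-wise. When the denominator is
#' zero (empty prediction against empty truth) the score is defined as 1,
#' rewarding a correctly predicted empty image.
#'
#' @param c a [confusion_counts()] object, or `TP` given the three counts
#'   separately.
#' @param FP,FN optional counts when `c` is given as a number.
#' @return Dice score in `[0, 1]`.
#' @export
dice_similarity <- function(c, FP = NULL, FN = NULL) {
  if (inherits(c, "confusion_counts")) {
    TP <- c$TP; FP <- c$FP; FN <- c$FN
  } else TP <- c
  den <- 2 * TP + FP + FN
  if (den == 0) return(1.0)
  2 * TP / den
}

#' Tversky loss
#'
#' `1 - (TP + s) / (TP + alpha * FP + beta * FN + s)` with soft
#' (probabilistic) confusion counts. With `alpha = beta = 0.5` this equals
#' one minus the smoothed Dice coefficient
#' `(2 TP + 2 s) / (2 TP + FP + FN + 2 s)`.
#'
#' @param pred foreground-probability matrix (values in `[0, 1]`) or hard
#'   mask.
#' @param truth binary mask with the same spatial dimensions.
#' @param params a [tversky_params()].
#' @return loss value >= 0.
#' @export
tversky_loss <- function(pred, truth, params = tversky_params()) {
  cc <- confusion_counts(pred, truth)
  1 - (cc$TP + params$smooth) /
    (cc$TP + params$alpha * cc$FP + params$beta * cc$FN + params$smooth)
}

#' Per-pixel categorical cross-entropy
#'
#' Mean over pixels of `-log p(true class)`, with probabilities clipped to
#' `[eps, 1 - eps]` before the logarithm.
#'
#' @param pred `(H, W, num_classes)` probability array, or an `H x W`
#'   foreground-probability matrix (two-class shorthand).
#' @param truth binary `H x W` mask (1 = foreground = class channel 2).
#' @param eps clipping constant, default `1e-7`.
#' @return mean cross-entropy >= 0.
#' @export
cross_entropy_loss <- function(pred, truth, eps = 1e-7) {
  if (is.matrix(pred)) {
    fg <- pred
  } else {
    if (!all(dim(pred)[1:2] == dim(truth)))
      stop("cross_entropy_loss: dimensions differ")
    fg <- pred[, , 2]
  }
  if (!all(dim(fg) == dim(truth)))
    stop("cross_entropy_loss: dimensions differ")
  fg <- pmin(pmax(fg, eps), 1 - eps)
  p_true <- ifelse(truth == 1, fg, 1 - fg)
  mean(-log(p_true))
}

#' Combined training objective: Tversky + cross-entropy
#'
#' The unweighted sum of [tversky_loss()] (on the foreground probability
#' channel) and [cross_entropy_loss()].
#'
#' @inheritParams cross_entropy_loss
#' @param params a [tversky_params()].
#' @return loss value >= 0.
#' @export
combined_loss <- function(pred, truth, params = tversky_params(),
                          eps = 1e-7) {
  fg <- if (is.matrix(pred)) pred else pred[, , 2]
  tversky_loss(fg, truth, params) + cross_entropy_loss(pred, truth, eps)
}

# d(combined loss)/d(logits) for a 2-class softmax head; prob is (H, W, 2),
# truth an H x W binary mask. Cross-entropy term: (p - onehot)/Npix.
# Tversky term: chain rule through the foreground softmax probability.
combined_loss_grad_logits <- function(prob, truth, params = tversky_params(),
                                      eps = 1e-7) {
  d <- dim(prob)
  npix <- d[1] * d[2]
  t <- truth
  onehot <- array(0, d)
  onehot[, , 1] <- 1 - t
  onehot[, , 2] <- t
  g_ce <- (prob - onehot) / npix

  pf <- prob[, , 2]
  TP <- sum(pf * t); FP <- sum(pf * (1 - t)); FN <- sum((1 - pf) * t)
  s <- params$smooth
  num <- TP + s
  den <- TP + params$alpha * FP + params$beta * FN + s
  # dL/dpf per pixel; dTP/dpf = t, dFP/dpf = 1 - t, dFN/dpf = -t
  dden <- t + params$alpha * (1 - t) - params$beta * t
  g_pf <- -(t * den - num * dden) / den^2
  jac <- pf * (1 - pf)       # dpf/dz_fg = -dpf/dz_bg for 2 classes
  g_tv <- array(0, d)
  g_tv[, , 2] <- g_pf * jac
  g_tv[, , 1] <- -g_pf * jac
  g_ce + g_tv
}

#' Per-class Dice scores of a prediction
#'
#' Computes the Dice similarity coefficient separately per class, treating
#' each class in turn as the positive one; the mean over classes matches the
#' across-classes reporting convention.
#'
#' @param pred_mask binary predicted mask (1 = foreground).
#' @param truth binary ground-truth mask.
#' @return named numeric vector `c(background, foreground)`.
#' @export
dice_per_class <- function(pred_mask, truth) {
  fg <- dice_similarity(confusion_counts(pred_mask, truth))
  bg <- dice_similarity(confusion_counts(1 - pred_mask, 1 - truth))
  c(background = bg, foreground = fg)
}
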