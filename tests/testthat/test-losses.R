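test_that("confusion counts are exact for hard masks and soft for probabilities", {
  all1 <- matrix(1, 10, 10)
  all0 <- matrix(0, 10, 10)
  cc <- confusion_counts(all1, all1)
  expect_equal(c(cc$TP, cc$FP, cc$FN), c(100, 0, 0))
  cc2 <- confusion_counts(all1, all0)
  expect_equal(c(cc2$TP, cc2$FP, cc2$FN), c(0, 100, 0))
  cc3 <- confusion_counts(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))
  expect_equal(c(cc3$TP, cc3$FP, cc3$FN), c(1, 1, 1))
  # soft counts: TP = sum p*t etc.
  p <- matrix(c(0.2, 0.8), 1); t <- matrix(c(1, 0), 1)
  cc4 <- confusion_counts(p, t)
  expect_equal(c(cc4$TP, cc4$FP, cc4$FN), c(0.2, 0.8, 0.8))
  expect_error(confusion_counts(matrix(1, 2, 2), matrix(1, 3, 3)), "dimensions")
})

test_that("Dice similarity follows 2TP/(2TP+FP+FN) with empty/empty = 1", {
  expect_equal(dice_similarity(confusion_counts(matrix(0, 2, 2), matrix(0, 2, 2))), 1.0)
  expect_equal(dice_similarity(5, 0, 0), 1.0)
  expect_equal(dice_similarity(2, 1, 1), 2 / 3, tolerance = 1e-4)
})

test_that("Dice is symmetric in FP/FN and monotone in errors", {
  set.seed(4)
  for (i in 1:25) {
    tp <- runif(1, 0, 50); fp <- runif(1, 0, 50); fn <- runif(1, 0, 50)
    expect_equal(dice_similarity(tp, fp, fn), dice_similarity(tp, fn, fp))
    expect_lte(dice_similarity(tp, fp + runif(1, 0, 10), fn),
               dice_similarity(tp, fp, fn))
    expect_lte(dice_similarity(tp, fp, fn + runif(1, 0, 10)),
               dice_similarity(tp, fp, fn))
    expect_gte(dice_similarity(tp, fp, fn), 0)
    expect_lte(dice_similarity(tp, fp, fn), 1)
  }
})

test_that("Tversky loss generalizes Dice and vanishes on perfect prediction", {
  t <- matrix(rbinom(100, 1, 0.5), 10, 10)
  expect_equal(tversky_loss(t, t, tversky_params(smooth = 1)), 0)
  # hard counts TP=2, FP=1, FN=1, alpha=beta=0.5, no smoothing -> 1/3
  p <- matrix(c(1, 1, 1, 0, 0, 0), 2); tr <- matrix(c(1, 1, 0, 1, 0, 0), 2)
  expect_equal(tversky_loss(p, tr, tversky_params(smooth = 0)), 1 / 3)
})

test_that("cross-entropy matches analytic values", {
  t <- matrix(c(1, 0), 1, 2)
  perfect <- array(c(0, 1, 1, 0), c(1, 2, 2))  # bg channel then fg channel
  expect_lt(cross_entropy_loss(perfect, t), 1e-5)
  uniform <- array(0.5, c(4, 4, 2))
  expect_equal(cross_entropy_loss(uniform, matrix(rbinom(16, 1, 0.5), 4, 4)),
               log(2), tolerance = 1e-9)
  # foreground prob 0.25 where truth is foreground contributes -log 0.25
  p <- array(0, c(1, 1, 2)); p[1, 1, ] <- c(0.75, 0.25)
  expect_equal(cross_entropy_loss(p, matrix(1, 1, 1)), -log(0.25),
               tolerance = 1e-6)
})

test_that("the training objective is the plain sum of its two terms", {
  set.seed(11)
  for (i in 1:10) {
    sm <- random_soft_map()
    prob <- array(c(1 - sm$pred, sm$pred), c(dim(sm$pred), 2))
    tp <- tversky_params(alpha = runif(1), beta = runif(1),
                         smooth = runif(1, 0, 2))
    expect_equal(combined_loss(prob, sm$truth, tp),
                 tversky_loss(sm$pred, sm$truth, tp) +
                   cross_entropy_loss(prob, sm$truth))
    expect_gte(combined_loss(prob, sm$truth, tp), 0)
  }
  t <- matrix(rbinom(64, 1, 0.3), 8, 8)
  prob <- array(c(1 - t, t), c(8, 8, 2))
  expect_lt(combined_loss(prob, t), 1e-5)
})

test_that("per-class Dice treats each class as positive in turn", {
  pred <- matrix(c(1, 1, 0, 0), 2); truth <- matrix(c(1, 0, 1, 0), 2)
  d <- dice_per_class(pred, truth)
  expect_equal(unname(d["foreground"]), 0.5)   # TP=1 FP=1 FN=1
  expect_equal(unname(d["background"]), 0.5)
  expect_equal(unname(dice_per_class(truth, truth)),
               c(1, 1))
})

test_that("the loss gradient wrt logits matches finite differences", {
  set.seed(5)
  t <- matrix(rbinom(36, 1, 0.4), 6, 6)
  z <- array(rnorm(72), c(6, 6, 2))
  tp <- tversky_params()
  loss_of <- function(z) combined_loss(mpunet:::softmax_channels(z), t, tp)
  g <- mpunet:::combined_loss_grad_logits(mpunet:::softmax_channels(z), t, tp)
  eps <- 1e-6
  for (ix in sample(length(z), 12)) {
    zp <- z; zp[ix] <- z[ix] + eps
    zm <- z; zm[ix] <- z[ix] - eps
    num <- (loss_of(zp) - loss_of(zm)) / (2 * eps)
    expect_lt(abs(num - g[ix]), 1e-6 + 1e-4 * abs(num))
  }
})
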