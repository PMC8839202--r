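# Training protocol: k-fold cross-validation with equally sized validation
# sets, Adam with a time-based learning-rate decay, early stopping on the
# training loss, per-epoch validation Dice tracking.

#' Cross-validation fold plan
#'
#' Randomly permutes the sample indices under `seed` and splits them into
#' `k` contiguous chunks, so fold sizes differ by at most one (equal when `k`
#' divides `n`). Deterministic for fixed `(n, k, seed)`.
#'
#' @param n number of samples (>= k).
#' @param k number of folds (>= 2); 5 in the reference protocol.
#' @param seed integer seed.
#' @return object of class `fold_plan` with `fold_assignments` (integer in
#'   `1..k` per sample), `n`, `k`, `seed`.
#' @export
make_cv_folds <- function(n, k = 5L, seed = 1L) {
  stopifnot(n >= k, k >= 2)
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  structure(list(fold_assignments = fold, n = as.integer(n),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("%d-fold plan over %d samples (seed %d); validation sizes: %s\n",
              x$k, x$n, x$seed,
              paste(tabulate(x$fold_assignments, x$k), collapse = ", ")))
  invisible(x)
}

#' Time-based learning-rate decay
#'
#' `initial / (1 + decay * epoch)`; monotone nonincreasing in the epoch. With
#' the default decay of `initial / 200` the rate after 200 epochs is still
#' within about 10 percent of the initial value.
#'
#' @param initial initial learning rate (positive); 1e-4 in the reference
#'   protocol.
#' @param decay nonnegative decay constant per epoch.
#' @param epoch nonnegative epoch index (0 = first).
#' @return learning rate.
#' @export
time_decay_lr <- function(initial = 1e-4, decay = initial / 200, epoch = 0) {
  stopifnot(initial > 0, decay >= 0, all(epoch >= 0))
  initial / (1 + decay * epoch)
}

#' Training control parameters
#'
#' @param learning_rate initial Adam learning rate.
#' @param decay time-decay constant ([time_decay_lr()]); defaults to
#'   `learning_rate / 200`.
#' @param max_epochs epoch cap (200 in the reference protocol).
#' @param patience early-stopping patience: training stops when the epoch-mean
#'   training loss has not improved (strict decrease by more than
#'   `improve_tol`) for this many consecutive epochs.
#' @param improve_tol minimum decrease counting as improvement.
#' @param batch_size examples per Adam step.
#' @param tversky a [tversky_params()].
#' @param threshold foreground threshold for validation Dice.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @param seed seed for batch shuffling and dropout masks.
#' @param verbose print per-epoch progress.
#' @return object of class `train_control`.
#' @export
train_control <- function(learning_rate = 1e-4, decay = learning_rate / 200,
                          max_epochs = 200L, patience = 20L,
                          improve_tol = 1e-6, batch_size = 2L,
                          tversky = tversky_params(), threshold = 0.5,
                          beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                          seed = 1L, verbose = FALSE) {
  stopifnot(learning_rate > 0, decay >= 0, max_epochs >= 1, patience >= 1,
            batch_size >= 1)
  structure(list(learning_rate = learning_rate, decay = decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 improve_tol = improve_tol,
                 batch_size = as.integer(batch_size), tversky = tversky,
                 threshold = threshold, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

adam_init <- function(params) {
  lapply(params, function(layer) lapply(layer, function(a) {
    z <- a; z[] <- 0
    list(m = z, v = z)
  }))
}

adam_step <- function(params, grads, state, lr, t, control) {
  b1 <- control$beta1; b2 <- control$beta2; eps <- control$adam_eps
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      st <- state[[nm]][[pn]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g * g
      mhat <- st$m / (1 - b1^t)
      vhat <- st$v / (1 - b2^t)
      params[[nm]][[pn]] <- params[[nm]][[pn]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[nm]][[pn]] <- st
    }
  }
  list(params = params, state = state)
}

accumulate_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g))
    for (pn in names(g[[nm]]))
      total[[nm]][[pn]] <- total[[nm]][[pn]] + g[[nm]][[pn]]
  total
}

scale_grads <- function(g, s) {
  for (nm in names(g))
    for (pn in names(g[[nm]])) g[[nm]][[pn]] <- g[[nm]][[pn]] * s
  g
}

eval_dsc <- function(model, images, masks, threshold) {
  scores <- vapply(seq_along(images), function(i) {
    prob <- forward_mpunet(model, images[[i]], training = FALSE)$prob
    dice_per_class(predict_mask(prob, threshold), masks[[i]])
  }, numeric(2))
  rowMeans(scores)
}

#' Train one cross-validation fold
#'
#' Runs Adam on the combined Tversky + cross-entropy objective. After every
#' epoch the per-class Dice on the validation set is evaluated (hard masks at
#' the control threshold) and the running best is kept together with the
#' weights that achieved it. Training stops at `max_epochs` or as soon as the
#' epoch-mean training loss has failed to improve for `patience` consecutive
#' epochs, whichever comes first.
#'
#' @param model a [build_multipath_unet()] model (trained in place
#'   functionally; the returned state carries the updated weights).
#' @param train_images,train_masks lists of preprocessed input arrays and
#'   binary masks.
#' @param val_images,val_masks validation set (disjoint from training).
#' @param control a [train_control()].
#' @return object of class `train_state`: `epoch` (epochs run),
#'   `best_train_loss`, `epochs_since_improvement`, `best_val_dsc_per_class`,
#'   `best_epoch`, `history` (per-epoch data frame), `model` (final weights)
#'   and `best_model` (weights at the best validation epoch).
#' @export
train_fold <- function(model, train_images, train_masks,
                       val_images, val_masks, control = train_control()) {
  stopifnot(inherits(model, "multipath_unet"),
            length(train_images) >= 1, length(val_images) >= 1,
            length(train_images) == length(train_masks),
            length(val_images) == length(val_masks))
  n <- length(train_images)
  state <- adam_init(model$params)
  best_train_loss <- Inf
  since_improve <- 0L
  best_val <- c(background = -Inf, foreground = -Inf)
  best_mean <- -Inf
  best_epoch <- 0L
  best_params <- model$params
  history <- list()
  t_adam <- 0L

  with_seed(control$seed, {
    epoch <- 0L
    while (epoch < control$max_epochs) {
      epoch <- epoch + 1L
      lr <- time_decay_lr(control$learning_rate, control$decay, epoch - 1L)
      order_idx <- sample.int(n)
      epoch_loss <- 0
      for (start in seq(1, n, by = control$batch_size)) {
        idx <- order_idx[start:min(start + control$batch_size - 1L, n)]
        grads <- NULL
        batch_loss <- 0
        for (i in idx) {
          fw <- forward_mpunet(model, train_images[[i]], training = TRUE,
                               keep_cache = TRUE)
          loss_i <- combined_loss(fw$prob, train_masks[[i]], control$tversky)
          gl <- combined_loss_grad_logits(fw$prob, train_masks[[i]],
                                          control$tversky)
          grads <- accumulate_grads(grads,
                                    backward_mpunet(model, fw$cache, gl))
          batch_loss <- batch_loss + loss_i
        }
        grads <- scale_grads(grads, 1 / length(idx))
        t_adam <- t_adam + 1L
        upd <- adam_step(model$params, grads, state, lr, t_adam, control)
        model$params <- upd$params
        state <- upd$state
        epoch_loss <- epoch_loss + batch_loss
      }
      epoch_loss <- epoch_loss / n

      val_dsc <- eval_dsc(model, val_images, val_masks, control$threshold)
      if (mean(val_dsc) > best_mean) {
        best_mean <- mean(val_dsc)
        best_params <- model$params
      }
      best_val <- pmax(best_val, val_dsc)
      history[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, train_loss = epoch_loss,
        val_dsc_background = val_dsc["background"],
        val_dsc_foreground = val_dsc["foreground"])

      if (epoch_loss < best_train_loss - control$improve_tol) {
        best_train_loss <- epoch_loss
        since_improve <- 0L
        best_epoch <- epoch
      } else {
        since_improve <- since_improve + 1L
      }
      if (control$verbose)
        message(sprintf(
          "epoch %3d  lr %.2e  loss %.4f  val DSC bg %.4f fg %.4f",
          epoch, lr, epoch_loss, val_dsc["background"],
          val_dsc["foreground"]))
      if (since_improve >= control$patience) break
    }
  })

  history <- do.call(rbind, history)
  rownames(history) <- NULL
  structure(list(
    epoch = epoch, learning_rate = time_decay_lr(control$learning_rate,
                                                 control$decay, epoch - 1L),
    best_train_loss = best_train_loss,
    epochs_since_improvement = since_improve,
    best_val_dsc_per_class = best_val,
    best_epoch = best_epoch,
    history = history,
    model = model,
    best_model = { m <- model; m$params <- best_params; m },
    control = control
  ), class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf(
    "Training run: %d epoch(s); best train loss %.4f (epoch %d)\n",
    x$epoch, x$best_train_loss, x$best_epoch))
  cat(sprintf("  best validation DSC: background %.4f, foreground %.4f\n",
              x$best_val_dsc_per_class["background"],
              x$best_val_dsc_per_class["foreground"]))
  invisible(x)
}

#' @export
plot.train_state <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "Objective", ...)
  graphics::plot(h$epoch, h$val_dsc_foreground, type = "l", col = 2,
                 ylim = c(0, 1), xlab = "epoch", ylab = "validation DSC",
                 main = "Validation Dice")
  graphics::lines(h$epoch, h$val_dsc_background, col = 4)
  graphics::legend("bottomright", legend = c("foreground", "background"),
                   col = c(2, 4), lty = 1, bty = "n")
  invisible(x)
}

#' k-fold cross-validation of a multi-path U-Net
#'
#' Builds one freshly initialized model per fold (seed offset by the fold
#' index), trains it with [train_fold()] on the out-of-fold samples, and
#' aggregates each fold's best validation Dice per class into mean and
#' standard deviation.
#'
#' @param images,masks lists of preprocessed inputs and binary masks.
#' @param config an [mpunet_config()].
#' @param k number of folds.
#' @param seed seed for the fold plan and per-fold weight seeds.
#' @param control a [train_control()].
#' @param keep_models keep each fold's best-epoch model in the result
#'   (needed for downstream held-out predictions).
#' @return object of class `cv_result`: `fold_dsc` (k x 2 matrix of best
#'   per-class DSC), `mean`, `sd`, `mean_across_classes`, `folds`
#'   (the [make_cv_folds()] plan), `states`, optionally `models`.
#' @export
cross_validate <- function(images, masks, config, k = 5L, seed = 1L,
                           control = train_control(), keep_models = FALSE) {
  n <- length(images)
  stopifnot(n >= k, length(masks) == n)
  plan <- make_cv_folds(n, k, seed)
  fold_dsc <- matrix(NA_real_, k, 2,
                     dimnames = list(NULL, c("background", "foreground")))
  states <- vector("list", k)
  models <- if (keep_models) vector("list", k) else NULL
  for (f in seq_len(k)) {
    val_idx <- which(plan$fold_assignments == f)
    tr_idx <- setdiff(seq_len(n), val_idx)
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    model <- build_multipath_unet(cfg_f)
    ctl_f <- control
    ctl_f$seed <- control$seed + f
    st <- train_fold(model, images[tr_idx], masks[tr_idx],
                     images[val_idx], masks[val_idx], ctl_f)
    fold_dsc[f, ] <- st$best_val_dsc_per_class
    st$val_idx <- val_idx
    if (keep_models) models[[f]] <- st$best_model
    st$model <- NULL
    if (!keep_models) st$best_model <- NULL
    states[[f]] <- st
  }
  structure(list(
    fold_dsc = fold_dsc,
    mean = colMeans(fold_dsc),
    sd = apply(fold_dsc, 2, sd),
    mean_across_classes = mean(fold_dsc),
    folds = plan,
    states = states,
    models = models
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  k <- nrow(x$fold_dsc)
  cat(sprintf("%d-fold cross-validation (best validation DSC per fold):\n", k))
  print(round(x$fold_dsc, 4))
  cat(sprintf("mean +/- sd: background %.4f +/- %.4f, foreground %.4f +/- %.4f\n",
              x$mean["background"], x$sd["background"],
              x$mean["foreground"], x$sd["foreground"]))
  cat(sprintf("mean across classes: %.4f\n", x$mean_across_classes))
  invisible(x)
}

#' Write a cross-validation metrics report
#'
#' @param cv a `cv_result`.
#' @param path output file; format by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  df <- data.frame(fold = seq_len(nrow(cv$fold_dsc)), cv$fold_dsc)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(per_fold = df,
                              mean = as.list(cv$mean),
                              sd = as.list(cv$sd),
                              mean_across_classes = cv$mean_across_classes),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    agg <- data.frame(fold = c("mean", "sd"),
                      rbind(cv$mean, cv$sd))
    write.csv(rbind(df, agg), path, row.names = FALSE)
  }
  invisible(path)
}
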