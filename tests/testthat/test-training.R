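test_that("cross-validation folds partition the samples into equal sets", {
  plan <- make_cv_folds(150, 5, seed = 2)
  expect_identical(unname(tabulate(plan$fold_assignments, 5)), rep(30L, 5))
  plan2 <- make_cv_folds(10, 5, seed = 9)
  expect_identical(unname(tabulate(plan2$fold_assignments, 5)), rep(2L, 5))
  # every index sits in exactly one validation fold
  expect_identical(sort(unlist(lapply(1:5, function(f)
    which(plan2$fold_assignments == f)))), 1:10)
  # determinism and near-equal sizes when k does not divide n
  expect_identical(make_cv_folds(10, 5, seed = 9), plan2)
  plan3 <- make_cv_folds(13, 5, seed = 1)
  expect_lte(diff(range(tabulate(plan3$fold_assignments, 5))), 1L)
  expect_error(make_cv_folds(3, 5), "n >= k")
})

test_that("time-based decay starts at the initial rate and never increases", {
  expect_equal(time_decay_lr(1e-4, 5e-4, 0), 1e-4)
  expect_equal(time_decay_lr(1e-4, 0, 150), 1e-4)
  expect_equal(time_decay_lr(1e-4, 5e-4, 200), 1e-4 / 1.1)
  lrs <- time_decay_lr(1e-4, 1e-3, 0:300)
  expect_true(all(diff(lrs) <= 0))
})

test_that("early stopping halts exactly patience epochs after the last improvement", {
  cfg <- mpunet_config(list(pathway_spec(2, c(2), 2)),
                       input_size = c(8, 8), input_channels = 1,
                       dropout_rate = 0, seed = 3)
  model <- build_multipath_unet(cfg)
  set.seed(8)
  imgs <- replicate(2, array(rnorm(64), c(8, 8, 1)), simplify = FALSE)
  msks <- replicate(2, matrix(rbinom(64, 1, 0.5), 8, 8), simplify = FALSE)
  # a vanishing learning rate makes the loss stagnate from the first epoch
  ctl <- train_control(learning_rate = 1e-30, max_epochs = 200, patience = 20,
                       batch_size = 2, seed = 4)
  st <- train_fold(model, imgs, msks, imgs, msks, ctl)
  expect_identical(st$best_epoch, 1L)
  expect_identical(st$epoch, 21L)         # 1 improvement + 20 stagnant epochs
  expect_identical(st$epochs_since_improvement, 20L)
})

test_that("training never exceeds the epoch cap", {
  cfg <- mpunet_config(list(pathway_spec(2, c(2), 2)),
                       input_size = c(8, 8), input_channels = 1,
                       dropout_rate = 0, seed = 3)
  model <- build_multipath_unet(cfg)
  set.seed(8)
  imgs <- list(array(rnorm(64), c(8, 8, 1)))
  msks <- list(matrix(rbinom(64, 1, 0.5), 8, 8))
  ctl <- train_control(learning_rate = 1e-30, max_epochs = 40, patience = 1000,
                       batch_size = 1, seed = 4)
  st <- train_fold(model, imgs, msks, imgs, msks, ctl)
  expect_identical(st$epoch, 40L)
  expect_lte(nrow(st$history), 40L)
})

test_that("best validation DSC is the running maximum over epochs", {
  cfg <- mpunet_config(list(pathway_spec(2, c(3), 4)),
                       input_size = c(16, 16), input_channels = 1,
                       dropout_rate = 0, seed = 5)
  model <- build_multipath_unet(cfg)
  set.seed(31)
  imgs <- replicate(3, array(rnorm(256), c(16, 16, 1)), simplify = FALSE)
  msks <- lapply(1:3, function(i) {
    m <- matrix(0L, 16, 16); m[4:9, 4:9] <- 1L; m
  })
  ctl <- train_control(learning_rate = 5e-3, max_epochs = 8, batch_size = 3,
                       seed = 6)
  st <- train_fold(model, imgs, msks, imgs[1], msks[1], ctl)
  expect_gte(st$best_val_dsc_per_class["foreground"],
             max(st$history$val_dsc_foreground))
  expect_gte(st$best_val_dsc_per_class["background"],
             max(st$history$val_dsc_background))
  expect_identical(nrow(st$history), st$epoch)
})

test_that("cross_validate trains one model per fold and aggregates recomputably", {
  set.seed(77)
  imgs <- replicate(5, array(rnorm(256), c(16, 16, 1)), simplify = FALSE)
  msks <- replicate(5, {
    m <- matrix(0L, 16, 16); m[sample(4:10, 1):12, 5:11] <- 1L; m
  }, simplify = FALSE)
  cfg <- mpunet_config(list(pathway_spec(2, c(3), 4)),
                       input_size = c(16, 16), input_channels = 1,
                       dropout_rate = 0, seed = 5)
  cv <- cross_validate(imgs, msks, cfg, k = 5, seed = 2,
                       control = train_control(learning_rate = 2e-3,
                                               max_epochs = 3, batch_size = 2))
  expect_identical(dim(cv$fold_dsc), c(5L, 2L))
  expect_identical(length(cv$states), 5L)
  expect_equal(unname(cv$mean), unname(colMeans(cv$fold_dsc)))
  expect_equal(unname(cv$sd), unname(apply(cv$fold_dsc, 2, sd)))
  expect_equal(cv$mean_across_classes, mean(cv$fold_dsc))
})

test_that("training runs are reproducible under fixed seeds", {
  cfg <- mpunet_config(list(pathway_spec(2, c(3), 4)),
                       input_size = c(16, 16), input_channels = 1,
                       dropout_rate = 0.1, seed = 5)
  set.seed(14)
  imgs <- replicate(2, array(rnorm(256), c(16, 16, 1)), simplify = FALSE)
  msks <- replicate(2, matrix(rbinom(256, 1, 0.3), 16, 16), simplify = FALSE)
  ctl <- train_control(learning_rate = 1e-3, max_epochs = 4, seed = 9)
  st1 <- train_fold(build_multipath_unet(cfg), imgs, msks, imgs, msks, ctl)
  st2 <- train_fold(build_multipath_unet(cfg), imgs, msks, imgs, msks, ctl)
  expect_identical(st1$history, st2$history)
  expect_identical(st1$model$params, st2$model$params)
})
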