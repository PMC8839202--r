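test_that("pathway coherence returns the shared downsampling factor", {
  expect_identical(
    validate_pathway_coherence(list(pathway_spec(4, c(40, 240), 240),
                                    pathway_spec(2, c(40, 80, 160, 220), 220))),
    16L)
  expect_identical(validate_pathway_coherence(list(pathway_spec(2, c(8, 8, 8), 8))),
                   8L)
  expect_error(
    validate_pathway_coherence(list(pathway_spec(4, c(8, 8), 8),
                                    pathway_spec(2, c(8, 8, 8), 8))),
    "incoherent")
})

test_that("decoder filters are the reverse of the encoder's", {
  p <- pathway_spec(2, c(40, 80, 160, 220), 220)
  expect_identical(p$decoder_filters, c(220L, 160L, 80L, 40L))
  expect_identical(p$depth, 4L)
})

test_that("conv_block preserves spatial dims and sets the channel count", {
  cfg <- tiny_config()
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  y <- conv_block(x, filters = 40, cfg)
  expect_identical(dim(y), c(16L, 16L, 40L))
  # all-zero input stays all zero (convolution bias is zero-initialized)
  expect_true(all(conv_block(array(0, c(16, 16, 3)), 8, cfg) == 0))
})

test_that("leaky ReLU scales negative pre-activations by the slope", {
  x <- c(-2, -0.5, 0, 0.5, 2)
  expect_equal(leaky_relu(x, 0.1), c(-0.2, -0.05, 0, 0.5, 2))
})

test_that("layer normalization matches hand-computed cross-channel stats", {
  # constant across channels at every position -> all zeros
  x <- array(rep(matrix(rnorm(9), 3, 3), 5), c(3, 3, 5))
  y <- interconnect_layer_norm(x, g = matrix(1, 3, 3), b = matrix(0, 3, 3))
  expect_lt(max(abs(y)), 1e-2)  # sigma = 0, epsilon-guarded
  # two channels {1, 3}: mu = 2, sigma^2 = 1 -> {-1, +1} (epsilon -> 0)
  x2 <- array(c(1, 3), c(1, 1, 2))
  y2 <- interconnect_layer_norm(x2, g = matrix(1, 1, 1), b = matrix(0, 1, 1),
                                eps = 1e-12)
  expect_equal(as.numeric(y2), c(-1, 1), tolerance = 1e-6)
  # zero gain -> output equals the bias regardless of input
  b <- matrix(rnorm(4), 2, 2)
  x3 <- array(rnorm(2 * 2 * 6), c(2, 2, 6))
  y3 <- interconnect_layer_norm(x3, g = matrix(0, 2, 2), b = b)
  expect_equal(array(rep(b, 6), c(2, 2, 6)), y3)
})

test_that("layer norm rejects mismatched gain/bias shapes", {
  x <- array(rnorm(8), c(2, 2, 2))
  expect_error(interconnect_layer_norm(x, matrix(1, 3, 3), matrix(0, 3, 3)),
               "shape")
})

test_that("spatial dropout zeroes whole channels and rescales survivors", {
  x <- array(rnorm(4 * 4 * 10000), c(4, 4, 10000))
  expect_identical(spatial_dropout(x, rate = 0, training = TRUE), x)
  expect_identical(spatial_dropout(x, rate = 0.7, training = FALSE), x)
  y <- spatial_dropout(x, rate = 0.5, training = TRUE, seed = 99L)
  ch_zero <- apply(y == 0, 3, all)
  # binomial check: fraction of dropped channels within 3 SE of 0.5
  expect_lt(abs(mean(ch_zero) - 0.5), 3 * sqrt(0.25 / 10000))
  # every non-dropped channel is the input scaled by exactly 1/(1 - rate)
  expect_equal(y[, , !ch_zero], x[, , !ch_zero] * 2)
  # partially-zeroed channels never occur
  frac0 <- apply(y == 0, 3, mean)
  expect_true(all(frac0 %in% c(0, 1) | apply(x == 0, 3, mean) > 0))
})

test_that("the assembled reference model has the expected structure", {
  model <- build_multipath_unet(reference_config())
  expect_identical(model$bottleneck_size, c(32L, 32L))
  # concatenated bottleneck channels feed the first decoder deconvolutions
  expect_identical(nrow(model$params$p1_dec1_up$W), 240L + 220L)
  expect_identical(nrow(model$params$p2_dec1_up$W), 240L + 220L)
  # layer-norm gain/bias live on the 32x32 bottleneck grid
  expect_identical(dim(model$params$ln$g), c(32L, 32L))
})

test_that("incoherent or indivisible configurations are rejected", {
  expect_error(mpunet_config(list(pathway_spec(4, c(8, 8), 8),
                                  pathway_spec(2, c(8, 8, 8), 8)),
                             input_size = c(64, 64)),
               "incoherent")
  expect_error(mpunet_config(list(pathway_spec(4, c(8, 8), 8),
                                  pathway_spec(2, c(8, 8, 8, 8), 8)),
                             input_size = c(100, 100)),
               "divisible")
})

test_that("parameter counting matches hand counts and ignores the seed", {
  # single conv layer 1 -> 1 channel with bias: 3*3*1*1 + 1 = 10
  cfg1 <- mpunet_config(list(pathway_spec(2, c(1), 1)),
                        input_size = c(8, 8), input_channels = 1,
                        num_classes = 2)
  m1 <- build_multipath_unet(cfg1)
  expect_identical(sum(lengths(m1$params$p1_enc1_c1)), 10L)
  # two stacked 3x3 convs 3 -> 40 -> 40 with biases: 1120 + 14440 = 15560
  cfg2 <- mpunet_config(list(pathway_spec(2, c(40), 40)),
                        input_size = c(8, 8), input_channels = 3)
  m2 <- build_multipath_unet(cfg2)
  expect_identical(sum(lengths(m2$params$p1_enc1_c1)) +
                     sum(lengths(m2$params$p1_enc1_c2)), 15560L)
  # pure function of the configuration: any seed, same count
  cfg3 <- tiny_config(seed = 1L)
  cfg4 <- tiny_config(seed = 12345L)
  expect_identical(count_trainable_parameters(build_multipath_unet(cfg3)),
                   count_trainable_parameters(build_multipath_unet(cfg4)))
})

test_that("forward pass preserves spatial dims and yields simplex outputs", {
  cfg <- tiny_config(input = c(24L, 16L), dropout = 0.2)
  model <- build_multipath_unet(cfg)
  x <- array(rnorm(24 * 16 * 2), c(24, 16, 2))
  for (training in c(FALSE, TRUE)) {
    fw <- mpunet:::forward_mpunet(model, x, training = training)
    expect_identical(dim(fw$prob), c(24L, 16L, 2L))
    expect_lt(max(abs(apply(fw$prob, c(1, 2), sum) - 1)), 1e-5)
    expect_true(all(fw$prob >= 0 & fw$prob <= 1))
  }
  expect_error(mpunet:::forward_mpunet(model, array(0, c(16, 16, 2))),
               "expects")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tiny_config(dropout = 0)
  model <- build_multipath_unet(cfg)
  set.seed(21)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  truth <- matrix(rbinom(256, 1, 0.4), 16, 16)
  tp <- tversky_params()
  fw <- mpunet:::forward_mpunet(model, x, keep_cache = TRUE)
  gl <- mpunet:::combined_loss_grad_logits(fw$prob, truth, tp)
  grads <- mpunet:::backward_mpunet(model, fw$cache, gl)
  loss_at <- function(m) {
    combined_loss(mpunet:::forward_mpunet(m, x)$prob, truth, tp)
  }
  eps <- 1e-5
  for (nm in c("p1_enc1_c1", "p2_bot_c2", "p1_dec2_c1", "ln", "out")) {
    for (pn in names(model$params[[nm]])) {
      a <- model$params[[nm]][[pn]]
      for (ix in sample(length(a), min(3, length(a)))) {
        mp <- mm <- model
        mp$params[[nm]][[pn]][ix] <- a[ix] + eps
        mm$params[[nm]][[pn]][ix] <- a[ix] - eps
        num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
        ana <- grads[[nm]][[pn]][ix]
        expect_lt(abs(num - ana), 1e-4 + 1e-3 * (abs(num) + abs(ana)))
      }
    }
  }
})

test_that("probability maps binarize with a strict foreground threshold", {
  p <- array(0, c(2, 2, 2))
  p[, , 2] <- matrix(c(1, 0.5, 0.2, 0.7), 2, 2)
  p[, , 1] <- 1 - p[, , 2]
  m <- predict_mask(p, 0.5)
  expect_identical(m, matrix(c(1L, 0L, 0L, 1L), 2, 2))
  expect_identical(predict_mask(matrix(1, 3, 3)), matrix(1L, 3, 3))
  expect_identical(predict_mask(matrix(0.5, 3, 3), 0.5), matrix(0L, 3, 3))
})

test_that("configurations and weights round-trip through files", {
  cfg <- tiny_config()
  f <- tempfile(fileext = ".yaml")
  write_mpunet_config(cfg, f)
  cfg2 <- read_mpunet_config(f)
  expect_equal(cfg, cfg2)
  model <- build_multipath_unet(cfg)
  fw <- tempfile(fileext = ".json")
  save_mpunet(model, fw)
  model2 <- load_mpunet(fw)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  expect_equal(predict(model, x), predict(model2, x), tolerance = 1e-12)
})
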