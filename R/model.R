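# Multi-path U-Net: declarative pathway/model configuration, coherence
# validation, weight initialization, forward and backward passes, parameter
# counting.

#' Declare one receptive-field pathway
#'
#' A pathway is a complete encoder-bottleneck-decoder branch with its own
#' square pooling window. The encoder applies `length(encoder_filters)`
#' levels of (two-conv block, max pooling, spatial dropout); the decoder
#' mirrors it with transposed convolutions whose kernel and stride equal the
#' pooling window. Decoder filter counts are the reverse of the encoder's.
#'
#' @param pool_window integer >= 2; side of the square max-pooling window
#'   (and of the matching transposed-convolution kernel/stride).
#' @param encoder_filters integer vector of filters per encoder level, e.g.
#'   `c(40, 240)` or `c(40, 80, 160, 220)`.
#' @param bottleneck_filters filters of the pathway's bottleneck conv block.
#' @return object of class `pathway_spec`.
#' @examples
#' pathway_spec(4, c(40, 240), 240)
#' @export
pathway_spec <- function(pool_window, encoder_filters, bottleneck_filters) {
  stopifnot(length(pool_window) == 1, pool_window >= 2,
            pool_window == as.integer(pool_window),
            length(encoder_filters) >= 1, all(encoder_filters >= 1),
            length(bottleneck_filters) == 1, bottleneck_filters >= 1)
  structure(list(
    pool_window = as.integer(pool_window),
    encoder_filters = as.integer(encoder_filters),
    decoder_filters = rev(as.integer(encoder_filters)),
    bottleneck_filters = as.integer(bottleneck_filters),
    depth = length(encoder_filters)
  ), class = "pathway_spec")
}

#' @export
print.pathway_spec <- function(x, ...) {
  cat(sprintf(
    "Receptive-field pathway: pool %dx%d, depth %d (downsampling factor %d)\n",
    x$pool_window, x$pool_window, x$depth, x$pool_window^x$depth))
  cat("  encoder filters:", paste(x$encoder_filters, collapse = ", "),
      "| bottleneck:", x$bottleneck_filters, "\n")
  invisible(x)
}

#' Validate that all pathways reach the same downsampling factor
#'
#' Pathways are coherent when `pool_window ^ depth` is identical across all
#' of them (e.g. a pool-4 depth-2 pathway and a pool-2 depth-4 pathway both
#' downsample by 16, since 4^2 = 2^4), so their bottleneck feature maps have
#' compatible spatial dimensions and can be concatenated.
#'
#' @param pathways nonempty list of [pathway_spec()] objects.
#' @return the common downsampling factor, an integer.
#' @examples
#' validate_pathway_coherence(list(
#'   pathway_spec(4, c(40, 240), 240),
#'   pathway_spec(2, c(40, 80, 160, 220), 220)
#' )) # 16
#' @export
validate_pathway_coherence <- function(pathways) {
  stopifnot(is.list(pathways), length(pathways) >= 1)
  factors <- vapply(pathways, function(p) p$pool_window^p$depth, numeric(1))
  if (any(factors != factors[1])) {
    bad <- which(factors != factors[1])[1]
    stop(sprintf(
      paste0("incoherent pathways: pathway %d downsamples by %d^%d = %d, ",
             "but pathway 1 downsamples by %d"),
      bad, pathways[[bad]]$pool_window, pathways[[bad]]$depth,
      factors[bad], factors[1]), call. = FALSE)
  }
  as.integer(factors[1])
}

#' Assemble a model configuration
#'
#' @param pathways nonempty list of [pathway_spec()]; all must share one
#'   downsampling factor, which must divide both input dimensions.
#' @param input_size integer vector `c(height, width)` in pixels.
#' @param input_channels 1 (grayscale) or 3 (RGB) typically.
#' @param num_classes number of output classes; 2 for background/foreground.
#'   Channel 1 is background, channel 2 foreground.
#' @param conv_kernel,conv_stride convolution kernel side and stride of every
#'   conv-block layer (3 and 1 in the reference architecture).
#' @param leaky_slope negative-side slope of the leaky ReLU (0.1).
#' @param dropout_rate spatial-dropout rate in `[0, 1)`.
#' @param norm_epsilon stabilizer for instance and layer normalization.
#' @param seed integer seed for weight initialization.
#' @return object of class `mpunet_config`.
#' @export
mpunet_config <- function(pathways,
                          input_size = c(512L, 512L),
                          input_channels = 3L,
                          num_classes = 2L,
                          conv_kernel = 3L,
                          conv_stride = 1L,
                          leaky_slope = 0.1,
                          dropout_rate = 0.1,
                          norm_epsilon = 1e-5,
                          seed = 42L) {
  if (inherits(pathways, "pathway_spec")) pathways <- list(pathways)
  stopifnot(length(input_size) == 2, all(input_size >= 1),
            input_channels >= 1, num_classes >= 1,
            conv_kernel >= 1, conv_kernel %% 2 == 1, conv_stride == 1,
            leaky_slope > 0, leaky_slope < 1,
            dropout_rate >= 0, dropout_rate < 1, norm_epsilon > 0)
  f <- validate_pathway_coherence(pathways)
  if (any(input_size %% f != 0))
    stop(sprintf("input size %dx%d is not divisible by the downsampling factor %d",
                 input_size[1], input_size[2], f), call. = FALSE)
  structure(list(
    input_height = as.integer(input_size[1]),
    input_width = as.integer(input_size[2]),
    input_channels = as.integer(input_channels),
    num_classes = as.integer(num_classes),
    pathways = pathways,
    conv_kernel = as.integer(conv_kernel),
    conv_stride = as.integer(conv_stride),
    leaky_slope = leaky_slope,
    dropout_rate = dropout_rate,
    norm_epsilon = norm_epsilon,
    seed = as.integer(seed),
    downsampling_factor = f
  ), class = "mpunet_config")
}

#' @export
print.mpunet_config <- function(x, ...) {
  cat(sprintf("Multi-path U-Net configuration: %dx%dx%d input, %d classes\n",
              x$input_height, x$input_width, x$input_channels, x$num_classes))
  cat(sprintf("  %d pathway(s), common downsampling factor %d\n",
              length(x$pathways), x$downsampling_factor))
  for (p in x$pathways) print(p)
  cat(sprintf("  conv %dx%d stride %d, leaky slope %g, dropout %g\n",
              x$conv_kernel, x$conv_kernel, x$conv_stride,
              x$leaky_slope, x$dropout_rate))
  invisible(x)
}

he_uniform <- function(n_in, dims) {
  lim <- sqrt(6 / n_in)
  array(runif(prod(dims), -lim, lim), dims)
}

# Conv weights live as (k*k*Cin) x Cout GEMM matrices, matching the im2col
# column order of the C++ kernels; deconv weights as Cin x (p*p*Cout).
init_params <- function(config) {
  k <- config$conv_kernel
  params <- list()
  conv_par <- function(cin, cout)
    list(W = he_uniform(k * k * cin, c(k * k * cin, cout)),
         b = numeric(cout))
  total_bottleneck <- sum(vapply(config$pathways,
                                 function(p) p$bottleneck_filters, numeric(1)))
  for (i in seq_along(config$pathways)) {
    p <- config$pathways[[i]]
    cin <- config$input_channels
    for (j in seq_len(p$depth)) {
      f <- p$encoder_filters[j]
      params[[sprintf("p%d_enc%d_c1", i, j)]] <- conv_par(cin, f)
      params[[sprintf("p%d_enc%d_c2", i, j)]] <- conv_par(f, f)
      cin <- f
    }
    params[[sprintf("p%d_bot_c1", i)]] <- conv_par(cin, p$bottleneck_filters)
    params[[sprintf("p%d_bot_c2", i)]] <-
      conv_par(p$bottleneck_filters, p$bottleneck_filters)
    cin <- total_bottleneck
    for (j in seq_len(p$depth)) {
      f <- p$decoder_filters[j]
      pw <- p$pool_window
      params[[sprintf("p%d_dec%d_up", i, j)]] <-
        list(W = he_uniform(pw * pw * cin, c(cin, pw * pw * f)),
             b = numeric(f))
      skip_f <- p$encoder_filters[p$depth - j + 1]
      params[[sprintf("p%d_dec%d_c1", i, j)]] <- conv_par(f + skip_f, f)
      params[[sprintf("p%d_dec%d_c2", i, j)]] <- conv_par(f, f)
      cin <- f
    }
  }
  hb <- config$input_height %/% config$downsampling_factor
  wb <- config$input_width %/% config$downsampling_factor
  params$ln <- list(g = matrix(1, hb, wb), b = matrix(0, hb, wb))
  out_in <- sum(vapply(config$pathways,
                       function(p) p$decoder_filters[p$depth], numeric(1)))
  params$out <- list(W = he_uniform(out_in, c(out_in, config$num_classes)),
                     b = numeric(config$num_classes))
  params
}

#' Build the multi-path U-Net
#'
#' Assembles and initializes the network described by a configuration: per
#' pathway an encoder (two-conv blocks, max pooling, spatial dropout), a
#' bottleneck conv block; channel-wise concatenation of all pathway
#' bottlenecks followed by cross-channel layer normalization and spatial
#' dropout; per pathway a decoder (transposed convolution with kernel and
#' stride equal to the pooling window, concatenation with the same-resolution
#' encoder skip, conv block, spatial dropout); and a final 1x1 convolution
#' over the concatenated full-resolution pathway outputs, with per-pixel
#' softmax to class probabilities. Convolution weights use He-uniform
#' initialization; layer-norm gain starts at 1 and bias at 0.
#'
#' @param config an [mpunet_config()].
#' @return object of class `multipath_unet` with elements `config`, `params`
#'   (named list of weight arrays) and `bottleneck_size`.
#' @seealso [count_trainable_parameters()], [predict.multipath_unet()],
#'   [train_fold()]
#' @export
build_multipath_unet <- function(config) {
  stopifnot(inherits(config, "mpunet_config"))
  params <- with_seed(config$seed, init_params(config))
  f <- config$downsampling_factor
  structure(list(
    config = config,
    params = params,
    bottleneck_size = c(config$input_height %/% f, config$input_width %/% f)
  ), class = "multipath_unet")
}

#' Count trainable parameters
#'
#' Counts every trainable scalar of the model: convolution and
#' transposed-convolution weights and biases, layer-normalization gains and
#' biases. (Instance normalization carries no trainable parameters.) The
#' count depends only on the configuration, never on the seed.
#'
#' @param model a `multipath_unet`.
#' @return integer count.
#' @export
count_trainable_parameters <- function(model) {
  stopifnot(inherits(model, "multipath_unet"))
  sum(vapply(model$params,
             function(layer) sum(vapply(layer, length, numeric(1))),
             numeric(1)))
}

#' Two-convolution block
#'
#' The elementary block of every pathway: two successive 3x3 stride-1
#' spatial-size-preserving convolutions, each followed by instance
#' normalization and leaky ReLU. Output spatial dimensions equal the input's;
#' the channel count becomes `filters`.
#'
#' @param input feature stack `(H, W, C)` (a matrix is treated as one
#'   channel).
#' @param filters output channel count.
#' @param config an [mpunet_config()] supplying kernel size, leaky slope and
#'   norm epsilon.
#' @param weights optional list with `c1` and `c2` (each `list(W, b)`), e.g.
#'   taken from a built model; freshly initialized from `config$seed` when
#'   omitted.
#' @return feature stack `(H, W, filters)`.
#' @export
conv_block <- function(input, filters, config, weights = NULL) {
  input <- as_stack(input)
  if (any(dim(input)[1:2] < config$conv_kernel))
    stop("conv_block: spatial dimensions smaller than the kernel")
  if (is.null(weights)) {
    k <- config$conv_kernel
    cin <- dim(input)[3]
    weights <- with_seed(config$seed, list(
      c1 = list(W = he_uniform(k * k * cin, c(k * k * cin, filters)),
                b = numeric(filters)),
      c2 = list(W = he_uniform(k * k * filters, c(k * k * filters, filters)),
                b = numeric(filters))))
  }
  conv_block_forward(input, weights$c1, weights$c2, config)$y
}

conv_block_forward <- function(x, w1, w2, config) {
  k <- config$conv_kernel
  z1 <- .cpp_conv2d(x, w1$W, w1$b, k)
  n1 <- instance_norm_forward(z1, config$norm_epsilon)
  a1 <- leaky_relu(n1$y, config$leaky_slope)
  z2 <- .cpp_conv2d(a1, w2$W, w2$b, k)
  n2 <- instance_norm_forward(z2, config$norm_epsilon)
  a2 <- leaky_relu(n2$y, config$leaky_slope)
  list(y = a2, cache = list(x = x, n1 = n1, a1 = a1, n2 = n2))
}

conv_block_backward <- function(cache, w1, w2, gy, config) {
  k <- config$conv_kernel
  g <- leaky_relu_backward(cache$n2$y, gy, config$leaky_slope)
  g <- instance_norm_backward(cache$n2$cache, g)
  b2 <- .cpp_conv2d_backward(cache$a1, w2$W, g, k)
  g <- leaky_relu_backward(cache$n1$y, b2$gx, config$leaky_slope)
  g <- instance_norm_backward(cache$n1$cache, g)
  b1 <- .cpp_conv2d_backward(cache$x, w1$W, g, k)
  list(gx = b1$gx,
       g1 = list(W = b1$gw, b = as.numeric(b1$gb)),
       g2 = list(W = b2$gw, b = as.numeric(b2$gb)))
}

deconv_forward <- function(x, w, config, pool) {
  z <- .cpp_deconv(x, w$W, w$b, pool)
  n <- instance_norm_forward(z, config$norm_epsilon)
  a <- leaky_relu(n$y, config$leaky_slope)
  list(y = a, cache = list(x = x, n = n))
}

deconv_backward <- function(cache, w, gy, config, pool) {
  g <- leaky_relu_backward(cache$n$y, gy, config$leaky_slope)
  g <- instance_norm_backward(cache$n$cache, g)
  b <- .cpp_deconv_backward(cache$x, w$W, g, pool)
  list(gx = b$gx, gw = list(W = b$gw, b = as.numeric(b$gb)))
}

concat_channels <- function(stacks) {
  d <- dim(stacks[[1]])
  chans <- vapply(stacks, function(s) dim(s)[3], numeric(1))
  out <- array(0, c(d[1], d[2], sum(chans)))
  at <- 0L
  for (s in stacks) {
    cs <- dim(s)[3]
    out[, , (at + 1):(at + cs)] <- s
    at <- at + cs
  }
  out
}

split_channels <- function(stack, chans) {
  out <- vector("list", length(chans))
  at <- 0L
  for (i in seq_along(chans)) {
    out[[i]] <- stack[, , (at + 1):(at + chans[i]), drop = FALSE]
    at <- at + chans[i]
  }
  out
}

# Full forward pass for one example. Returns the per-pixel class probability
# array and, when keep_cache, everything backward needs.
forward_mpunet <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  pr <- model$params
  x <- as_stack(x)
  if (dim(x)[1] != cfg$input_height || dim(x)[2] != cfg$input_width ||
      dim(x)[3] != cfg$input_channels)
    stop(sprintf("input is %s but the model expects %dx%dx%d",
                 paste(dim(x), collapse = "x"),
                 cfg$input_height, cfg$input_width, cfg$input_channels))
  np <- length(cfg$pathways)
  enc_caches <- skips <- dec_caches <- vector("list", np)
  bottlenecks <- vector("list", np)
  rate <- cfg$dropout_rate

  for (i in seq_len(np)) {
    p <- cfg$pathways[[i]]
    cur <- x
    ec <- vector("list", p$depth)
    sk <- vector("list", p$depth)
    for (j in seq_len(p$depth)) {
      cb <- conv_block_forward(cur, pr[[sprintf("p%d_enc%d_c1", i, j)]],
                               pr[[sprintf("p%d_enc%d_c2", i, j)]], cfg)
      sk[[j]] <- cb$y
      mp <- .cpp_maxpool(cb$y, p$pool_window)
      dp <- spatial_dropout_forward(mp$y, rate, training)
      ec[[j]] <- list(cb = cb$cache, mp_idx = mp$idx,
                      mp_in_dim = dim(cb$y), dp = dp$cache)
      cur <- dp$y
    }
    bt <- conv_block_forward(cur, pr[[sprintf("p%d_bot_c1", i)]],
                             pr[[sprintf("p%d_bot_c2", i)]], cfg)
    bottlenecks[[i]] <- bt$y
    enc_caches[[i]] <- list(levels = ec, bot = bt$cache)
    skips[[i]] <- sk
  }

  bott_chans <- vapply(bottlenecks, function(s) dim(s)[3], numeric(1))
  stack <- concat_channels(bottlenecks)
  ln <- interconnect_layer_norm_forward(stack, pr$ln$g, pr$ln$b,
                                        cfg$norm_epsilon)
  bdp <- spatial_dropout_forward(ln$y, rate, training)
  shared <- bdp$y

  outs <- vector("list", np)
  for (i in seq_len(np)) {
    p <- cfg$pathways[[i]]
    cur <- shared
    dc <- vector("list", p$depth)
    for (j in seq_len(p$depth)) {
      up <- deconv_forward(cur, pr[[sprintf("p%d_dec%d_up", i, j)]],
                           cfg, p$pool_window)
      skip <- skips[[i]][[p$depth - j + 1]]
      cat_in <- concat_channels(list(up$y, skip))
      cb <- conv_block_forward(cat_in, pr[[sprintf("p%d_dec%d_c1", i, j)]],
                               pr[[sprintf("p%d_dec%d_c2", i, j)]], cfg)
      dp <- spatial_dropout_forward(cb$y, rate, training)
      dc[[j]] <- list(up = up$cache, up_chan = dim(up$y)[3],
                      cb = cb$cache, dp = dp$cache)
      cur <- dp$y
    }
    outs[[i]] <- cur
    dec_caches[[i]] <- dc
  }

  out_chans <- vapply(outs, function(s) dim(s)[3], numeric(1))
  final <- concat_channels(outs)
  d <- dim(final)
  fm <- matrix(final, d[1] * d[2], d[3])
  logits <- array(sweep(fm %*% pr$out$W, 2, pr$out$b, `+`),
                  c(d[1], d[2], cfg$num_classes))
  prob <- softmax_channels(logits)

  cache <- NULL
  if (keep_cache)
    cache <- list(enc = enc_caches, dec = dec_caches, ln = ln$cache,
                  bdp = bdp$cache, bott_chans = bott_chans,
                  out_chans = out_chans, final_mat = fm, final_dim = d,
                  prob = prob)
  list(prob = prob, logits = logits, cache = cache)
}

# Backward pass from d(loss)/d(logits). Returns grads named like params.
backward_mpunet <- function(model, cache, glogits) {
  cfg <- model$config
  pr <- model$params
  np <- length(cfg$pathways)
  grads <- list()
  d <- cache$final_dim
  gl <- matrix(glogits, d[1] * d[2], cfg$num_classes)
  grads$out <- list(W = crossprod(cache$final_mat, gl),
                    b = colSums(gl))
  gfinal <- array(gl %*% t(pr$out$W), d)
  gouts <- split_channels(gfinal, cache$out_chans)

  gshared_total <- 0
  for (i in seq_len(np)) {
    p <- cfg$pathways[[i]]
    g <- gouts[[i]]
    gskips <- vector("list", p$depth)
    for (j in rev(seq_len(p$depth))) {
      dcj <- cache$dec[[i]][[j]]
      g <- spatial_dropout_backward(dcj$dp, g)
      cb <- conv_block_backward(dcj$cb, pr[[sprintf("p%d_dec%d_c1", i, j)]],
                                pr[[sprintf("p%d_dec%d_c2", i, j)]], g, cfg)
      grads[[sprintf("p%d_dec%d_c1", i, j)]] <- cb$g1
      grads[[sprintf("p%d_dec%d_c2", i, j)]] <- cb$g2
      parts <- split_channels(cb$gx, c(dcj$up_chan,
                                       dim(cb$gx)[3] - dcj$up_chan))
      gskips[[p$depth - j + 1]] <- parts[[2]]
      up <- deconv_backward(dcj$up, pr[[sprintf("p%d_dec%d_up", i, j)]],
                            parts[[1]], cfg, p$pool_window)
      grads[[sprintf("p%d_dec%d_up", i, j)]] <- up$gw
      g <- up$gx
    }
    gshared_total <- gshared_total + g
    cache$enc[[i]]$gskips <- gskips
    cache$enc[[i]]$.keep <- TRUE
  }

  g <- spatial_dropout_backward(cache$bdp, gshared_total)
  ln <- interconnect_layer_norm_backward(cache$ln, g)
  grads$ln <- list(g = ln$gg, b = ln$gb)
  gbots <- split_channels(ln$gx, cache$bott_chans)

  for (i in seq_len(np)) {
    p <- cfg$pathways[[i]]
    ecs <- cache$enc[[i]]
    bt <- conv_block_backward(ecs$bot, pr[[sprintf("p%d_bot_c1", i)]],
                              pr[[sprintf("p%d_bot_c2", i)]], gbots[[i]], cfg)
    grads[[sprintf("p%d_bot_c1", i)]] <- bt$g1
    grads[[sprintf("p%d_bot_c2", i)]] <- bt$g2
    g <- bt$gx
    for (j in rev(seq_len(p$depth))) {
      lv <- ecs$levels[[j]]
      g <- spatial_dropout_backward(lv$dp, g)
      g <- .cpp_maxpool_backward(lv$mp_idx, g, lv$mp_in_dim[1],
                                 lv$mp_in_dim[2])
      g <- g + ecs$gskips[[j]]  # skip connection contributes at this level
      cb <- conv_block_backward(lv$cb, pr[[sprintf("p%d_enc%d_c1", i, j)]],
                                pr[[sprintf("p%d_enc%d_c2", i, j)]], g, cfg)
      grads[[sprintf("p%d_enc%d_c1", i, j)]] <- cb$g1
      grads[[sprintf("p%d_enc%d_c2", i, j)]] <- cb$g2
      g <- cb$gx
    }
  }
  grads
}

#' Binarize a probability map
#'
#' Per-pixel foreground where the foreground probability strictly exceeds the
#' threshold; ties go to background.
#'
#' @param probabilities `(H, W, num_classes)` probability array (channel 2 is
#'   foreground) or an `H x W` matrix of foreground probabilities.
#' @param threshold decision threshold in (0, 1); default 0.5.
#' @return integer `H x W` matrix with values 0 (background) / 1 (foreground).
#' @export
predict_mask <- function(probabilities, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  fg <- if (is.matrix(probabilities)) probabilities else probabilities[, , 2]
  m <- matrix(0L, nrow(fg), ncol(fg))
  m[fg > threshold] <- 1L
  m
}

#' @export
print.multipath_unet <- function(x, ...) {
  n <- count_trainable_parameters(x)
  cat(sprintf("Multi-path U-Net: %d pathway(s), %s trainable parameters (%.2f M)\n",
              length(x$config$pathways), format(n, big.mark = ","), n / 1e6))
  cat(sprintf("  input %dx%dx%d -> bottleneck %dx%d -> %d classes\n",
              x$config$input_height, x$config$input_width,
              x$config$input_channels, x$bottleneck_size[1],
              x$bottleneck_size[2], x$config$num_classes))
  invisible(x)
}

#' Per-layer summary of a multi-path U-Net
#'
#' @param object a `multipath_unet`.
#' @param ... unused.
#' @return data frame (class `summary.multipath_unet`) with one row per
#'   parameterized layer: name, weight shape and parameter count.
#' @export
summary.multipath_unet <- function(object, ...) {
  rows <- lapply(names(object$params), function(nm) {
    layer <- object$params[[nm]]
    shapes <- vapply(layer, function(a) {
      paste(if (is.null(dim(a))) length(a) else dim(a), collapse = "x")
    }, character(1))
    data.frame(layer = nm,
               shapes = paste(paste0(names(layer), ":", shapes),
                              collapse = " "),
               n_params = sum(vapply(layer, length, numeric(1))))
  })
  out <- do.call(rbind, rows)
  attr(out, "total") <- sum(out$n_params)
  class(out) <- c("summary.multipath_unet", "data.frame")
  out
}

#' @export
print.summary.multipath_unet <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  total <- attr(x, "total")
  cat(sprintf("Total trainable parameters: %s (%.2f M)\n",
              format(total, big.mark = ","), total / 1e6))
  invisible(x)
}

#' @export
coef.multipath_unet <- function(object, ...) object$params

#' Segment new images with a multi-path U-Net
#'
#' @param object a `multipath_unet` (typically after training).
#' @param newdata one image array `(H, W, C)` / matrix, or a list of them;
#'   spatial dimensions must match the configuration.
#' @param type `"prob"` for per-pixel class probabilities, `"mask"` for a
#'   thresholded binary mask.
#' @param threshold foreground threshold for `type = "mask"`.
#' @param ... unused.
#' @return a probability array / mask matrix, or a list thereof when
#'   `newdata` is a list.
#' @export
predict.multipath_unet <- function(object, newdata, type = c("prob", "mask"),
                                   threshold = 0.5, ...) {
  type <- match.arg(type)
  one <- function(x) {
    prob <- forward_mpunet(object, x, training = FALSE)$prob
    if (type == "mask") predict_mask(prob, threshold) else prob
  }
  if (is.list(newdata)) lapply(newdata, one) else one(newdata)
}
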