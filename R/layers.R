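# Layer primitives. A feature stack is a numeric array with dim (H, W, C) for
# one example; batches are lists of such arrays. Each *_forward returns
# list(y, cache); each *_backward consumes the cache and the upstream gradient.

as_stack <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x
}

#' Leaky rectified linear activation
#'
#' Elementwise `x` for positive inputs and `slope * x` for negative inputs.
#'
#' @param x numeric array.
#' @param slope negative-side slope in (0, 1); the architecture default is 0.1.
#' @return array of the same shape.
#' @export
leaky_relu <- function(x, slope = 0.1) {
  x * (slope + (1 - slope) * (x > 0))
}

leaky_relu_backward <- function(x, gy, slope = 0.1) {
  gy * (slope + (1 - slope) * (x > 0))
}

# Instance normalization: each channel of each example is standardized by its
# own spatial mean and population variance. Carries no trainable parameters.
instance_norm_forward <- function(x, eps = 1e-5) {
  d <- dim(x)
  hw <- d[1] * d[2]
  m <- matrix(x, hw, d[3])
  mu <- colMeans(m)
  xc <- m - rep(mu, each = hw)
  v <- colMeans(xc * xc)
  inv_std <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv_std, each = hw)
  y <- array(xhat, d)
  list(y = y, cache = list(xhat = xhat, inv_std = inv_std, d = d))
}

instance_norm_backward <- function(cache, gy) {
  d <- cache$d
  hw <- d[1] * d[2]
  g <- matrix(gy, hw, d[3])
  xhat <- cache$xhat
  gm <- colMeans(g)
  gxm <- colMeans(g * xhat)
  gx <- (g - rep(gm, each = hw) - xhat * rep(gxm, each = hw)) *
    rep(cache$inv_std, each = hw)
  array(gx, d)
}

#' Cross-channel layer normalization of a concatenated feature stack
#'
#' Normalizes a feature stack across its channel axis: at each spatial
#' position of each example, the mean and the mean squared deviation are taken
#' over all channels (the concatenated pathway feature maps), and the
#' standardized values are rescaled by a learned per-position gain `g` and
#' shifted by a learned per-position bias `b`. `g` and `b` have the spatial
#' dimensions of a single feature map and broadcast over examples and
#' channels. No statistic is shared between examples.
#'
#' @param stack numeric array `(H, W, C)`: one example's concatenated
#'   bottleneck feature maps.
#' @param g,b numeric `H x W` matrices (gain and bias).
#' @param eps small positive stabilizer added to the variance.
#' @return array of the same shape as `stack`.
#' @export
interconnect_layer_norm <- function(stack, g, b, eps = 1e-5) {
  interconnect_layer_norm_forward(stack, g, b, eps)$y
}

interconnect_layer_norm_forward <- function(stack, g, b, eps = 1e-5) {
  stack <- as_stack(stack)
  d <- dim(stack)
  if (!is.matrix(g)) g <- matrix(g, d[1], d[2])
  if (!is.matrix(b)) b <- matrix(b, d[1], d[2])
  if (!all(dim(g) == d[1:2]) || !all(dim(b) == d[1:2]))
    stop("layer norm: gain/bias spatial shape does not match the stack")
  m <- matrix(stack, d[1] * d[2], d[3])
  mu <- rowMeans(m)
  xc <- m - mu
  v <- rowMeans(xc * xc)
  inv_std <- 1 / sqrt(v + eps)
  xhat <- xc * inv_std
  y <- xhat * as.vector(g) + as.vector(b)
  list(y = array(y, d),
       cache = list(xhat = xhat, inv_std = inv_std, g = as.vector(g), d = d))
}

interconnect_layer_norm_backward <- function(cache, gy) {
  d <- cache$d
  gm <- matrix(gy, d[1] * d[2], d[3])
  xhat <- cache$xhat
  gg <- rowSums(gm * xhat)           # d/dg, per spatial position
  gb <- rowSums(gm)                  # d/db
  gxhat <- gm * cache$g
  gx <- (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat)) *
    cache$inv_std
  list(gx = array(gx, d),
       gg = matrix(gg, d[1], d[2]),
       gb = matrix(gb, d[1], d[2]))
}

#' Spatial (channel-wise) dropout
#'
#' In training mode each whole feature map (channel) is independently zeroed
#' with probability `rate`, and the surviving channels are rescaled by
#' `1 / (1 - rate)` so the expected output equals the input. A dropped
#' channel is zero at every spatial position, which promotes independence
#' between feature maps. In inference mode the input is returned unchanged.
#'
#' @param input numeric array `(H, W, C)`.
#' @param rate drop probability in `[0, 1)`.
#' @param training logical; dropout is only active when `TRUE`.
#' @param seed optional integer seed for the channel mask (the caller's RNG
#'   state is restored afterwards). When `NULL`, the current RNG stream is
#'   used.
#' @return array of the same shape.
#' @export
spatial_dropout <- function(input, rate = 0.1, training = FALSE, seed = NULL) {
  spatial_dropout_forward(input, rate, training, seed)$y
}

spatial_dropout_forward <- function(input, rate, training, seed = NULL) {
  input <- as_stack(input)
  if (!training || rate == 0)
    return(list(y = input, cache = list(mask = NULL)))
  stopifnot(rate >= 0, rate < 1)
  C <- dim(input)[3]
  keep <- if (is.null(seed)) rbinom(C, 1L, 1 - rate) else
    with_seed(seed, rbinom(C, 1L, 1 - rate))
  scale <- keep / (1 - rate)
  y <- input * rep(scale, each = dim(input)[1] * dim(input)[2])
  list(y = y, cache = list(mask = scale))
}

spatial_dropout_backward <- function(cache, gy) {
  if (is.null(cache$mask)) return(gy)
  gy * rep(cache$mask, each = dim(gy)[1] * dim(gy)[2])
}

# Softmax over the channel (class) axis, numerically stabilized.
softmax_channels <- function(z) {
  d <- dim(z)
  m <- matrix(z, d[1] * d[2], d[3])
  mx <- m[, 1]
  for (j in seq_len(d[3])[-1]) mx <- pmax(mx, m[, j])
  e <- exp(m - mx)
  array(e / rowSums(e), d)
}
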