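# Input pipeline: PNG/TIFF loading, Gaussian-smoothed rescale to the network
# input size, per-image z-scoring. All deterministic.

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable anti-aliasing blur with per-axis sigma (EBImage::filter2 with 1-D
# kernels, replicate boundary). sigma of 0 skips the corresponding axis.
blur_anisotropic <- function(m, sigma_row, sigma_col) {
  img <- EBImage::Image(m)
  if (sigma_row > 0) {
    k <- gaussian_kernel_1d(sigma_row)
    img <- EBImage::filter2(img, matrix(k, ncol = 1), boundary = "replicate")
  }
  if (sigma_col > 0) {
    k <- gaussian_kernel_1d(sigma_col)
    img <- EBImage::filter2(img, matrix(k, nrow = 1), boundary = "replicate")
  }
  EBImage::imageData(img)
}

#' Rescale an image with Gaussian anti-aliasing
#'
#' Rescales to `target x target` pixels. When an axis is shrunk by factor
#' `s > 1`, a Gaussian blur with `sigma = s / 3` along that axis is applied
#' first (anti-aliasing); upscaled axes are not blurred. Interpolation is
#' bilinear and each channel is processed identically. Non-square inputs are
#' resized anisotropically. Binary masks must instead be resized with
#' [resize_mask()], which uses nearest-neighbor sampling and preserves
#' binarity.
#'
#' @param image numeric matrix `(H, W)` or array `(H, W, C)` with `C` in
#'   `{1, 3}`.
#' @param target output side length in pixels (>= 8); default 512.
#' @return real-valued array `target x target x C` (matrix input returns
#'   `C = 1`).
#' @export
resize_with_gaussian_smoothing <- function(image, target = 512L) {
  stopifnot(target >= 8)
  image <- as_stack(image * 1.0)
  C <- dim(image)[3]
  if (!C %in% c(1L, 3L)) stop("unsupported channel count: ", C)
  s_row <- dim(image)[1] / target
  s_col <- dim(image)[2] / target
  out <- array(0, c(target, target, C))
  for (c in seq_len(C)) {
    m <- image[, , c]
    m <- blur_anisotropic(m,
                          if (s_row > 1) s_row / 3 else 0,
                          if (s_col > 1) s_col / 3 else 0)
    out[, , c] <- EBImage::imageData(
      EBImage::resize(EBImage::Image(m), w = target, h = target,
                      filter = "bilinear"))
  }
  out
}

#' Resize a binary mask with nearest-neighbor sampling
#'
#' @param mask binary matrix.
#' @param target output side length.
#' @return integer binary matrix `target x target`; binarity is preserved
#'   exactly.
#' @export
resize_mask <- function(mask, target = 512L) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  out <- EBImage::imageData(
    EBImage::resize(EBImage::Image(mask * 1.0), w = target, h = target,
                    filter = "none"))
  storage.mode(out) <- "integer"
  out
}

#' Per-image z-score normalization
#'
#' Standardizes with one mean and one population standard deviation taken
#' over all pixels and channels: `(x - mean) / (sd + 1e-8)`. A constant image
#' maps to all zeros through the epsilon guard. Z-scoring is scale-free, so
#' 8-bit and 16-bit inputs need no prior rescaling.
#'
#' @param image real-valued matrix or array.
#' @return array of the same shape with mean ~0 and standard deviation ~1
#'   (for non-constant input).
#' @export
zscore_normalize <- function(image) {
  stopifnot(length(image) > 0)
  x <- as_stack(image * 1.0)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))   # population sd
  (x - mu) / (sigma + 1e-8)
}

#' Full input preprocessing
#'
#' [resize_with_gaussian_smoothing()] followed by [zscore_normalize()]: the
#' standard transform applied to every image before it enters the network.
#'
#' @inheritParams resize_with_gaussian_smoothing
#' @return normalized `target x target x C` array.
#' @export
preprocess_image <- function(image, target = 512L) {
  zscore_normalize(resize_with_gaussian_smoothing(image, target))
}

read_image_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    info <- attr(x, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    x <- x * (2^depth - 1)
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE)
  } else stop("unsupported image format: ", ext)
  x <- round(x)
  if (length(dim(x)) == 3 && dim(x)[3] == 4) x <- x[, , 1:3]  # drop alpha
  if (length(dim(x)) == 3 && dim(x)[3] == 2) x <- x[, , 1]    # drop gray alpha
  if (length(dim(x)) == 3 && !dim(x)[3] %in% c(1, 3))
    stop("unsupported channel count: ", dim(x)[3])
  x
}

#' Load a paired image and segmentation mask
#'
#' Reads a PNG or TIFF image (8-bit RGB or gray, or 16-bit gray) with its
#' mask file; any nonzero mask label is binarized to foreground. The mask
#' must have the image's spatial dimensions.
#'
#' @param image_path,mask_path file paths (PNG or TIFF).
#' @return list with `image` (integer-valued array, native scale) and `mask`
#'   (integer binary matrix).
#' @export
load_pair <- function(image_path, mask_path) {
  img <- read_image_file(image_path)
  msk <- read_image_file(mask_path)
  if (length(dim(msk)) == 3) msk <- msk[, , 1]
  img_dims <- dim(as_stack(img))[1:2]
  if (!is.matrix(msk) || !all(dim(msk) == img_dims))
    stop(sprintf("mask dimensions (%s) do not match image (%s)",
                 paste(dim(msk), collapse = "x"),
                 paste(img_dims, collapse = "x")))
  mask <- matrix(0L, nrow(msk), ncol(msk))
  mask[msk != 0] <- 1L
  list(image = img, mask = mask)
}

#' Load a generated dataset directory
#'
#' Reads the `images/`, `masks/` and `counts.csv` layout written by
#' [generate_dataset()].
#'
#' @param dir dataset directory.
#' @return list with `images`, `masks` (lists, manifest order) and `manifest`
#'   (data frame with `id`, `true_count`).
#' @export
load_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "counts.csv"), stringsAsFactors = FALSE)
  pairs <- lapply(manifest$id, function(id)
    load_pair(file.path(dir, "images", paste0(id, ".png")),
              file.path(dir, "masks", paste0(id, ".png"))))
  list(images = lapply(pairs, `[[`, "image"),
       masks = lapply(pairs, `[[`, "mask"),
       manifest = manifest)
}
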