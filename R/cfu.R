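# Colony-forming-unit quantification on binary segmentation masks:
# connected-component counting, count MAE, the 3-interval food-safety
# binning and fine-grained equal-width binning with per-bin accuracy.

#' Count connected foreground components
#'
#' Counts maximal connected foreground regions of a binary mask under 4- or
#' 8-connectivity. A colony touching another only diagonally is one colony
#' under 8-connectivity (the default) and two under 4-connectivity.
#'
#' @param mask binary matrix (0 background, 1 foreground).
#' @param connectivity 4 or 8.
#' @param min_size optional minimum component area in pixels; smaller
#'   components are ignored. Off (0) by default: very small colonies are the
#'   hard and interesting cases, so nothing is filtered unless asked.
#' @return nonnegative integer component count.
#' @export
count_components <- function(mask, connectivity = 8L, min_size = 0L) {
  stopifnot(is.matrix(mask))
  if (!all(mask %in% c(0, 1))) stop("count_components: mask is not binary")
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  lab <- .cpp_label_components(m, as.integer(connectivity))
  n <- attr(lab, "n_components")
  if (min_size > 0 && n > 0) {
    sizes <- tabulate(lab[lab > 0], n)
    n <- sum(sizes >= min_size)
  }
  n
}

#' Label connected foreground components
#'
#' @inheritParams count_components
#' @return integer matrix of component labels (0 = background), with
#'   attribute `n_components`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  .cpp_label_components(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                        as.integer(connectivity))
}

#' Count-interval binning scheme
#'
#' Defines half-open count intervals `[e_i, e_{i+1})`, the last extending to
#' infinity, jointly covering `[0, Inf)`. Bin indices are 0-based.
#'
#' @param edges strictly increasing nonnegative thresholds starting at 0.
#' @return object of class `bin_scheme`.
#' @export
bin_scheme <- function(edges) {
  stopifnot(length(edges) >= 1, edges[1] == 0, !is.unsorted(edges, strictly = TRUE))
  structure(list(edges = as.numeric(edges), n_bins = length(edges)),
            class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  e <- x$edges
  iv <- c(sprintf("[%g,%g)", e[-length(e)], e[-1]),
          sprintf("[%g,Inf)", e[length(e)]))
  cat(sprintf("Bin scheme with %d interval(s): %s\n", x$n_bins,
              paste(iv, collapse = " ")))
  invisible(x)
}

#' The 3-interval food-safety binning scheme
#'
#' Intervals `[0, 40)`, `[40, 300)` and `[300, Inf)`, the conventional
#' contamination grading of plate counts in food-safety practice.
#'
#' @return a [bin_scheme()].
#' @export
bin3_scheme <- function() bin_scheme(c(0, 40, 300))

#' Assign counts to bins
#'
#' @param count nonnegative count vector.
#' @param scheme a [bin_scheme()].
#' @return integer bin indices, 0-based.
#' @export
assign_bin <- function(count, scheme = bin3_scheme()) {
  stopifnot(all(count >= 0))
  findInterval(count, scheme$edges) - 1L
}

#' Three-interval bin of a CFU count
#'
#' 0 for counts in `[0, 40)`, 1 for `[40, 300)`, 2 for `[300, Inf)`.
#'
#' @param count nonnegative count vector.
#' @return integer vector with values in `{0, 1, 2}`.
#' @examples
#' bin3(c(0, 39, 40, 299, 300)) # 0 0 1 1 2
#' @export
bin3 <- function(count) assign_bin(count, bin3_scheme())

#' Equal-width binning scheme
#'
#' `n_bins` equal-width half-open intervals spanning `[0, max_count)`, the
#' final interval extended to infinity. With `max_count = 400` and 20 bins
#' the intervals are `[0,20), [20,40), ...`.
#'
#' @param max_count upper count range (>= n_bins).
#' @param n_bins number of bins.
#' @return a [bin_scheme()].
#' @export
make_equal_bins <- function(max_count, n_bins = 20L) {
  stopifnot(max_count >= n_bins, n_bins >= 1)
  bin_scheme(seq(0, max_count, length.out = n_bins + 1)[seq_len(n_bins)])
}

#' Per-image CFU records
#'
#' Tabulates predicted and true colony counts per image together with their
#' 3-interval bins and, when a fine scheme is supplied, fine-grained bins.
#'
#' @param id image identifiers.
#' @param predicted_count,true_count nonnegative integer vectors.
#' @param fine_scheme optional [bin_scheme()] for fine binning; when `NULL`,
#'   an equal-width 20-bin scheme spanning the maximum true count is built
#'   (requires `max(true_count) >= 20`).
#' @return data frame of class `cfu_records` with bin columns; the active
#'   fine scheme is stored in the `fine_scheme` attribute.
#' @export
cfu_records <- function(id, predicted_count, true_count, fine_scheme = NULL) {
  stopifnot(length(predicted_count) == length(true_count),
            all(predicted_count >= 0), all(true_count >= 0))
  if (missing(id) || is.null(id)) id <- seq_along(true_count)
  if (is.null(fine_scheme))
    fine_scheme <- make_equal_bins(max(max(true_count), 20L), 20L)
  out <- data.frame(
    id = id,
    predicted_count = as.integer(predicted_count),
    true_count = as.integer(true_count),
    predicted_bin3 = bin3(predicted_count),
    true_bin3 = bin3(true_count),
    predicted_bin_fine = assign_bin(predicted_count, fine_scheme),
    true_bin_fine = assign_bin(true_count, fine_scheme),
    stringsAsFactors = FALSE)
  attr(out, "fine_scheme") <- fine_scheme
  class(out) <- c("cfu_records", "data.frame")
  out
}

#' Mean absolute error of CFU counts
#'
#' Mean over images of `|predicted - true|`.
#'
#' @param records a [cfu_records()] data frame, or a vector of predicted
#'   counts.
#' @param true_count true counts when `records` is a plain vector.
#' @return nonnegative MAE.
#' @export
count_mae <- function(records, true_count = NULL) {
  if (inherits(records, "cfu_records")) {
    p <- records$predicted_count; t <- records$true_count
  } else {
    p <- records; t <- true_count
  }
  stopifnot(length(p) >= 1, length(p) == length(t))
  mean(abs(p - t))
}

#' Binning accuracy of CFU counts
#'
#' Overall accuracy is the fraction of images whose predicted bin equals the
#' true bin under `scheme`; per-bin accuracy groups images by their TRUE bin.
#' Bins with no images are reported as `NA`.
#'
#' @param records a [cfu_records()] data frame.
#' @param scheme a [bin_scheme()]; defaults to the 3-interval scheme.
#' @return list with `overall` (accuracy in `[0, 1]`) and `per_bin` (data
#'   frame: bin index, n, accuracy).
#' @export
binned_accuracy <- function(records, scheme = bin3_scheme()) {
  stopifnot(inherits(records, "data.frame"), nrow(records) >= 1)
  pb <- assign_bin(records$predicted_count, scheme)
  tb <- assign_bin(records$true_count, scheme)
  hit <- pb == tb
  per <- data.frame(bin = seq_len(scheme$n_bins) - 1L)
  per$n <- vapply(per$bin, function(b) sum(tb == b), numeric(1))
  per$accuracy <- vapply(per$bin, function(b)
    if (any(tb == b)) mean(hit[tb == b]) else NA_real_, numeric(1))
  list(overall = mean(hit), per_bin = per)
}

#' Segment and count colonies on a set of images
#'
#' Applies a trained model to each image, binarizes at the threshold, counts
#' 8-connected components, and tabulates them against the true counts.
#'
#' @param model a trained `multipath_unet`.
#' @param images list of preprocessed input arrays.
#' @param true_count true colony counts (same length).
#' @param threshold foreground threshold.
#' @param connectivity component connectivity (4 or 8).
#' @param ... passed to [cfu_records()].
#' @return a [cfu_records()] data frame.
#' @export
count_cfu <- function(model, images, true_count, threshold = 0.5,
                      connectivity = 8L, ...) {
  pred <- vapply(images, function(x) {
    mask <- predict(model, x, type = "mask", threshold = threshold)
    count_components(mask, connectivity)
  }, numeric(1))
  cfu_records(seq_along(images), pred, true_count, ...)
}
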