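# Deterministic generator of agar-plate-like and cell-like scenes with exact
# ground-truth masks and known colony counts. The scenes emulate the
# phenomena that make real plate imagery hard -- small low-contrast colonies,
# background texture, pen captions and specular reflections -- without any
# claim of matching a real dataset's statistics.

#' Specification of a synthetic scene
#'
#' @param height,width scene size in pixels.
#' @param n_colonies number of colonies (or cells) to place.
#' @param radius_range `c(min, max)` colony radius in pixels (min >= 1).
#' @param intensity_contrast colony-to-background contrast in (0, 1].
#' @param background_texture_scale amplitude of the low-frequency background
#'   texture (0 disables it).
#' @param artifacts logical flags `c(text_glyphs = , specular_highlight = )`;
#'   artifact pixels alter the image but never the mask.
#' @param allow_overlap allow colonies to overlap (when `FALSE`, placement is
#'   rejection-sampled to keep all colonies disjoint, so the mask's
#'   8-connected component count equals `n_colonies`).
#' @param colony_darker render colonies darker than the background instead of
#'   lighter (real plates vary both ways).
#' @param channels 1 (grayscale) or 3 (RGB).
#' @param seed integer seed; scenes are bit-identical for identical spec.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(height = 128L, width = 128L, n_colonies = 20L,
                       radius_range = c(3, 8), intensity_contrast = 0.6,
                       background_texture_scale = 0.08,
                       artifacts = c(text_glyphs = FALSE,
                                     specular_highlight = FALSE),
                       allow_overlap = FALSE, colony_darker = FALSE,
                       channels = 1L, seed = 1L) {
  stopifnot(height >= 16, width >= 16, n_colonies >= 0,
            length(radius_range) == 2, radius_range[1] >= 1,
            radius_range[2] >= radius_range[1],
            intensity_contrast > 0, intensity_contrast <= 1,
            background_texture_scale >= 0, channels %in% c(1L, 3L))
  arts <- c(text_glyphs = FALSE, specular_highlight = FALSE)
  arts[names(artifacts)] <- as.logical(artifacts)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_colonies = as.integer(n_colonies),
                 radius_range = radius_range,
                 intensity_contrast = intensity_contrast,
                 background_texture_scale = background_texture_scale,
                 artifacts = arts, allow_overlap = isTRUE(allow_overlap),
                 colony_darker = isTRUE(colony_darker),
                 channels = as.integer(channels), seed = as.integer(seed)),
            class = "scene_spec")
}

# Low-frequency texture: blurred white noise, zero-mean, unit peak scale.
smooth_noise <- function(h, w, sigma = 8) {
  n <- matrix(rnorm(h * w), h, w)
  n <- blur_anisotropic(n, sigma, sigma)
  n / max(abs(n), 1e-12)
}

# Sample disjoint (or free) colony centers/radii inside the plate disc.
place_colonies <- function(spec, plate_center, plate_radius) {
  n <- spec$n_colonies
  centers <- matrix(0, n, 2)
  radii <- numeric(n)
  attempts <- 0L
  max_attempts <- 300L * max(n, 1L)
  placed <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("colony placement failed: scene too crowded for disjoint colonies")
    r <- runif(1, spec$radius_range[1], spec$radius_range[2])
    ang <- runif(1, 0, 2 * pi)
    rad <- sqrt(runif(1)) * (plate_radius - r - 2)
    cy <- plate_center[1] + rad * sin(ang)
    cx <- plate_center[2] + rad * cos(ang)
    if (!spec$allow_overlap && placed > 0) {
      d <- sqrt((centers[seq_len(placed), 1] - cy)^2 +
                (centers[seq_len(placed), 2] - cx)^2)
      if (any(d <= radii[seq_len(placed)] + r + 2)) next
    }
    placed <- placed + 1L
    centers[placed, ] <- c(cy, cx)
    radii[placed] <- r
  }
  list(centers = centers, radii = radii)
}

# Stamp one rounded shape: adds intensity with a smooth falloff and sets mask
# pixels within the boundary. boundary_r(theta) gives the angle-dependent
# radius (constant for a disk).
stamp_shape <- function(img, mask, cy, cx, boundary_r, amplitude) {
  h <- nrow(img); w <- ncol(img)
  rmax <- max(boundary_r(seq(0, 2 * pi, length.out = 64)))
  i0 <- max(1, floor(cy - rmax - 1)); i1 <- min(h, ceiling(cy + rmax + 1))
  j0 <- max(1, floor(cx - rmax - 1)); j1 <- min(w, ceiling(cx + rmax + 1))
  if (i0 > i1 || j0 > j1) return(list(img = img, mask = mask))
  ii <- i0:i1; jj <- j0:j1
  dy <- outer(ii - cy, rep(1, length(jj)))
  dx <- outer(rep(1, length(ii)), jj - cx)
  dist <- sqrt(dy^2 + dx^2)
  theta <- atan2(dy, dx)
  rb <- matrix(boundary_r(theta), nrow(dist), ncol(dist))
  inside <- dist <= rb
  # cosine taper from 0.6 r to r gives colonies a soft rim
  taper <- pmin(pmax((rb - dist) / (0.4 * rb), 0), 1)
  fall <- ifelse(taper >= 1, 1, 0.5 * (1 - cos(pi * taper)))
  img[ii, jj] <- img[ii, jj] + amplitude * fall
  mask[ii, jj][inside] <- 1L
  list(img = img, mask = mask)
}

stamp_glyphs <- function(img, plate_center, plate_radius, n_glyphs = 3L) {
  h <- nrow(img); w <- ncol(img)
  for (g in seq_len(n_glyphs)) {
    # short dark pen strokes: a polyline of 2-3 segments
    y <- plate_center[1] + runif(1, -0.6, 0.6) * plate_radius
    x <- plate_center[2] + runif(1, -0.6, 0.6) * plate_radius
    for (s in seq_len(sample(2:3, 1))) {
      ang <- runif(1, 0, 2 * pi)
      len <- runif(1, 6, 14)
      steps <- ceiling(len * 2)
      ys <- y + seq(0, len, length.out = steps) * sin(ang)
      xs <- x + seq(0, len, length.out = steps) * cos(ang)
      for (t in seq_len(steps)) {
        i <- round(ys[t]); j <- round(xs[t])
        if (i >= 2 && i < h && j >= 2 && j < w)
          img[(i - 1):(i + 1), (j - 1):(j + 1)] <-
            img[(i - 1):(i + 1), (j - 1):(j + 1)] - 0.35
      }
      y <- ys[steps]; x <- xs[steps]
    }
  }
  img
}

stamp_specular <- function(img, plate_center, plate_radius) {
  h <- nrow(img); w <- ncol(img)
  cy <- plate_center[1] + runif(1, -0.4, 0.4) * plate_radius
  cx <- plate_center[2] + runif(1, -0.4, 0.4) * plate_radius
  sig <- plate_radius * runif(1, 0.15, 0.3)
  dy <- outer(seq_len(h) - cy, rep(1, w))
  dx <- outer(rep(1, h), seq_len(w) - cx)
  img + 0.3 * exp(-(dy^2 + dx^2) / (2 * sig^2))
}

render_scene <- function(spec, boundary_fun) {
  h <- spec$height; w <- spec$width
  plate_center <- c(h / 2, w / 2)
  plate_radius <- 0.47 * min(h, w)
  with_seed(spec$seed, {
    # plate disc over a dark benchtop
    dy <- outer(seq_len(h) - plate_center[1], rep(1, w))
    dx <- outer(rep(1, h), seq_len(w) - plate_center[2])
    in_plate <- sqrt(dy^2 + dx^2) <= plate_radius
    img <- matrix(0.12, h, w)
    img[in_plate] <- 0.55
    if (spec$background_texture_scale > 0)
      img <- img + spec$background_texture_scale *
        smooth_noise(h, w, sigma = min(h, w) / 12)
    mask <- matrix(0L, h, w)
    pl <- place_colonies(spec, plate_center, plate_radius)
    amp <- spec$intensity_contrast * (if (spec$colony_darker) -1 else 1)
    if (spec$n_colonies > 0) {
      for (ci in seq_len(spec$n_colonies)) {
        bf <- boundary_fun(pl$radii[ci])
        st <- stamp_shape(img, mask, pl$centers[ci, 1], pl$centers[ci, 2],
                          bf, amp)
        img <- st$img; mask <- st$mask
      }
    }
    if (spec$artifacts["text_glyphs"])
      img <- stamp_glyphs(img, plate_center, plate_radius)
    if (spec$artifacts["specular_highlight"])
      img <- stamp_specular(img, plate_center, plate_radius)
    # mild sensor noise, then quantize to 8-bit
    img <- img + 0.01 * matrix(rnorm(h * w), h, w)
    img8 <- matrix(as.integer(pmin(pmax(round(img * 255), 0), 255)), h, w)
    image_out <- if (spec$channels == 3L) {
      arr <- array(0L, c(h, w, 3))
      for (c in 1:3) arr[, , c] <- img8
      arr
    } else img8
    structure(list(image = image_out, mask = mask,
                   true_count = spec$n_colonies,
                   centers = pl$centers, radii = pl$radii, spec = spec),
              class = "synthetic_scene")
  })
}

#' Generate a synthetic agar-plate scene with disk-like colonies
#'
#' Renders a circular plate on a dark background with low-frequency texture
#' and `n_colonies` disk-shaped colonies with a smooth intensity falloff at
#' the rim. Optional artifacts (pen-stroke glyphs and a specular highlight)
#' perturb the image only: they are never foreground in the mask, which makes
#' artifact-robustness fixtures trivial to build. Bit-identical for identical
#' spec (including seed).
#'
#' @param spec a [scene_spec()].
#' @return object of class `synthetic_scene` with `image` (8-bit integer
#'   matrix or array), `mask` (binary matrix), `true_count`, `centers`,
#'   `radii`.
#' @export
generate_cfu_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  render_scene(spec, function(r) function(theta) rep(r, length(theta)))
}

#' Generate a synthetic scene with irregular cell-like shapes
#'
#' As [generate_cfu_scene()], but each object is a randomly oriented,
#' elongated shape whose boundary radius varies smoothly with angle
#' (an ellipse with a low-order sinusoidal perturbation), emulating
#' irregular cell outlines rather than round colonies.
#'
#' @param spec a [scene_spec()].
#' @return a `synthetic_scene`.
#' @export
generate_cell_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  render_scene(spec, function(r) {
    ecc <- runif(1, 0.45, 0.85)       # minor/major axis ratio
    phi <- runif(1, 0, pi)            # orientation
    wob <- runif(1, 0.05, 0.18)       # boundary perturbation amplitude
    wphase <- runif(1, 0, 2 * pi)
    function(theta) {
      a <- r; b <- r * ecc
      base <- a * b / sqrt((b * cos(theta - phi))^2 + (a * sin(theta - phi))^2)
      base * (1 + wob * sin(3 * (theta - phi) + wphase))
    }
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic %s scene: %dx%d, %d object(s)\n",
              if (x$spec$channels == 3) "RGB" else "grayscale",
              x$spec$height, x$spec$width, x$true_count))
  invisible(x)
}

#' @export
plot.synthetic_scene <- function(x, which = c("image", "mask"), ...) {
  which <- match.arg(which)
  m <- if (which == "image") {
    im <- if (is.matrix(x$image)) x$image else x$image[, , 1]
    im / 255
  } else x$mask
  graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(256),
                  asp = 1, axes = FALSE, main = which, ...)
  invisible(x)
}

#' Generate a dataset of scenes on disk
#'
#' Writes `n_images` scenes as 8-bit PNG image/mask pairs under
#' `dir/images` and `dir/masks` (matching file stems) plus a
#' `counts.csv` manifest of true colony counts, the layout [load_dataset()]
#' and [load_pair()] consume. Per-image seeds are derived from `seed`, so the
#' dataset is reproducible and all images are distinct.
#'
#' @param n_images number of scenes.
#' @param template a [scene_spec()] used for every scene (its seed is
#'   replaced per image); colony numbers can vary via `n_colonies_range`.
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @param n_colonies_range optional `c(min, max)`: per-image colony count
#'   drawn uniformly; when `NULL`, the template's count is used everywhere.
#' @param type `"cfu"` (disks) or `"cell"` (irregular shapes).
#' @return the manifest data frame, invisibly.
#' @export
generate_dataset <- function(n_images, template = scene_spec(), dir,
                             seed = 1L, n_colonies_range = NULL,
                             type = c("cfu", "cell")) {
  type <- match.arg(type)
  stopifnot(n_images >= 1)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  draws <- with_seed(seed, list(
    seeds = sample.int(2^30, n_images),
    counts = if (is.null(n_colonies_range)) rep(template$n_colonies, n_images)
             else sample(n_colonies_range[1]:n_colonies_range[2], n_images,
                         replace = TRUE)))
  gen <- if (type == "cfu") generate_cfu_scene else generate_cell_scene
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sp <- template
    sp$seed <- draws$seeds[i]
    sp$n_colonies <- draws$counts[i]
    scene <- gen(sp)
    id <- sprintf("scene_%03d", i)
    img <- if (is.matrix(scene$image)) scene$image / 255 else
      scene$image / 255
    png::writePNG(img, file.path(dir, "images", paste0(id, ".png")))
    png::writePNG(scene$mask * 1.0,
                  file.path(dir, "masks", paste0(id, ".png")))
    rows[[i]] <- data.frame(id = id, true_count = scene$true_count,
                            seed = sp$seed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "counts.csv"), row.names = FALSE)
  invisible(manifest)
}
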