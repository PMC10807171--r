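## Synthetic cell shapes with known geometry.

ellipse_mask <- function(image_size, center, a, b, angle_deg) {
  nr <- image_size[1]; nc <- image_size[2]
  x <- matrix(rep(0:(nc - 1), each = nr), nr)
  y <- matrix(rep(0:(nr - 1), times = nc), nr)
  th <- angle_deg * pi / 180
  dx <- x - center[1]; dy <- y - center[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  ((u / a)^2 + (v / b)^2 <= 1) + 0L
}

# Star-convex blob: radius r(phi) = r0 * (1 + sum_k amp_k cos(k phi + ph_k))
blob_mask <- function(image_size, center, r0, amp, seed_harmonics) {
  nr <- image_size[1]; nc <- image_size[2]
  k <- seq_along(seed_harmonics$phase)
  x <- matrix(rep(0:(nc - 1), each = nr), nr)
  y <- matrix(rep(0:(nr - 1), times = nc), nr)
  dx <- x - center[1]; dy <- y - center[2]
  phi <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  rad <- r0 * (1 + Reduce(`+`, lapply(k, function(kk)
    amp[kk] * cos(kk * phi + seed_harmonics$phase[kk]))))
  (r <= rad) + 0L
}

#' Generate a synthetic cell geometry
#'
#' Draws a binary cell mask (circle, ellipse or irregular star-convex blob)
#' with a concentric nucleus, records the constructed long-axis angle, and
#' returns a [cell_geometry()]. All randomness (blob harmonics) comes from
#' `seed`; identical arguments give bit-identical masks.
#'
#' @param shape `"circle"`, `"ellipse"` or `"blob"`.
#' @param image_size integer `(rows, cols)` of the raster in pixels.
#' @param radius circle/blob base radius in pixels.
#' @param semi_axes `(a, b)` ellipse semi-axes in pixels (`a >= b`).
#' @param angle ellipse rotation in degrees (long-axis angle by construction).
#' @param nucleus_fraction nucleus radius as a fraction of the cell radius.
#' @param irregularity blob boundary modulation amplitude (0 = circle).
#' @param pixel_size micrometres per pixel.
#' @param center shape centre in pixel coordinates; default image centre.
#' @param seed integer seed for the blob harmonics (unused for deterministic
#'   shapes, accepted for a uniform interface).
#'
#' @return A `cell_geometry` whose `long_axis_angle` is the constructed value
#'   (ellipse `angle`, otherwise the measured principal axis).
#' @export
gen_cell_mask <- function(shape = c("circle", "ellipse", "blob"),
                          image_size = c(256, 256),
                          radius = 100, semi_axes = c(100, 50), angle = 0,
                          nucleus_fraction = 0.3, irregularity = 0.15,
                          pixel_size = 0.1, center = NULL, seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(length(image_size) == 2, all(image_size >= 8))
  if (is.null(center)) center <- c((image_size[2] - 1) / 2, (image_size[1] - 1) / 2)

  extent <- switch(shape,
    circle = radius,
    ellipse = max(semi_axes),
    blob = radius * (1 + 2.25 * irregularity))  # max harmonic amplitude sum
  if (center[1] - extent < 0 || center[1] + extent > image_size[2] - 1 ||
      center[2] - extent < 0 || center[2] + extent > image_size[1] - 1)
    stop("shape exceeds image bounds")

  res <- with_seed(seed, {
    cell <- switch(shape,
      circle = ellipse_mask(image_size, center, radius, radius, 0),
      ellipse = ellipse_mask(image_size, center, semi_axes[1], semi_axes[2], angle),
      blob = {
        harm <- list(phase = stats::runif(4, 0, 2 * pi))
        amp <- irregularity * c(1, 0.6, 0.4, 0.25) * stats::runif(4, 0.5, 1)
        blob_mask(image_size, center, radius, amp, harm)
      })
    nuc_r <- nucleus_fraction * switch(shape,
      circle = radius, ellipse = min(semi_axes), blob = radius * 0.8)
    nucleus <- ellipse_mask(image_size, center, nuc_r, nuc_r, 0)
    nucleus[cell == 0] <- 0L
    list(cell = cell, nucleus = nucleus)
  })

  axis_angle <- if (shape == "ellipse") angle %% 180 else NULL
  cell_geometry(res$cell, res$nucleus, pixel_size = pixel_size,
                long_axis_angle = axis_angle)
}
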