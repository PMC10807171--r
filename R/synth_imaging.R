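## Synthetic fluorescence imagery with known ground truth.

# von Mises sampler (Best & Fisher 1979); kappa = 0 falls back to uniform.
rvonmises <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

add_noise <- function(img, noise_sd, noise_model) {
  if (noise_model == "poisson") img <- array(stats::rpois(length(img), pmax(img, 0)),
                                             dim = dim(img))
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
  img
}

#' Generate a z-stack of Gaussian puncta with known ground truth
#'
#' Renders `n` isotropic 2D Gaussian spots at random in-mask positions with a
#' Gaussian axial profile, emulating diffraction-limited plasmalemmal puncta
#' (AQP4 aggregates / plectin microdomains) in a confocal z-stack. Spot
#' centres respect a minimum pairwise distance; noise is additive Gaussian by
#' default with a Poisson photon-noise option.
#'
#' @param geom a [cell_geometry()] giving the cell mask and calibration.
#' @param n number of puncta (>= 0).
#' @param sigma lateral Gaussian SD in pixels.
#' @param amplitude peak intensity per spot.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param z_planes number of z-planes.
#' @param z_step axial spacing in micrometres.
#' @param axial_sigma axial Gaussian SD in planes.
#' @param min_separation minimum pairwise centre distance in pixels.
#' @param noise_model `"gaussian"` or `"poisson"` (Poisson on the signal,
#'   then additive Gaussian).
#' @param max_tries placement attempts per spot before giving up.
#' @param seed integer seed.
#'
#' @return A list with `stack` (an [image_stack()]) and `truth`, a list with
#'   `centers` (n x 3 matrix, x/y/z in micrometres), `centers_px`,
#'   `z_plane`, `sigmas` (px), `amplitudes` and `cell_area` (um^2).
#' @export
gen_puncta_stack <- function(geom, n, sigma = 2, amplitude = 1000,
                             noise_sd = 0, z_planes = 7, z_step = 0.5,
                             axial_sigma = 1, min_separation = 0,
                             noise_model = c("gaussian", "poisson"),
                             max_tries = 2000, seed = NULL) {
  stopifnot(inherits(geom, "cell_geometry"), n >= 0, sigma > 0,
            min_separation >= 0, z_planes >= 1)
  noise_model <- match.arg(noise_model)
  mask <- geom$cell_mask
  nr <- nrow(mask); nc <- ncol(mask)
  in_idx <- which(mask != 0)

  with_seed(seed, {
    centers <- matrix(numeric(0), 0, 2)  # (x, y) px
    tries <- 0L
    while (nrow(centers) < n) {
      if (tries >= max_tries * max(n, 1))
        stop(sprintf("could not place %d puncta at min_separation %.1f px (placed %d)",
                     n, min_separation, nrow(centers)))
      tries <- tries + 1L
      pick <- in_idx[sample.int(length(in_idx), 1L)]
      cand <- c((pick - 1L) %/% nr, (pick - 1L) %% nr) + stats::runif(2, -0.5, 0.5)
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= min_separation)
        centers <- rbind(centers, cand)
    }
    z_mid <- if (z_planes >= 3) sample(2:(z_planes - 1), max(n, 0), replace = TRUE)
             else rep(ceiling(z_planes / 2), max(n, 0))

    vox <- array(0, dim = c(nr, nc, z_planes))
    w <- ceiling(4 * sigma)
    for (i in seq_len(n)) {
      cx <- centers[i, 1]; cy <- centers[i, 2]
      cols <- max(0, floor(cx - w)):min(nc - 1, ceiling(cx + w))
      rows <- max(0, floor(cy - w)):min(nr - 1, ceiling(cy + w))
      g2 <- exp(-outer((rows - cy)^2, (cols - cx)^2, `+`) / (2 * sigma^2))
      for (z in seq_len(z_planes)) {
        az <- exp(-((z - z_mid[i])^2) / (2 * axial_sigma^2))
        if (az < 1e-6) next
        vox[rows + 1, cols + 1, z] <- vox[rows + 1, cols + 1, z] +
          amplitude * az * g2
      }
    }
    vox <- add_noise(vox, noise_sd, noise_model)

    truth <- list(
      centers = if (n > 0) cbind(x = centers[, 1] * geom$pixel_size,
                                 y = centers[, 2] * geom$pixel_size,
                                 z = (z_mid - 1) * z_step)
                else matrix(numeric(0), 0, 3),
      centers_px = centers, z_plane = z_mid,
      sigmas = rep(sigma, n), amplitudes = rep(amplitude, n),
      cell_area = geom$cell_area_um2)
    list(stack = image_stack(vox, pixel_size = geom$pixel_size, z_step = z_step),
         truth = truth)
  })
}

#' Generate an oriented filament texture
#'
#' Renders straight filament segments inside a cell mask with orientations
#' drawn from a von Mises distribution (on doubled angles) about
#' `mean_angle`, and per-filament intensities drawn from a gamma distribution
#' whose shape parameter controls the skewness of the intensity distribution
#' (skewness of a gamma with shape s is 2/sqrt(s)); low shape = few bright
#' bundles over a dim background, emulating filament bundling.
#'
#' @param geom a [cell_geometry()].
#' @param n_filaments number of segments.
#' @param mean_angle mean orientation in degrees (mod 180).
#' @param concentration von Mises concentration; 0 = uniform orientations,
#'   large values collapse onto `mean_angle`.
#' @param width filament width in pixels.
#' @param intensity_skew gamma shape of the per-filament intensity
#'   distribution (smaller = more skewed).
#' @param length_range segment length range in pixels.
#' @param amplitude mean filament intensity.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed.
#'
#' @return A list with `stack` (single-plane [image_stack()]) and `truth`
#'   (orientations in degrees mod 180, lengths px, intensities).
#' @export
gen_filament_image <- function(geom, n_filaments = 100, mean_angle = 0,
                               concentration = 0, width = 2,
                               intensity_skew = 4, length_range = c(20, 60),
                               amplitude = 100, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(geom, "cell_geometry"), concentration >= 0, width > 0)
  mask <- geom$cell_mask
  nr <- nrow(mask); nc <- ncol(mask)
  in_idx <- which(mask != 0)

  with_seed(seed, {
    dev <- rvonmises(n_filaments, concentration) / 2 * 180 / pi
    theta <- (mean_angle + dev) %% 180
    lens <- stats::runif(n_filaments, length_range[1], length_range[2])
    inten <- amplitude * stats::rgamma(n_filaments, shape = intensity_skew,
                                       rate = intensity_skew)
    img <- matrix(0, nr, nc)
    half_w <- width / 2
    for (i in seq_len(n_filaments)) {
      pick <- in_idx[sample.int(length(in_idx), 1L)]
      cx <- (pick - 1L) %/% nr; cy <- (pick - 1L) %% nr
      th <- theta[i] * pi / 180
      ux <- cos(th); uy <- sin(th)
      h <- lens[i] / 2
      x0 <- cx - h * ux; y0 <- cy - h * uy
      x1 <- cx + h * ux; y1 <- cy + h * uy
      cols <- max(0, floor(min(x0, x1) - width)):min(nc - 1, ceiling(max(x0, x1) + width))
      rows <- max(0, floor(min(y0, y1) - width)):min(nr - 1, ceiling(max(y0, y1) + width))
      px <- matrix(rep(cols, each = length(rows)), length(rows))
      py <- matrix(rep(rows, times = length(cols)), length(rows))
      # distance from pixel to segment
      t <- ((px - x0) * ux + (py - y0) * uy) / lens[i]
      t <- pmin(pmax(t, 0), 1)
      d <- sqrt((px - (x0 + t * lens[i] * ux))^2 + (py - (y0 + t * lens[i] * uy))^2)
      hit <- d <= half_w
      sub <- img[rows + 1, cols + 1]
      sub[hit] <- sub[hit] + inten[i]
      img[rows + 1, cols + 1] <- sub
    }
    img[mask == 0] <- 0
    img <- add_noise(img, noise_sd, "gaussian")
    list(stack = image_stack(img, pixel_size = geom$pixel_size, z_step = 0.5),
         truth = list(orientations = theta, lengths = lens, intensities = inten))
  })
}
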