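#' Cell geometry container
#'
#' Bundles a binary cell mask, a binary nucleus mask, the pixel calibration
#' and the orientation of the cell's long axis. This is the geometric context
#' consumed by the region constructors ([subplasmalemmal_band()],
#' [perinuclear_region()]) and by occupancy measurements.
#'
#' @param cell_mask binary matrix (rows = y, cols = x); nonzero = inside cell.
#' @param nucleus_mask binary matrix of the same dimensions; must be a subset
#'   of `cell_mask`. May be `NULL` when no nucleus is defined.
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @param long_axis_angle orientation of the cell long axis in degrees in
#'   `[0, 180)`, measured from the image x-axis. If `NULL` it is computed
#'   from the mask with [long_axis()].
#'
#' @return An object of class `cell_geometry`: a list with elements
#'   `cell_mask`, `nucleus_mask`, `pixel_size`, `long_axis_angle` and
#'   `cell_area_um2`.
#' @export
cell_geometry <- function(cell_mask, nucleus_mask = NULL, pixel_size = 0.1,
                          long_axis_angle = NULL) {
  assert_mask(cell_mask, "cell_mask")
  stopifnot(pixel_size > 0)
  cell_mask <- (cell_mask != 0) + 0L
  if (!is.null(nucleus_mask)) {
    if (!all(dim(nucleus_mask) == dim(cell_mask)))
      stop("nucleus_mask and cell_mask dimensions differ")
    nucleus_mask <- (nucleus_mask != 0) + 0L
    if (any(nucleus_mask > cell_mask))
      stop("nucleus_mask must be contained in cell_mask")
  }
  if (is.null(long_axis_angle)) long_axis_angle <- long_axis(cell_mask)$angle
  structure(list(
    cell_mask = cell_mask,
    nucleus_mask = nucleus_mask,
    pixel_size = pixel_size,
    long_axis_angle = long_axis_angle %% 180,
    cell_area_um2 = mask_area_px(cell_mask) * pixel_size^2
  ), class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "<cell_geometry> %d x %d px, pixel %.4g um, cell %.1f um2, long axis %.1f deg\n",
    nrow(x$cell_mask), ncol(x$cell_mask), x$pixel_size, x$cell_area_um2,
    x$long_axis_angle))
  invisible(x)
}

#' Principal (long) axis of a binary mask
#'
#' Orientation of the principal axis of the pixel-coordinate covariance of a
#' mask, i.e. the direction of maximal spatial extent. Used as the reference
#' axis for filament-orientation statistics.
#'
#' @param mask binary matrix.
#' @return A list with `angle` (degrees in `[0, 180)`, from the x-axis) and
#'   `degenerate` (`TRUE` when the two covariance eigenvalues agree within
#'   1\%, e.g. for a disk, in which case the angle is arbitrary).
#' @export
long_axis <- function(mask) {
  assert_mask(mask)
  idx <- which(mask != 0)
  if (length(idx) < 2L) stop("mask needs at least 2 pixels")
  nr <- nrow(mask)
  y <- (idx - 1L) %% nr     # row - 1
  x <- (idx - 1L) %/% nr    # col - 1
  cv <- stats::cov(cbind(x, y))
  if (all(abs(cv) < .Machine$double.eps))
    stop("mask has zero second moments")
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  angle <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  degenerate <- (e$values[1] - e$values[2]) <= 0.01 * e$values[1]
  list(angle = angle, degenerate = degenerate)
}
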