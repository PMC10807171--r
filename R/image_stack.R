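#' Image stack container
#'
#' A calibrated 3D fluorescence volume: a numeric array indexed
#' `[row (y), col (x), plane (z)]` with lateral pixel size and axial step.
#' Single-plane images are stored as one-plane stacks.
#'
#' @param voxels numeric array `(y, x, z)` or a matrix (promoted to 1 plane).
#' @param pixel_size micrometres per pixel in x/y (> 0).
#' @param z_step axial plane spacing in micrometres (> 0); confocal stacks
#'   here are acquired at 0.5 um intervals, the default.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size = 0.1, z_step = 0.5) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L,
            pixel_size > 0, z_step > 0, dim(voxels)[3] >= 1)
  structure(list(voxels = voxels, pixel_size = pixel_size, z_step = z_step),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d px, %d plane(s), pixel %.4g um, z-step %.4g um\n",
              d[1], d[2], d[3], x$pixel_size, x$z_step))
  invisible(x)
}

#' Maximum- or sum-intensity z-projection
#'
#' @param stack an [image_stack()].
#' @param method `"max"` (default, the merged-stack convention used for
#'   occupancy) or `"sum"`.
#' @return A numeric matrix.
#' @export
z_project <- function(stack, method = c("max", "sum")) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "image_stack"))
  apply(stack$voxels, c(1, 2), if (method == "max") max else sum)
}

#' Write / read a calibrated stack as multi-page TIFF + sidecar JSON
#'
#' The TIFF holds one 16-bit page per z-plane, with intensities mapped
#' linearly onto `[0, 1]`; the sidecar `<path>.json` records pixel size,
#' z-step and the affine intensity mapping (scale, offset) so the stack
#' round-trips to 16-bit precision.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns an [image_stack()].
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mn <- min(stack$voxels)
  scale <- max(max(stack$voxels) - mn, 1e-12)
  pages <- lapply(seq_len(dim(stack$voxels)[3]),
                  function(z) (stack$voxels[, , z] - mn) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size = stack$pixel_size, z_step = stack$z_step,
         scale = scale, offset = mn),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  offset <- if (is.null(meta$offset)) 0 else meta$offset
  vox <- array(unlist(pages),
               dim = c(dim(pages[[1]]), length(pages))) * meta$scale + offset
  image_stack(vox, pixel_size = meta$pixel_size, z_step = meta$z_step)
}
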