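## Cell subregions: subplasmalemmal band and perinuclear zone, plus
## occupancy (percentage of supra-threshold pixels in a region).

# Binary search a threshold on a distance map so that the thresholded area
# hits `target_px` as closely as the discrete distance values allow.
threshold_distmap_to_area <- function(dmap, eligible, target_px, keep_leq) {
  vals <- sort(unique(as.numeric(dmap[eligible])))
  # area as a function of the cut is a step function over `vals`
  areas <- vapply(vals, function(v) {
    if (keep_leq) sum(eligible & dmap <= v) else sum(eligible & dmap > v)
  }, numeric(1))
  best <- which.min(abs(areas - target_px))
  list(cut = vals[best], area = areas[best])
}

#' Shrink a cell outline to a target fractional area
#'
#' Computes an inner mask whose area is `fraction` of the cell area, the
#' virtual "smaller outline (by area)" used to delimit the subplasmalemmal
#' band. Implemented by thresholding the Euclidean distance-to-boundary
#' transform of the mask (equivalent to a morphological erosion with
#' sub-pixel radius selection), which is robust for concave outlines.
#'
#' @param cell_mask binary matrix.
#' @param fraction target area ratio in `(0, 1]`.
#' @param tol acceptable deviation of the achieved ratio (default 0.005).
#' @return A binary matrix (inner mask), a subset of `cell_mask`, with
#'   attribute `achieved_fraction`.
#' @export
shrink_outline <- function(cell_mask, fraction, tol = 0.005) {
  assert_mask(cell_mask, "cell_mask")
  stopifnot(fraction > 0, fraction <= 1)
  cell_mask <- (cell_mask != 0) + 0L
  if (fraction == 1) {
    attr(cell_mask, "achieved_fraction") <- 1
    return(cell_mask)
  }
  area <- mask_area_px(cell_mask)
  dmap <- EBImage::distmap(cell_mask)
  fit <- threshold_distmap_to_area(dmap, cell_mask != 0,
                                   target_px = fraction * area, keep_leq = FALSE)
  achieved <- fit$area / area
  if (abs(achieved - fraction) > tol)
    stop(sprintf(
      "mask too thin to shrink to fraction %.3f (closest achievable %.3f)",
      fraction, achieved))
  inner <- (cell_mask != 0 & dmap > fit$cut) + 0L
  attr(inner, "achieved_fraction") <- achieved
  inner
}

#' Subplasmalemmal band of a cell
#'
#' The annular region between the cell outline and the virtual outline
#' shrunk to `fraction` of the cell area: the band holds `1 - fraction` of
#' the area. Conventional fractions: 0.8 for actin/vimentin filaments and
#' 0.9 for intracellular plectin.
#'
#' @param geom a [cell_geometry()].
#' @param fraction inner-outline area fraction (default 0.8).
#' @return A list of class `region_set` with `band` and `inner` binary masks
#'   (an exact partition of the cell mask), `shrink_fraction` and
#'   `achieved_fraction`.
#' @export
subplasmalemmal_band <- function(geom, fraction = 0.8) {
  stopifnot(inherits(geom, "cell_geometry"))
  inner <- shrink_outline(geom$cell_mask, fraction)
  band <- geom$cell_mask - inner
  structure(list(band = band, inner = inner, shrink_fraction = fraction,
                 achieved_fraction = attr(inner, "achieved_fraction")),
            class = "region_set")
}

#' Perinuclear region of a cell
#'
#' The region of twice the nuclear area including the nucleus, grown
#' outwards from the nucleus by distance (iterative dilation in the limit)
#' and clipped to the cell mask. If clipping prevents reaching twice the
#' nuclear area the maximal achievable region is returned with
#' `clipped = TRUE`.
#'
#' @param geom a [cell_geometry()] with a nonempty nucleus mask.
#' @param tol relative tolerance on the achieved area ratio (default 0.02).
#' @return A binary matrix with attributes `area_ratio` (region area /
#'   nucleus area) and `clipped`.
#' @export
perinuclear_region <- function(geom, tol = 0.02) {
  stopifnot(inherits(geom, "cell_geometry"))
  if (is.null(geom$nucleus_mask) || mask_area_px(geom$nucleus_mask) == 0)
    stop("geometry has no nucleus mask")
  nuc <- geom$nucleus_mask
  cell <- geom$cell_mask
  n_area <- mask_area_px(nuc)
  target <- 2 * n_area
  halo <- cell != 0 & nuc == 0
  if (n_area + sum(halo) < target * (1 - tol)) {
    region <- (cell != 0) + 0L
    attr(region, "area_ratio") <- mask_area_px(region) / n_area
    attr(region, "clipped") <- TRUE
    return(region)
  }
  dmap <- EBImage::distmap((nuc == 0) + 0L)  # distance from the nucleus
  fit <- threshold_distmap_to_area(dmap, halo, target_px = target - n_area,
                                   keep_leq = TRUE)
  region <- (nuc != 0 | (halo & dmap <= fit$cut)) + 0L
  ratio <- mask_area_px(region) / n_area
  clipped <- abs(ratio - 2) > tol * 2
  attr(region, "area_ratio") <- ratio
  attr(region, "clipped") <- clipped
  region
}

#' Occupancy: percentage of supra-threshold pixels in a region
#'
#' The amount of signal (e.g. cytoskeleton) per unit area, expressed as the
#' percentage of pixels above threshold among the pixels of the selected
#' region, computed on a merged (z-projected) image.
#'
#' @param image a numeric matrix or an [image_stack()] (projected first).
#' @param region binary matrix (nonempty).
#' @param threshold intensity threshold, or `"otsu"` (default) for an Otsu
#'   threshold computed on the in-region intensity histogram.
#' @param projection `"max"` (default) or `"sum"`, used when `image` is a
#'   stack.
#' @return Percentage in `[0, 100]`, with attribute `threshold_used`.
#' @export
occupancy <- function(image, region, threshold = "otsu",
                      projection = c("max", "sum")) {
  assert_mask(region, "region")
  if (inherits(image, "image_stack"))
    image <- z_project(image, match.arg(projection))
  stopifnot(all(dim(image) == dim(region)))
  vals <- image[region != 0]
  thr <- if (identical(threshold, "otsu")) otsu_threshold(vals) else threshold
  out <- 100 * sum(vals > thr) / length(vals)
  attr(out, "threshold_used") <- thr
  out
}
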