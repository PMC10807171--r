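## Object-based and pixel-based (Pearson / Manders) colocalization.

#' Object-based colocalization percentage
#'
#' Percentage of objects in set A that share at least one voxel with any
#' object in set B, e.g. the percentage of plasmalemmal AQP4 aggregates
#' colocalized with plectin among all aggregates in the cell.
#'
#' @param setA,setB `puncta_set` objects from [detect_objects()] with label
#'   arrays of identical dimensions.
#' @return Percentage in `[0, 100]`; `NA` with a warning when A is empty.
#' @export
object_colocalization <- function(setA, setB) {
  stopifnot(inherits(setA, "puncta_set"), inherits(setB, "puncta_set"),
            all(dim(setA$labels) == dim(setB$labels)))
  nA <- nrow(setA$objects)
  if (nA == 0) {
    warning("set A has no objects; colocalization undefined")
    return(NA_real_)
  }
  overlap_ids <- unique(setA$labels[setA$labels > 0 & setB$labels > 0])
  100 * length(overlap_ids) / nA
}

#' Pixel-based colocalization coefficients
#'
#' Pearson correlation of in-mask voxel intensities plus Manders overlap
#' coefficients: `M1` is the fraction of channel-A intensity found in voxels
#' where channel B exceeds its threshold, and `M2` symmetrically.
#'
#' @param imgA,imgB [image_stack()] objects (or arrays) of matching shape.
#' @param mask optional binary 2D mask applied to every plane.
#' @param thresholds numeric length-2 `(threshold_A, threshold_B)` or
#'   `"otsu"` (default) for per-channel Otsu within the mask.
#' @return A list with `pearson_r` (`NA` with a warning for a zero-variance
#'   channel), `manders_m1`, `manders_m2`, and `thresholds`.
#' @export
pixel_colocalization <- function(imgA, imgB, mask = NULL, thresholds = "otsu") {
  a <- if (inherits(imgA, "image_stack")) imgA$voxels else imgA
  b <- if (inherits(imgB, "image_stack")) imgB$voxels else imgB
  if (is.matrix(a)) a <- array(a, c(dim(a), 1))
  if (is.matrix(b)) b <- array(b, c(dim(b), 1))
  stopifnot(all(dim(a) == dim(b)))
  sel <- if (is.null(mask)) rep(TRUE, length(a))
         else rep(mask != 0, dim(a)[3])
  va <- as.numeric(a)[sel]; vb <- as.numeric(b)[sel]
  if (identical(thresholds, "otsu"))
    thresholds <- c(otsu_threshold(va), otsu_threshold(vb))
  r <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("zero-variance channel; Pearson undefined")
    NA_real_
  } else stats::cor(va, vb)
  m1 <- if (sum(va) > 0) sum(va[vb > thresholds[2]]) / sum(va) else NA_real_
  m2 <- if (sum(vb) > 0) sum(vb[va > thresholds[1]]) / sum(vb) else NA_real_
  list(pearson_r = r, manders_m1 = m1, manders_m2 = m2,
       thresholds = thresholds)
}
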