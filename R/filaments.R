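## Cytoskeletal architecture metrics: skeleton-based segment orientations
## versus the cell long axis (avgTheta), parallelness (circular mean
## resultant length on doubled angles) and bundling (intensity skewness).

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen binary thinning. Returns a 1-px-wide 8-connected skeleton.
skeletonize_mask <- function(mask) {
  img <- (mask != 0) + 0L
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9: N, NE, E, SE, S, SW, W, NW
      p <- list(
        shift_mat(img, -1, 0), shift_mat(img, -1, 1), shift_mat(img, 0, 1),
        shift_mat(img, 1, 1), shift_mat(img, 1, 0), shift_mat(img, 1, -1),
        shift_mat(img, 0, -1), shift_mat(img, -1, -1))
      B <- Reduce(`+`, p)
      A <- matrix(0L, nrow(img), ncol(img))
      for (k in 1:8) {
        nxt <- p[[if (k == 8) 1 else k + 1]]
        A <- A + (p[[k]] == 0L & nxt == 1L)
      }
      if (step == 1) {
        c1 <- p[[1]] * p[[3]] * p[[5]]
        c2 <- p[[3]] * p[[5]] * p[[7]]
      } else {
        c1 <- p[[1]] * p[[3]] * p[[7]]
        c2 <- p[[1]] * p[[5]] * p[[7]]
      }
      del <- img == 1L & B >= 2 & B <= 6 & A == 1L & c1 == 0L & c2 == 0L
      if (any(del)) {
        img[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

#' Skeletonize a filament mask and decompose it into straight segments
#'
#' Thins the mask to a 1-pixel skeleton (Zhang-Suen), breaks the skeleton at
#' branch points (pixels with more than two 8-connected skeleton
#' neighbours), and fits each remaining branch by a total-least-squares line
#' (principal axis of its pixel coordinates). Segments shorter than
#' `min_segment_px` skeleton pixels are discarded as spurs.
#'
#' @param filament_mask binary matrix of filament pixels.
#' @param min_segment_px minimum skeleton pixels per segment (default 5).
#' @return A data.frame with one row per segment: `length_px` (skeleton
#'   pixel count) and `orientation` (degrees mod 180 from the x-axis).
#'   Empty mask gives zero rows.
#' @export
skeletonize_segments <- function(filament_mask, min_segment_px = 5) {
  if (!is.matrix(filament_mask)) stop("`filament_mask` must be a matrix")
  empty <- data.frame(length_px = integer(0), orientation = numeric(0))
  if (mask_area_px(filament_mask) == 0) return(empty)
  skel <- skeletonize_mask(filament_mask)
  # branch points by crossing number: more than two connected blocks of
  # skeleton neighbours around the pixel (robust on diagonal staircases,
  # where the raw neighbour count exceeds 2 on straight runs)
  p <- lapply(list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                   c(1, 0), c(1, -1), c(0, -1), c(-1, -1)),
              function(o) shift_mat(skel, o[1], o[2]))
  blocks <- matrix(0L, nrow(skel), ncol(skel))
  for (k in 1:8) {
    nxt <- p[[if (k == 8) 1 else k + 1]]
    blocks <- blocks + (p[[k]] == 0L & nxt == 1L)
  }
  branch <- skel == 1L & blocks > 2
  # remove branch points together with their 8-neighbourhood: arms of a
  # junction stay diagonally connected if only the branch pixel is dropped
  branch_zone <- branch + 0L
  for (o in list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                 c(1, 0), c(1, -1), c(0, -1), c(-1, -1)))
    branch_zone <- branch_zone + shift_mat(branch + 0L, o[1], o[2])
  pruned <- skel
  pruned[branch_zone > 0] <- 0L
  lab <- label_components_8(pruned)
  nlab <- max(lab)
  if (nlab == 0) return(empty)
  segs <- lapply(seq_len(nlab), function(i) {
    idx <- which(lab == i)
    if (length(idx) < min_segment_px) return(NULL)
    nr <- nrow(lab)
    x <- (idx - 1L) %/% nr
    y <- (idx - 1L) %% nr
    if (length(unique(x)) == 1L && length(unique(y)) == 1L) return(NULL)
    e <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE)
    v <- e$vectors[, 1]
    data.frame(length_px = length(idx),
               orientation = (atan2(v[2], v[1]) * 180 / pi) %% 180)
  })
  out <- do.call(rbind, segs)
  if (is.null(out)) empty else `rownames<-`(out, NULL)
}

acute_angle <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

#' Mean filament angle against the cell long axis (avgTheta)
#'
#' Length-weighted mean of the acute angle between each segment orientation
#' and the cell long axis; 0 means filaments run along the axis, 90
#' perpendicular to it, and uniformly oriented filaments average 45.
#'
#' @param segments data.frame from [skeletonize_segments()].
#' @param long_axis_angle cell long-axis orientation in degrees.
#' @param weighted length-weight the segments (default `TRUE`).
#' @return Degrees in `[0, 90]`; `NA` with a warning when no segments.
#' @export
avg_theta <- function(segments, long_axis_angle, weighted = TRUE) {
  if (nrow(segments) == 0) {
    warning("no segments; avg_theta undefined")
    return(NA_real_)
  }
  w <- if (weighted) segments$length_px else rep(1, nrow(segments))
  sum(w * acute_angle(segments$orientation, long_axis_angle)) / sum(w)
}

#' Parallelness of filament orientations
#'
#' Circular mean resultant length on doubled angles,
#' `R = |sum w exp(2 i theta)| / sum w`: 1 when all segments share one
#' orientation (mod 180), 0 for balanced orthogonal families or uniform
#' orientations. An index of how little the angle distribution varies,
#' analogous to plugin-reported parallelness scores (normAvgRad).
#'
#' @inheritParams avg_theta
#' @return Dimensionless in `[0, 1]`; `NA` with a warning when no segments.
#' @export
parallelness <- function(segments, weighted = TRUE) {
  if (nrow(segments) == 0) {
    warning("no segments; parallelness undefined")
    return(NA_real_)
  }
  w <- if (weighted) segments$length_px else rep(1, nrow(segments))
  th <- segments$orientation * pi / 90  # doubled angle in radians
  sqrt(sum(w * cos(th))^2 + sum(w * sin(th))^2) / sum(w)
}

#' Bundling skewness of an intensity distribution
#'
#' Fisher's moment coefficient of skewness `g1 = m3 / m2^(3/2)` of the
#' in-region pixel intensities. Bundled filaments concentrate signal into
#' few bright pixels, skewing the intensity histogram to the right.
#'
#' @param image numeric matrix (or [image_stack()], max-projected).
#' @param region binary matrix with at least 3 pixels.
#' @return Dimensionless skewness; `NA` with a warning for zero variance.
#' @export
bundling_skewness <- function(image, region) {
  if (inherits(image, "image_stack")) image <- z_project(image)
  assert_mask(region, "region")
  stopifnot(all(dim(image) == dim(region)))
  x <- image[region != 0]
  if (length(x) < 3) stop("region must have at least 3 pixels")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    warning("zero intensity variance; skewness undefined")
    return(NA_real_)
  }
  mean((x - m)^3) / m2^1.5
}

#' Full cytoskeletal architecture summary for one cell
#'
#' Segments the filament image (Otsu within the cell by default),
#' skeletonizes it, and reports orientation, parallelness, bundling and
#' subplasmalemmal / perinuclear occupancy in one pass.
#'
#' @param image filament channel, matrix or [image_stack()].
#' @param geom a [cell_geometry()].
#' @param spl_fraction inner-outline fraction for the subplasmalemmal band.
#' @param threshold filament threshold or `"otsu"`.
#' @param min_segment_px passed to [skeletonize_segments()].
#' @return A list with `avg_theta`, `parallelness`, `bundling_skewness`,
#'   `occupancy_spl`, `occupancy_pn` (NA without a nucleus), `n_segments`.
#' @export
filament_metrics <- function(image, geom, spl_fraction = 0.8,
                             threshold = "otsu", min_segment_px = 5) {
  stopifnot(inherits(geom, "cell_geometry"))
  if (inherits(image, "image_stack")) image <- z_project(image)
  vals <- image[geom$cell_mask != 0]
  thr <- if (identical(threshold, "otsu")) otsu_threshold(vals) else threshold
  fmask <- (image > thr & geom$cell_mask != 0) + 0L
  segs <- skeletonize_segments(fmask, min_segment_px)
  regions <- subplasmalemmal_band(geom, spl_fraction)
  occ_pn <- if (!is.null(geom$nucleus_mask) &&
                mask_area_px(geom$nucleus_mask) > 0)
    as.numeric(occupancy(image, perinuclear_region(geom), threshold = thr))
  else NA_real_
  list(avg_theta = avg_theta(segs, geom$long_axis_angle),
       parallelness = parallelness(segs),
       bundling_skewness = bundling_skewness(image, geom$cell_mask),
       occupancy_spl = as.numeric(occupancy(image, regions$band, threshold = thr)),
       occupancy_pn = occ_pn,
       n_segments = nrow(segs))
}
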