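## 3D puncta detection, density normalization and FWHM sizing.

neighbor_offsets <- function(connectivity) {
  offs <- expand.grid(dr = -1:1, dc = -1:1, dz = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0 & offs$dz == 0), ]
  ord <- abs(offs$dr) + abs(offs$dc) + abs(offs$dz)
  switch(as.character(connectivity),
         "6" = offs[ord == 1, ],
         "18" = offs[ord <= 2, ],
         "26" = offs,
         stop("connectivity must be 6, 18 or 26"))
}

# 3D connected-component labeling of a logical array via igraph components.
label_components_3d <- function(fg, connectivity = 26) {
  dims <- dim(fg)
  idx <- which(fg)
  lab <- array(0L, dims)
  if (length(idx) == 0L) return(lab)
  nr <- dims[1]; nc <- dims[2]
  rr <- (idx - 1L) %% nr + 1L
  cc <- ((idx - 1L) %/% nr) %% nc + 1L
  zz <- (idx - 1L) %/% (nr * nc) + 1L
  offs <- neighbor_offsets(connectivity)
  pos <- seq_along(idx)
  edges <- integer(0)
  for (k in seq_len(nrow(offs))) {
    r2 <- rr + offs$dr[k]; c2 <- cc + offs$dc[k]; z2 <- zz + offs$dz[k]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc & z2 >= 1 & z2 <= dims[3]
    nb <- (z2[ok] - 1L) * nr * nc + (c2[ok] - 1L) * nr + r2[ok]
    hit <- match(nb, idx)
    keep <- !is.na(hit)
    if (any(keep)) edges <- c(edges, rbind(pos[ok][keep], hit[keep]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

#' Detect 3D fluorescent objects in a z-stack
#'
#' Thresholds the stack, labels connected components of the supra-threshold
#' voxel set and filters them by size, in the manner of 3D object-counting
#' plugins. Centroids are intensity-weighted and reported in micrometres.
#'
#' @param stack an [image_stack()].
#' @param threshold intensity threshold, or `"otsu"` (default) for Otsu on
#'   the stack (restricted to `mask` if given). A stack with no intensity
#'   variation yields an empty set.
#' @param min_voxels minimum object size in voxels (default 4).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param mask optional binary cell mask (2D); restricts Otsu to in-cell
#'   voxels.
#' @param max_fg_fraction sparse-signal guard for the auto threshold:
#'   puncta occupy a small fraction of the volume, so if the Otsu threshold
#'   would mark more than this fraction of voxels as foreground the
#'   histogram is treated as noise-dominated and the threshold falls back
#'   to robust background statistics (median + 3.5 MAD); if even that marks
#'   too many voxels the stack is treated as signal-free. Default 0.05.
#' @return An object of class `puncta_set`: list with `objects` (data.frame:
#'   `id`, `x_um`, `y_um`, `z_um`, `voxel_count`, `equatorial_plane`,
#'   `peak_intensity`), `labels` (integer array), `threshold_used`,
#'   `connectivity`, `pixel_size`, `z_step`.
#' @export
detect_objects <- function(stack, threshold = "otsu", min_voxels = 4,
                           connectivity = 26, mask = NULL,
                           max_fg_fraction = 0.05) {
  stopifnot(inherits(stack, "image_stack"), min_voxels >= 1)
  vox <- stack$voxels
  if (identical(threshold, "otsu")) {
    vals <- if (is.null(mask)) as.numeric(vox)
            else as.numeric(vox[rep(mask != 0, dim(vox)[3])])
    threshold <- if (diff(range(vals)) == 0) Inf else otsu_threshold(vals)
    if (mean(vals > threshold) > max_fg_fraction) {
      # Otsu has split a noise-dominated histogram rather than isolated a
      # sparse signal mode; fall back to robust background statistics
      madv <- stats::mad(vals)
      threshold <- if (madv > 0) stats::median(vals) + 3.5 * madv else Inf
      if (mean(vals > threshold) > max_fg_fraction) threshold <- Inf
    }
  }
  fg <- vox > threshold
  lab <- label_components_3d(fg, connectivity)
  nlab <- max(lab)
  objects <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                        z_um = numeric(0), voxel_count = integer(0),
                        equatorial_plane = integer(0),
                        peak_intensity = numeric(0))
  if (nlab > 0) {
    idx <- which(lab > 0)
    li <- lab[idx]
    counts <- tabulate(li, nlab)
    keep <- which(counts >= min_voxels)
    # drop small components from the label array, then renumber
    if (length(keep) < nlab) {
      drop <- idx[!(li %in% keep)]
      lab[drop] <- 0L
      remap <- integer(nlab); remap[keep] <- seq_along(keep)
      idx <- which(lab > 0)
      lab[idx] <- remap[lab[idx]]
      li <- lab[idx]
    }
    nkeep <- max(lab, 0L)
    if (nkeep > 0) {
      dims <- dim(vox)
      rr <- (idx - 1L) %% dims[1]
      cc <- ((idx - 1L) %/% dims[1]) %% dims[2]
      zz <- (idx - 1L) %/% (dims[1] * dims[2])
      w <- vox[idx]
      wsum <- tapply(w, li, sum)
      objects <- data.frame(
        id = seq_len(nkeep),
        x_um = as.numeric(tapply(w * cc, li, sum) / wsum) * stack$pixel_size,
        y_um = as.numeric(tapply(w * rr, li, sum) / wsum) * stack$pixel_size,
        z_um = as.numeric(tapply(w * zz, li, sum) / wsum) * stack$z_step,
        voxel_count = as.integer(tapply(w, li, length)),
        equatorial_plane = as.integer(tapply(seq_along(idx), li, function(ii) {
          pl <- zz[ii] + 1L
          sums <- tapply(w[ii], pl, sum)
          as.integer(names(sums)[which.max(sums)])
        })),
        peak_intensity = as.numeric(tapply(w, li, max)))
    }
  }
  structure(list(objects = objects, labels = lab,
                 threshold_used = threshold, connectivity = connectivity,
                 pixel_size = stack$pixel_size, z_step = stack$z_step),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %d object(s), threshold %.4g, connectivity %d\n",
              nrow(x$objects), x$threshold_used, x$connectivity))
  invisible(x)
}

#' Puncta density normalized to 100 square micrometres
#'
#' @param puncta a `puncta_set` (or a count).
#' @param cell_area cell area in square micrometres (> 0).
#' @return Objects per 100 um^2: `100 * N / cell_area`.
#' @export
density_per_100um2 <- function(puncta, cell_area) {
  if (cell_area <= 0) stop("cell_area must be positive")
  n <- if (inherits(puncta, "puncta_set")) nrow(puncta$objects) else puncta
  100 * n / cell_area
}

# Half-maximum crossings of a 1D profile around a peak index, by linear
# interpolation; returns the width in samples or NA if a side never crosses.
# The peak value is refined by a parabola through the three top samples so
# that sub-pixel spot centres do not depress the half-maximum level.
profile_fwhm <- function(profile) {
  mx <- which.max(profile)
  pk <- profile[mx]
  if (mx > 1 && mx < length(profile)) {
    y0 <- profile[mx - 1]; y1 <- profile[mx]; y2 <- profile[mx + 1]
    den <- y0 - 2 * y1 + y2
    if (den < 0) pk <- y1 - (y2 - y0)^2 / (8 * den)
  }
  half <- pk / 2
  peak_idx <- mx
  if (!is.finite(half) || half <= 0) return(NA_real_)
  left <- NA_real_
  if (peak_idx >= 2) for (i in seq(peak_idx, 2)) {
    if (profile[i - 1] <= half && profile[i] > half) {
      left <- (i - 1) + (half - profile[i - 1]) / (profile[i] - profile[i - 1])
      break
    }
  }
  right <- NA_real_
  if (peak_idx <= length(profile) - 1) for (i in seq(peak_idx, length(profile) - 1)) {
    if (profile[i + 1] <= half && profile[i] > half) {
      right <- i + (profile[i] - half) / (profile[i] - profile[i + 1])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' Full-width-at-half-maximum diameter of a detected object
#'
#' Selects the object's equatorial plane (the z-plane maximizing its
#' integrated intensity), draws horizontal and vertical intensity profiles
#' through the intensity-weighted centroid, subtracts a local background
#' (median in the 2-px frame at the border of the analysis window, far
#' enough from the object that its own tail does not bias the estimate) and
#' locates the half-maximum crossings by linear interpolation.
#'
#' @param stack the [image_stack()] the object was detected in.
#' @param puncta the `puncta_set` from [detect_objects()].
#' @param id object id.
#' @param window_px half-width of the analysis window around the centroid in
#'   pixels (default `12`).
#' @return A list with `fwhm_h`, `fwhm_v` and `diameter` (their mean), in
#'   micrometres; fields are `NA` (flag `measurable = FALSE`) when a profile
#'   never falls below half maximum inside the window.
#' @export
fwhm_diameter <- function(stack, puncta, id, window_px = 12) {
  stopifnot(inherits(stack, "image_stack"), inherits(puncta, "puncta_set"))
  obj <- puncta$objects[puncta$objects$id == id, ]
  if (nrow(obj) != 1) stop("unknown object id")
  z <- obj$equatorial_plane
  plane <- stack$voxels[, , z]
  cr <- round(obj$y_um / stack$pixel_size) + 1L
  cc <- round(obj$x_um / stack$pixel_size) + 1L
  rows <- max(1, cr - window_px):min(nrow(plane), cr + window_px)
  cols <- max(1, cc - window_px):min(ncol(plane), cc + window_px)
  # background: 2-px frame at the window border, excluding other objects
  frame <- matrix(FALSE, nrow(plane), ncol(plane))
  frame[rows, cols] <- TRUE
  inner_r <- rows[rows > min(rows) + 1 & rows < max(rows) - 1]
  inner_c <- cols[cols > min(cols) + 1 & cols < max(cols) - 1]
  if (length(inner_r) && length(inner_c)) frame[inner_r, inner_c] <- FALSE
  frame[puncta$labels[, , z] > 0] <- FALSE
  bg <- if (any(frame)) stats::median(plane[frame]) else 0
  prof_h <- plane[cr, cols] - bg   # along x
  prof_v <- plane[rows, cc] - bg   # along y
  fh <- profile_fwhm(prof_h)
  fv <- profile_fwhm(prof_v)
  measurable <- !is.na(fh) && !is.na(fv)
  list(fwhm_h = fh * stack$pixel_size,
       fwhm_v = fv * stack$pixel_size,
       diameter = if (measurable) (fh + fv) / 2 * stack$pixel_size else NA_real_,
       measurable = measurable)
}

#' FWHM diameters for every object of a puncta set
#'
#' @inheritParams fwhm_diameter
#' @return The `objects` data.frame augmented with `fwhm_h`, `fwhm_v`,
#'   `diameter` (micrometres) and `measurable`.
#' @export
measure_diameters <- function(stack, puncta, window_px = 12) {
  objs <- puncta$objects
  res <- lapply(objs$id, function(i) fwhm_diameter(stack, puncta, i, window_px))
  objs$fwhm_h <- vapply(res, `[[`, numeric(1), "fwhm_h")
  objs$fwhm_v <- vapply(res, `[[`, numeric(1), "fwhm_v")
  objs$diameter <- vapply(res, `[[`, numeric(1), "diameter")
  objs$measurable <- vapply(res, `[[`, logical(1), "measurable")
  objs
}
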