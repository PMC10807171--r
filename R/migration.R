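## Wound-healing collective migration kinetics and single-cell mobility.

#' Gap area from a binary mask
#'
#' @param gap_mask binary matrix of cell-free (gap) pixels.
#' @param pixel_size micrometres per pixel.
#' @return Area in square micrometres: pixel count times `pixel_size^2`.
#' @export
gap_area_from_mask <- function(gap_mask, pixel_size) {
  stopifnot(is.matrix(gap_mask), pixel_size > 0)
  sum(gap_mask != 0) * pixel_size^2
}

#' Linear fit of early gap closure
#'
#' Ordinary least squares of gap area on time over the first `n_points`
#' samples (default 4, i.e. 0-12 h at 4-h intervals), where closure is
#' approximately linear.
#'
#' @param series a [gap_series()].
#' @param n_points number of leading points to fit (>= 2).
#' @return A list with `slope` (um^2/h), `intercept`, `r_squared` and
#'   `fit_points`.
#' @export
fit_gap_closure <- function(series, n_points = 4) {
  stopifnot(inherits(series, "gap_series"))
  if (n_points < 2 || n_points > length(series$times))
    stop("n_points must be between 2 and the series length")
  t <- series$times[seq_len(n_points)]
  a <- series$areas[seq_len(n_points)]
  fit <- stats::lm(a ~ t)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((a - mean(a))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       fit_points = n_points)
}

#' Collective migration speed from the gap-area slope
#'
#' `v_migration = |slope| / (2 l)`: both wound fronts advance, so the area
#' declines at twice the single-front speed times the gap length `l`.
#'
#' @param slope gap-area slope, um^2/h.
#' @param gap_length gap length `l` in micrometres (> 0).
#' @return Speed in um/h.
#' @export
migration_speed <- function(slope, gap_length) {
  if (gap_length <= 0) stop("gap_length must be positive")
  abs(slope) / (2 * gap_length)
}

#' Gap half-closure time
#'
#' `t_1/2 = initial area / (2 |slope|)`: the time for the linearly closing
#' gap to reach half its initial area.
#'
#' @param initial_area initial gap area, um^2.
#' @param slope gap-area slope, um^2/h; must be negative (closing gap),
#'   otherwise `NA` is returned with a warning.
#' @return Half-closure time in hours.
#' @export
t_half_gap <- function(initial_area, slope) {
  if (slope >= 0) {
    warning("gap is not closing (slope >= 0); t_half undefined")
    return(NA_real_)
  }
  initial_area / (2 * abs(slope))
}

#' Analyze a wound-healing series end to end
#'
#' @param series a [gap_series()].
#' @param n_points fit window, see [fit_gap_closure()].
#' @return A list with `slope`, `intercept`, `r_squared`, `fit_points`,
#'   `v_migration` (um/h) and `t_half` (h).
#' @export
analyze_gap_closure <- function(series, n_points = 4) {
  fit <- fit_gap_closure(series, n_points)
  fit$v_migration <- migration_speed(fit$slope, series$gap_length)
  fit$t_half <- if (fit$slope < 0) t_half_gap(series$initial_area, fit$slope)
                else NA_real_
  fit
}

#' Single-cell mobility from a nucleus track
#'
#' Total path length (sum of Euclidean distances between sequential nucleus
#' positions) and average speed over the recording.
#'
#' @param track data.frame with columns `time_h`, `x_um`, `y_um` (>= 2 rows,
#'   strictly increasing times).
#' @return A list with `total_distance` (um), `avg_speed` (um/h),
#'   `net_displacement` (um) and `n_steps`.
#' @export
track_mobility <- function(track) {
  stopifnot(is.data.frame(track),
            all(c("time_h", "x_um", "y_um") %in% names(track)))
  if (nrow(track) < 2) stop("track needs at least 2 positions")
  if (is.unsorted(track$time_h, strictly = TRUE))
    stop("track times must be strictly increasing")
  steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  total <- sum(steps)
  elapsed <- track$time_h[nrow(track)] - track$time_h[1]
  list(total_distance = total,
       avg_speed = total / elapsed,
       net_displacement = sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
                               (track$y_um[nrow(track)] - track$y_um[1])^2),
       n_steps = length(steps))
}

#' Heuristic gap segmentation from a phase/DIC-like frame
#'
#' Convenience segmenter for wound-healing frames: the cell-free gap is
#' texture-poor, so pixels whose local intensity variance (in a square
#' window) falls below an Otsu cut on the variance image are classified as
#' gap. This is a labeled heuristic for quick looks — quantitative use
#' should supply curated binary gap masks.
#'
#' @param frame numeric matrix (single time-lapse frame).
#' @param window odd side length of the local-variance window (default 9).
#' @return Binary matrix (1 = gap).
#' @export
segment_gap_heuristic <- function(frame, window = 9) {
  stopifnot(is.matrix(frame), window %% 2 == 1, window >= 3)
  box <- matrix(1 / window^2, window, window)
  mu <- EBImage::filter2(frame, box)
  mu2 <- EBImage::filter2(frame^2, box)
  v <- pmax(mu2 - mu^2, 0)
  thr <- otsu_threshold(as.numeric(v))
  (v < thr) + 0L
}

#' Filter tracks by distance from the wound leading edge
#'
#' Keeps tracks whose starting position lies within a distance band from
#' the leading edge (given as an x-coordinate), e.g. 150-300 um.
#'
#' @param tracks data.frame with `track_id`, `time_h`, `x_um`, `y_um`.
#' @param edge_x leading-edge x-coordinate in micrometres.
#' @param band numeric `(min, max)` distance from the edge in micrometres.
#' @return The subset of `tracks` whose first position falls in the band.
#' @export
filter_tracks_by_edge <- function(tracks, edge_x, band = c(150, 300)) {
  stopifnot(is.data.frame(tracks), "track_id" %in% names(tracks))
  keep <- vapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$time_h), ]
    d <- abs(tr$x_um[1] - edge_x)
    d >= band[1] && d <= band[2]
  }, logical(1))
  tracks[tracks$track_id %in% names(keep)[keep], ]
}
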