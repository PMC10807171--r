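## Synthetic time series: wound-healing gap closure, calcein volume traces,
## single-cell tracks and expression matrices.

#' Gap-closure time series container
#'
#' @param times time points in hours (ascending, >= 2 points).
#' @param areas gap areas in square micrometres (>= 0).
#' @param gap_length gap length `l` in micrometres (the dimension along the
#'   wound; gap area = width x length).
#' @return An object of class `gap_series` with fields `times`, `areas`,
#'   `gap_length` and `initial_area` (= `areas[1]`).
#' @export
gap_series <- function(times, areas, gap_length) {
  stopifnot(length(times) == length(areas), length(times) >= 2,
            !is.unsorted(times, strictly = TRUE), all(areas >= 0),
            gap_length > 0)
  structure(list(times = as.numeric(times), areas = as.numeric(areas),
                 gap_length = gap_length, initial_area = as.numeric(areas[1])),
            class = "gap_series")
}

#' Generate a wound-healing gap series
#'
#' Both wound fronts advance at `v_true` um/h, so the rectangular gap area
#' declines as `area(t) = max(0, width - 2 v t) * length` plus optional
#' Gaussian noise. Defaults match time-lapse acquisition at 4-h intervals
#' for 28 h.
#'
#' @param gap_width initial gap width in micrometres.
#' @param gap_length gap length `l` in micrometres.
#' @param v_true migration speed of each front, um/h.
#' @param dt sampling interval in hours.
#' @param duration total recording time in hours.
#' @param noise_sd Gaussian noise SD on areas (um^2).
#' @param seed integer seed.
#' @return A [gap_series()].
#' @export
gen_gap_series <- function(gap_width = 500, gap_length = 1000, v_true = 10,
                           dt = 4, duration = 28, noise_sd = 0, seed = NULL) {
  stopifnot(gap_width > 0, gap_length > 0, dt > 0, duration > 0, v_true >= 0)
  times <- seq(0, duration, by = dt)
  areas <- pmax(0, gap_width - 2 * v_true * times) * gap_length
  if (noise_sd > 0)
    areas <- pmax(0, with_seed(seed, areas + stats::rnorm(length(areas), 0, noise_sd)))
  gap_series(times, areas, gap_length)
}

#' Calcein fluorescence trace container
#'
#' @param times time points in seconds (uniformly sampled).
#' @param F fluorescence intensities.
#' @param stimulus_onset time of hypotonic stimulation in seconds; the
#'   baseline window is `[0, stimulus_onset)`.
#' @param label `"whole-cell"` or `"LPR"` (local peripheral region).
#' @return An object of class `calcein_trace`.
#' @export
calcein_trace <- function(times, F, stimulus_onset = 30,
                          label = c("whole-cell", "LPR")) {
  label <- match.arg(label)
  stopifnot(length(times) == length(F), length(times) >= 3)
  dts <- diff(times)
  if (max(dts) - min(dts) > 1e-9 * max(dts)) stop("sampling must be uniform")
  if (stimulus_onset <= times[1] || stimulus_onset >= times[length(times)])
    stop("stimulus_onset must fall inside the record")
  structure(list(times = as.numeric(times), F = as.numeric(F),
                 stimulus_onset = stimulus_onset, label = label),
            class = "calcein_trace")
}

#' Generate a calcein cell-volume trace with known swelling parameters
#'
#' Produces a fluorescence record sampled at `rate` frames/s with a baseline
#' before stimulus onset, a logistic swelling phase, an exponential
#' regulatory volume decrease (RVD) after the swelling peak, linear
#' photobleaching and Gaussian noise. The relative response (in % of
#' baseline) is
#' \itemize{
#' \item baseline: 100 for `t < onset`;
#' \item swelling: `Fmax_pct / (1 + exp(-k (t - t0)))` for
#'   `onset <= t <= t_peak`, with `t_peak = t0 + log(99)/k` (99\% of the
#'   plateau);
#' \item RVD: exponential relaxation of the excess over baseline,
#'   `100 + (F_peak - 100) exp(-rvd_rate (t - t_peak))`.
#' }
#' The raw trace is `F0_level * response/100 + bleach_slope * t + noise`.
#'
#' @param F0_level baseline intensity.
#' @param Fmax_pct logistic plateau in % of baseline (> 100 for swelling;
#'   exactly 100 yields a flat, non-swelling trace).
#' @param k_true logistic rate, 1/s.
#' @param t0_true logistic midpoint, s. The default (`NULL`) places the
#'   midpoint so that the logistic passes through 100\% exactly at stimulus
#'   onset (`t0 = onset + log(Fmax_pct/100 - 1)/k`, before onset whenever
#'   `Fmax_pct < 200`), giving a continuous trace; an explicit `t0_true` is
#'   honoured as given and may introduce a step at onset.
#' @param rvd_rate exponential RVD rate, 1/s (0 = no recovery).
#' @param bleach_slope linear photobleaching slope, intensity/s (<= 0
#'   typically).
#' @param noise_sd Gaussian noise SD in % of `F0_level`.
#' @param baseline_s,post_s seconds recorded before / after stimulation.
#' @param rate acquisition rate, frames/s.
#' @param seed integer seed.
#'
#' @return A list with `trace` (a [calcein_trace()]) and `truth` (all
#'   generating parameters plus `t_peak`, `t_s_max` = `t_peak - onset`, and
#'   `t_rvd_50` = `log(2)/rvd_rate`).
#' @export
gen_calcein_trace <- function(F0_level = 500, Fmax_pct = 140, k_true = 0.5,
                              t0_true = NULL, rvd_rate = 0.02,
                              bleach_slope = 0, noise_sd = 0,
                              baseline_s = 30, post_s = 90, rate = 1,
                              seed = NULL) {
  stopifnot(baseline_s > 0, post_s > 0, rate > 0, Fmax_pct >= 100,
            k_true > 0, rvd_rate >= 0, noise_sd >= 0)
  times <- seq(0, baseline_s + post_s, by = 1 / rate)
  onset <- baseline_s
  # continuity at onset: Fmax/(1 + exp(-k (onset - t0))) = 100 solves to
  # t0 = onset + log(Fmax/100 - 1)/k; for Fmax < 200 the midpoint lies
  # before onset (the half-maximum value Fmax/2 < 100 is never observed)
  if (is.null(t0_true))
    t0_true <- if (Fmax_pct > 100) onset + log(Fmax_pct / 100 - 1) / k_true
               else onset + 1
  rel <- rep(100, length(times))
  if (Fmax_pct > 100) {
    t_peak <- t0_true + log(99) / k_true
    sw <- times >= onset & times <= t_peak
    rel[sw] <- Fmax_pct / (1 + exp(-k_true * (times[sw] - t0_true)))
    post <- times > t_peak
    f_peak <- Fmax_pct / (1 + exp(-k_true * (t_peak - t0_true)))
    rel[post] <- 100 + (f_peak - 100) * exp(-rvd_rate * (times[post] - t_peak))
  } else {
    t_peak <- NA_real_
  }
  F <- F0_level * rel / 100 + bleach_slope * times
  if (noise_sd > 0)
    F <- with_seed(seed, F + stats::rnorm(length(F), 0, noise_sd / 100 * F0_level))
  list(trace = calcein_trace(times, F, stimulus_onset = onset),
       truth = list(F0_level = F0_level, Fmax_pct = Fmax_pct, k_true = k_true,
                    t0_true = t0_true, rvd_rate = rvd_rate,
                    bleach_slope = bleach_slope, noise_sd = noise_sd,
                    t_peak = t_peak,
                    t_s_max = if (is.na(t_peak)) NA_real_ else t_peak - onset,
                    t_rvd_50 = if (rvd_rate > 0) log(2) / rvd_rate else NA_real_))
}

#' Generate a single-cell nucleus track
#'
#' Random-walk positions with per-step lengths either fixed or drawn from a
#' supplied sampler; the ground-truth total path length is the sum of the
#' drawn step lengths.
#'
#' @param n_steps number of steps (>= 1).
#' @param step_length a single number (fixed step, micrometres) or a
#'   function `n -> lengths`.
#' @param dt frame interval in hours.
#' @param seed integer seed.
#' @return A list with `track` (data.frame `time_h`, `x_um`, `y_um`) and
#'   `truth` (`total_distance`, `avg_speed`).
#' @export
gen_tracks <- function(n_steps = 10, step_length = 5, dt = 4, seed = NULL) {
  stopifnot(n_steps >= 1, dt > 0)
  with_seed(seed, {
    lens <- if (is.function(step_length)) step_length(n_steps)
            else rep(step_length, n_steps)
    stopifnot(all(lens >= 0))
    ang <- stats::runif(n_steps, 0, 2 * pi)
    x <- c(0, cumsum(lens * cos(ang)))
    y <- c(0, cumsum(lens * sin(ang)))
    track <- data.frame(time_h = seq(0, by = dt, length.out = n_steps + 1),
                        x_um = x, y_um = y)
    list(track = track,
         truth = list(total_distance = sum(lens),
                      avg_speed = sum(lens) / (n_steps * dt)))
  })
}

#' Generate a gene x sample expression matrix with one correlated pair
#'
#' Two designated rows (`"GX"`, `"GY"`) follow `y = slope_true * x + noise`
#' on the z-score scale (x standard normal); the remaining rows are
#' independent standard normal noise. Used to validate the z-score
#' regression stage by slope recovery.
#'
#' @param n_genes,n_samples matrix dimensions (`n_samples >= 3`).
#' @param slope_true slope of the designated pair on the z-score scale.
#' @param noise_sd SD of the noise added to the dependent row.
#' @param seed integer seed.
#' @return A list with `matrix` (numeric, rownames `GX`, `GY`, `gene3`, ...)
#'   and `truth` (`slope_true`, `noise_sd`, designated row names).
#' @export
gen_expression <- function(n_genes = 50, n_samples = 100, slope_true = 0.35,
                           noise_sd = sqrt(1 - 0.35^2), seed = NULL) {
  stopifnot(n_samples >= 3, n_genes >= 2, noise_sd >= 0)
  with_seed(seed, {
    x <- stats::rnorm(n_samples)
    y <- slope_true * x + stats::rnorm(n_samples, 0, noise_sd)
    rest <- if (n_genes > 2)
      matrix(stats::rnorm((n_genes - 2) * n_samples), n_genes - 2) else NULL
    m <- rbind(x, y, rest)
    rownames(m) <- c("GX", "GY",
                     if (n_genes > 2) paste0("gene", seq_len(n_genes - 2)))
    colnames(m) <- paste0("s", seq_len(n_samples))
    list(matrix = m,
         truth = list(slope_true = slope_true, noise_sd = noise_sd,
                      gx = "GX", gy = "GY"))
  })
}
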