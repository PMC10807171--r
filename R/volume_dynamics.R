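## Calcein cell-volume dynamics: smoothing, bleach correction, baseline
## normalization, logistic swelling fit and RVD half-time.

#' Savitzky-Golay smoothing of a calcein trace
#'
#' @param trace a [calcein_trace()].
#' @param window odd filter window in samples (default 11).
#' @param polyorder polynomial order (default 3, < `window`).
#' @return The smoothed [calcein_trace()].
#' @export
smooth_trace <- function(trace, window = 11, polyorder = 3) {
  stopifnot(inherits(trace, "calcein_trace"))
  if (window %% 2 == 0 || window <= polyorder || window > length(trace$F))
    stop("window must be odd, greater than polyorder and at most the trace length")
  out <- trace
  out$F <- as.numeric(signal::sgolayfilt(trace$F, p = polyorder, n = window))
  out
}

#' Photobleaching correction from the baseline
#'
#' Fits a line to the pre-stimulus baseline and subtracts its slope
#' component (`m * t`) from the whole trace, so the baseline level itself is
#' preserved and the baseline slope becomes zero.
#'
#' @param trace a [calcein_trace()].
#' @param min_baseline minimum number of baseline samples (default 5).
#' @param margin samples dropped from the end of the baseline before the
#'   line fit (default 0); used after smoothing so that filter transients
#'   around stimulus onset do not bias the slope.
#' @return The corrected [calcein_trace()] with attribute `bleach_slope`
#'   (the removed slope, intensity/s).
#' @export
bleach_correct <- function(trace, min_baseline = 5, margin = 0) {
  stopifnot(inherits(trace, "calcein_trace"))
  base <- trace$times < trace$stimulus_onset
  if (margin > 0 && sum(base) > min_baseline + margin)
    base[utils::tail(which(base), margin)] <- FALSE
  if (sum(base) < min_baseline)
    stop(sprintf("need at least %d baseline samples", min_baseline))
  fit <- stats::lm(trace$F[base] ~ trace$times[base])
  m <- unname(stats::coef(fit)[2])
  out <- trace
  out$F <- trace$F - m * trace$times
  attr(out, "bleach_slope") <- m
  out
}

#' Baseline normalization to percent of F0
#'
#' `F0` is the mean of the (bleach-corrected) baseline; the trace is
#' reported as `F / F0 * 100` so the baseline maps to 100%.
#'
#' @param trace a [calcein_trace()].
#' @return The normalized [calcein_trace()] with attribute `F0`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "calcein_trace"))
  base <- trace$times < trace$stimulus_onset
  F0 <- mean(trace$F[base])
  if (!is.finite(F0) || F0 <= 0) stop("nonpositive baseline; cannot normalize")
  out <- trace
  out$F <- 100 * trace$F / F0
  attr(out, "F0") <- F0
  out
}

logistic_model <- function(t, Fmax, k, t0) Fmax / (1 + exp(-k * (t - t0)))

#' Fit the logistic swelling model to a normalized trace
#'
#' Nonlinear least squares of `F(t) = Fmax / (1 + exp(-k (t - t0)))` on the
#' swelling phase (stimulus onset to the trace peak), with `k > 0` for the
#' increasing response. A short transition guard after onset (half the
#' smoothing window) is excluded so smoothing transients at the stimulus
#' step do not bias the fit. Initialization: `Fmax` from the trace maximum,
#' `t0` at the half-rise time, `k = 4 * max slope / Fmax`; three jittered
#' restarts, best RMSE kept.
#'
#' @param trace normalized [calcein_trace()] (percent units, baseline 100).
#' @param guard_s seconds after onset excluded from the fit window
#'   (default 0; set to the smoothing half-window when fitting a smoothed
#'   trace with a step at onset).
#' @param n_starts number of jittered restarts (default 3).
#' @param peak_trace optional companion trace (typically the smoothed
#'   version of `trace`) used only to locate the swelling peak and to test
#'   for the absence of swelling; defaults to `trace` itself.
#' @return A list of class `swelling_fit`: `F_max` (% of F0), `k` (1/s),
#'   `t0` (s), `t_s_max` (s, onset to trace peak), `max_rate` (`F_max k / 4`,
#'   %/s, the realized maximal derivative), `rmse`, `converged`,
#'   `no_swelling`, `peak_time` (s). A flat trace (range < 2% of baseline)
#'   returns `no_swelling = TRUE` and no fit.
#' @export
fit_swelling <- function(trace, guard_s = 0, n_starts = 3,
                         peak_trace = NULL) {
  stopifnot(inherits(trace, "calcein_trace"))
  if (is.null(peak_trace)) peak_trace <- trace
  onset <- trace$stimulus_onset
  t_end <- trace$times[length(trace$times)]
  if (t_end - onset < 20) stop("trace must extend at least 20 s past onset")
  post <- trace$times >= onset
  empty <- list(F_max = NA_real_, k = NA_real_, t0 = NA_real_,
                t_s_max = NA_real_, max_rate = NA_real_, rmse = NA_real_,
                converged = FALSE, no_swelling = TRUE, peak_time = NA_real_)
  class(empty) <- "swelling_fit"
  if (max(peak_trace$F[post]) - 100 < 2) return(empty)

  peak_idx <- which(post)[which.max(peak_trace$F[post])]
  peak_time <- trace$times[peak_idx]
  win <- trace$times >= onset + guard_s & trace$times <= peak_time
  if (sum(win) < 4) win <- post & trace$times <= peak_time
  t <- trace$times[win]; y <- trace$F[win]

  Fmax0 <- max(y)
  half <- Fmax0 / 2
  above <- which(y >= half)
  t0_0 <- if (length(above)) t[above[1]] else mean(t)
  slope_max <- max(diff(y) / diff(t))
  k0 <- max(4 * slope_max / Fmax0, 1e-3)

  best <- NULL
  for (s in seq_len(n_starts)) {
    jit <- if (s == 1) c(1, 1, 0) else c(stats::runif(1, 0.8, 1.2),
                                         stats::runif(1, 0.5, 2),
                                         stats::runif(1, -2, 2))
    fit <- try(minpack.lm::nlsLM(
      y ~ Fmax / (1 + exp(-k * (tt - t0))),
      data = list(y = y, tt = t),
      start = list(Fmax = Fmax0 * jit[1], k = k0 * jit[2], t0 = t0_0 + jit[3]),
      lower = c(Fmax = 50, k = 1e-4, t0 = onset - 50),
      upper = c(Fmax = 10 * Fmax0, k = 100, t0 = t_end + 50),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rmse <- sqrt(mean(stats::residuals(fit)^2))
    if (is.null(best) || rmse < best$rmse)
      best <- list(fit = fit, rmse = rmse)
  }
  if (is.null(best)) {
    empty$no_swelling <- FALSE
    return(empty)
  }
  cf <- stats::coef(best$fit)
  out <- list(F_max = unname(cf["Fmax"]), k = unname(cf["k"]),
              t0 = unname(cf["t0"]),
              t_s_max = peak_time - onset,
              max_rate = unname(cf["Fmax"] * cf["k"] / 4),
              rmse = best$rmse,
              converged = best$fit$convInfo$isConv %||% TRUE,
              no_swelling = FALSE, peak_time = peak_time)
  class(out) <- "swelling_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.swelling_fit <- function(x, ...) {
  if (isTRUE(x$no_swelling)) {
    cat("<swelling_fit> no swelling detected\n")
  } else {
    cat(sprintf(
      "<swelling_fit> F_max %.1f%%, k %.3g /s, t0 %.1f s, t_s_max %.1f s, rmse %.3g\n",
      x$F_max, x$k, x$t0, x$t_s_max, x$rmse))
  }
  invisible(x)
}

#' Half-time of the regulatory volume decrease
#'
#' First time after the swelling peak at which the normalized fluorescence
#' falls to `100 + (F_peak - 100)/2`, located by linear interpolation
#' between the bracketing samples, reported as time elapsed since the peak.
#'
#' @param trace normalized [calcein_trace()].
#' @param peak_time time of the swelling peak in seconds.
#' @return A list with `t_rvd_50` (s) and `censored`; when the trace never
#'   reaches half-recovery, `censored = TRUE` and `t_rvd_50` is the elapsed
#'   record length after the peak.
#' @export
rvd_half_time <- function(trace, peak_time) {
  stopifnot(inherits(trace, "calcein_trace"))
  post <- which(trace$times >= peak_time)
  if (length(post) < 10) stop("need at least 10 samples after the peak")
  t <- trace$times[post]; y <- trace$F[post]
  target <- 100 + (y[1] - 100) / 2
  below <- which(y <= target)
  i <- below[below > 1][1]
  if (is.na(i))
    return(list(t_rvd_50 = t[length(t)] - peak_time, censored = TRUE))
  frac <- (y[i - 1] - target) / (y[i - 1] - y[i])
  list(t_rvd_50 = t[i - 1] + frac * (t[i] - t[i - 1]) - peak_time,
       censored = FALSE)
}

#' Full calcein trace analysis
#'
#' Composition of the pipeline: Savitzky-Golay smoothing, baseline bleach
#' correction, normalization to percent of F0, logistic swelling fit, and
#' RVD half-time after the swelling peak. Whole-cell and
#' local-peripheral-region traces are treated identically.
#'
#' The smoothed trace serves for landmark detection: the swelling peak
#' (hence `t_s_max` and the fit-window end), the no-swelling check, and the
#' RVD half-recovery crossing. The logistic itself is fitted to the
#' bleach-corrected, normalized raw samples: least squares performs its own
#' noise averaging, whereas pre-filtering a curve whose rise time is
#' comparable to the filter window biases the fitted rate downward.
#'
#' @param trace a raw [calcein_trace()].
#' @param window,polyorder smoothing parameters, see [smooth_trace()].
#' @param guard_s fit-window guard after onset, see [fit_swelling()].
#' @return A `swelling_fit` augmented with `t_rvd_50`, `rvd_censored`,
#'   `bleach_slope` and `F0`.
#' @export
analyze_trace <- function(trace, window = 11, polyorder = 3, guard_s = 0) {
  half_w <- (window - 1) / 2
  sm <- smooth_trace(trace, window, polyorder)
  nm_sm <- normalize_trace(bleach_correct(sm, margin = half_w))
  bc <- bleach_correct(trace)
  nm <- normalize_trace(bc)
  fit <- fit_swelling(nm, guard_s = guard_s, peak_trace = nm_sm)
  if (!isTRUE(fit$no_swelling) && is.finite(fit$peak_time)) {
    rvd <- try(rvd_half_time(nm_sm, fit$peak_time), silent = TRUE)
    if (!inherits(rvd, "try-error")) {
      fit$t_rvd_50 <- rvd$t_rvd_50
      fit$rvd_censored <- rvd$censored
    } else {
      fit$t_rvd_50 <- NA_real_
      fit$rvd_censored <- NA
    }
  } else {
    fit$t_rvd_50 <- NA_real_
    fit$rvd_censored <- NA
  }
  fit$bleach_slope <- attr(bc, "bleach_slope")
  fit$F0 <- attr(nm, "F0")
  fit
}
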