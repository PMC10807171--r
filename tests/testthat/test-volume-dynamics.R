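test_that("Savitzky-Golay smoothing preserves polynomials and reduces noise", {
  t <- 0:120
  cubic <- 2 + 0.5 * t - 0.01 * t^2 + 1e-4 * t^3
  tr <- calcein_trace(t, cubic, stimulus_onset = 30)
  sm <- smooth_trace(tr, window = 11, polyorder = 3)
  interior <- 6:115
  expect_equal(sm$F[interior], cubic[interior], tolerance = 1e-9)

  const <- calcein_trace(t, rep(7, 121), stimulus_onset = 30)
  expect_equal(smooth_trace(const)$F, rep(7, 121))

  set.seed(3)
  noisy <- calcein_trace(t, 100 + rnorm(121, 0, 5), stimulus_onset = 30)
  expect_lt(sd(smooth_trace(noisy)$F), 5)

  expect_error(smooth_trace(tr, window = 10), "odd")
  expect_error(smooth_trace(tr, window = 3, polyorder = 3), "odd|polyorder")
})

test_that("bleach correction flattens the baseline and keeps its level", {
  t <- 0:120
  tr <- calcein_trace(t, 500 - 0.5 * t, stimulus_onset = 30)
  bc <- bleach_correct(tr)
  expect_equal(attr(bc, "bleach_slope"), -0.5, tolerance = 1e-9)
  expect_equal(bc$F, rep(500, 121), tolerance = 1e-9)

  clean <- calcein_trace(t, rep(400, 121), stimulus_onset = 30)
  expect_equal(bleach_correct(clean)$F, clean$F, tolerance = 1e-12)

  short <- calcein_trace(0:40, rnorm(41) + 100, stimulus_onset = 2)
  expect_error(bleach_correct(short), "baseline")
})

test_that("bleach slope recovery attains the closed-form OLS accuracy", {
  # 30 baseline samples at noise sd 1% of F0 = 5: the OLS slope standard
  # error is sigma / sqrt(Sxx), so the median absolute error should sit
  # near 0.6745 * SE; assert recovery within twice that bound.
  tt <- 0:29
  se <- 5 / sqrt(sum((tt - mean(tt))^2))
  errs <- sapply(1:50, function(s) {
    tr <- gen_calcein_trace(F0_level = 500, bleach_slope = -0.5,
                            noise_sd = 1, seed = s)
    abs(attr(bleach_correct(tr$trace), "bleach_slope") - (-0.5))
  })
  expect_lt(median(errs), 2 * 0.6745 * se)
  # and noiseless recovery is exact
  tr0 <- gen_calcein_trace(F0_level = 500, bleach_slope = -0.5, noise_sd = 0)
  expect_equal(attr(bleach_correct(tr0$trace), "bleach_slope"), -0.5,
               tolerance = 1e-9)
})

test_that("normalization maps the baseline to 100% and is scale invariant", {
  t <- 0:120
  F <- c(rep(500, 30), rep(500, 91)); F[61:121] <- 700
  tr <- calcein_trace(t, F, stimulus_onset = 30)
  nm <- normalize_trace(tr)
  expect_equal(mean(nm$F[t < 30]), 100)
  expect_equal(max(nm$F), 140)
  nm2 <- normalize_trace(calcein_trace(t, 3.7 * F, stimulus_onset = 30))
  expect_equal(nm$F, nm2$F)
})

test_that("the full pipeline recovers noiseless swelling parameters", {
  tr <- gen_calcein_trace(F0_level = 500, Fmax_pct = 140, k_true = 0.5,
                          rvd_rate = log(2) / 30, bleach_slope = -0.3,
                          noise_sd = 0)
  fit <- analyze_trace(tr$trace)
  expect_false(fit$no_swelling)
  expect_lt(abs(fit$F_max / 140 - 1), 0.01)
  expect_lt(abs(fit$k / 0.5 - 1), 0.01)
  expect_lt(abs(fit$t0 / tr$truth$t0_true - 1), 0.01)
  expect_lt(abs(fit$t_s_max - tr$truth$t_s_max), 1)  # one sampling interval
  expect_lt(abs(fit$t_rvd_50 - 30), 2)
  expect_equal(fit$max_rate, fit$F_max * fit$k / 4, tolerance = 1e-9)
})

test_that("flat and bleach-only traces raise the no-swelling flag", {
  flat <- gen_calcein_trace(Fmax_pct = 100, noise_sd = 0)
  expect_true(analyze_trace(flat$trace)$no_swelling)
  bleachy <- gen_calcein_trace(Fmax_pct = 100, bleach_slope = -0.8, noise_sd = 0)
  expect_true(analyze_trace(bleachy$trace)$no_swelling)
})

test_that("swelling fit is invariant to rescaling the raw trace", {
  tr <- gen_calcein_trace(Fmax_pct = 130, k_true = 0.3, noise_sd = 1,
                          rvd_rate = log(2) / 40, seed = 12)
  f1 <- analyze_trace(tr$trace)
  scaled <- tr$trace
  scaled$F <- scaled$F * 4.2
  f2 <- analyze_trace(scaled)
  for (fld in c("F_max", "k", "t0", "t_s_max", "t_rvd_50"))
    expect_equal(f1[[fld]], f2[[fld]], tolerance = 1e-6)
})

test_that("RVD half-time matches exponential and linear closed forms", {
  t <- 0:120
  peak_t <- 50
  lam <- 0.0231
  F <- c(rep(100, 50), 100 + 40 * exp(-lam * (t[51:121] - peak_t)))
  tr <- calcein_trace(t, F, stimulus_onset = 30)
  rvd <- rvd_half_time(tr, peak_t)
  expect_false(rvd$censored)
  expect_lt(abs(rvd$t_rvd_50 - log(2) / lam), 0.5)

  Flin <- c(rep(100, 50), pmax(140 - 1 * (t[51:121] - peak_t), 100))
  rvdl <- rvd_half_time(calcein_trace(t, Flin, stimulus_onset = 30), peak_t)
  expect_equal(rvdl$t_rvd_50, 20)

  Fup <- c(rep(100, 50), 140 + 0.1 * (t[51:121] - peak_t))
  rvdc <- rvd_half_time(calcein_trace(t, Fup, stimulus_onset = 30), peak_t)
  expect_true(rvdc$censored)
})

test_that("noisy recovery: median k error < 10% at 2% noise", {
  # explicit midpoint 10 s after onset: the whole sigmoid rise is sampled
  errs <- sapply(1:50, function(s) {
    tr <- gen_calcein_trace(Fmax_pct = 140, k_true = 0.5, t0_true = 40,
                            noise_sd = 2, rvd_rate = log(2) / 30, seed = s)
    abs(analyze_trace(tr$trace)$k / 0.5 - 1)
  })
  expect_lt(median(errs), 0.10)
})
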