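## Group comparison (Mann-Whitney U with small-sample exact enumeration)
## and z-score expression regression.

#' Z-score expression matrix by gene (row)
#'
#' Per-gene standardization `(x - mean) / sd` with the sample SD (n - 1
#' denominator). Zero-variance rows are set to `NA` and flagged.
#'
#' @param mat numeric gene x sample matrix (>= 2 samples).
#' @return The z-scored matrix with attribute `zero_variance` (logical per
#'   row).
#' @export
zscore_rows <- function(mat) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2) stop("need at least 2 samples to z-score")
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  zero <- sdv == 0
  out <- (mat - mu) / ifelse(zero, NA, sdv)
  attr(out, "zero_variance") <- zero
  out
}

#' Regression of one z-scored gene on another
#'
#' Ordinary least squares of `y` on `x` with R-squared and the two-sided p
#' of the slope. On standardized variables the slope equals the Pearson
#' correlation and `slope^2 = R^2`.
#'
#' @param x,y numeric vectors of equal length >= 3 (typically z-scores).
#' @return A list with `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
regress_pair <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       n = length(x))
}

# Null distribution of U_a by full enumeration of rank placements.
mw_exact_null <- function(n_a, n_b) {
  n <- n_a + n_b
  combos <- utils::combn(n, n_a)
  ua <- colSums(combos) - n_a * (n_a + 1) / 2
  tabulate(ua + 1L, nbins = n_a * n_b + 1L) / ncol(combos)
}

#' Mann-Whitney U test
#'
#' Reports `U = min(U_a, U_b)` with midrank tie handling. For small
#' tie-free samples (`n_a + n_b <= max_exact`) the two-sided p-value is
#' exact, from full enumeration of all rank placements, doubling the
#' smaller tail (capped at 1); otherwise a normal approximation with tie
#' and continuity correction is used.
#'
#' @param a,b numeric samples (nonempty).
#' @param max_exact largest combined size for the exact path (default 12).
#' @return A list with `U`, `U_a`, `U_b`, `p`, and `method` (`"exact"` or
#'   `"normal_approx"`).
#' @export
mann_whitney <- function(a, b, max_exact = 12) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty")
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u_b <- n_a * n_b - u_a
  u <- min(u_a, u_b)
  ties <- any(duplicated(c(a, b)))
  if (!ties && n_a + n_b <= max_exact) {
    null <- mw_exact_null(n_a, n_b)
    lower <- sum(null[seq_len(u_a + 1)])
    upper <- sum(null[(u_a + 1):length(null)])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    n <- n_a + n_b
    tie_tab <- table(c(a, b))
    tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma <- sqrt(n_a * n_b / 12 * (n + 1 - tie_corr))
    z <- (u - mu + 0.5) / sigma  # continuity correction toward the mean
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal_approx"
  }
  list(U = u, U_a = u_a, U_b = u_b, p = p, method = method)
}

#' Median with bootstrap standard error
#'
#' Group summaries are reported as median plus a bootstrap standard error
#' of the median (the SE of a median has no standard closed form).
#'
#' @param x numeric sample.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return A list with `median` and `se`.
#' @export
median_boot_se <- function(x, n_boot = 1000, seed = NULL) {
  stopifnot(length(x) >= 2)
  meds <- with_seed(seed, vapply(seq_len(n_boot), function(i)
    stats::median(sample(x, replace = TRUE)), numeric(1)))
  list(median = stats::median(x), se = stats::sd(meds))
}
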