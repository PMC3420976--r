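#' Closed-form m-Tau peak delays over half-size-to-speed ratios
#'
#' The small-angle peak delay of m-Tau as a function of the stimulus ratio
#' \code{x = R / v}: \code{tc - t_hat = sqrt(x^2 + 2 x / mu)}.  The curve is
#' intrinsically nonlinear in \code{x}; its local slope
#' \code{(x + 1/mu) / sqrt(x^2 + 2 x / mu)} decreases toward one, and the
#' whole curve tends to the slope-one line \code{x} as \code{mu} grows.
#'
#' @param mu Leakage constant (rad/s), positive.
#' @param x_values Half-size-to-speed ratios (s), positive.
#' @return Peak delays (s), one per ratio.
#' @export
m_tau_peak_curve <- function(mu, x_values) {
  if (mu <= 0) stop("mu must be positive")
  if (any(x_values <= 0)) stop("x values must be positive")
  sqrt(x_values^2 + 2 * x_values / mu)
}

#' Noisify peak delays with ratio-proportional noise
#'
#' Adds centred Gaussian noise with standard deviation \code{c * x} to each
#' peak delay (the noise level grows with the stimulus ratio) and averages
#' \code{n_trials} draws per ratio, as in the simulated peak-time
#' measurements.
#'
#' @param delays Clean peak delays (s), one per ratio.
#' @param x_values Matching ratios (s).
#' @param noise_coeff_c Proportionality constant of the noise SD (>= 0).
#' @param n_trials Draws averaged per ratio.
#' @param seed Integer seed.
#' @return List with \code{means} (trial-mean delays) and \code{variances}
#'   (per-ratio sample variances of the draws; 0 when \code{n_trials = 1}).
#' @export
noisify_peaks <- function(delays, x_values, noise_coeff_c, n_trials = 25L,
                          seed = 1L) {
  if (length(delays) != length(x_values))
    stop("delays and x_values must have equal length")
  if (noise_coeff_c < 0) stop("noise_coeff_c must be >= 0")
  if (n_trials < 1L) stop("n_trials must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  means <- vars <- numeric(length(delays))
  for (i in seq_along(delays)) {
    draws <- delays[i] + (noise_coeff_c * x_values[i]) * stats::rnorm(n_trials)
    means[i] <- mean(draws)
    vars[i] <- if (n_trials > 1L) stats::var(draws) else 0
  }
  list(means = means, variances = vars)
}

#' Weighted least-squares line fit with residual diagnostics
#'
#' Fits \code{y = intercept + slope * x} by weighted least squares
#' (unit weights reduce exactly to OLS), and reports: the slope standard
#' error, weighted r-squared, a Kolmogorov-Smirnov-type (Lilliefors) test of
#' residual normality, and the overall-regression F test.
#'
#' @param x,y Data vectors, >= 3 points, \code{x} not collinear (non-constant).
#' @param weights Positive weights, conventionally 1/variance.
#' @return List of class \code{"line_fit"}: \code{slope}, \code{intercept},
#'   \code{slope_sd}, \code{r2}, \code{ks_stat_p} (residual-normality p),
#'   \code{f_p} (regression F-test p), \code{weights_used}.
#' @export
weighted_line_fit <- function(x, y, weights = rep(1, length(x))) {
  if (length(x) < 3L) stop("need >= 3 points")
  if (length(y) != length(x) || length(weights) != length(x))
    stop("x, y and weights must have equal length")
  if (any(weights <= 0)) stop("weights must be positive")
  if (diff(range(x)) == 0) stop("degenerate x: all values identical")
  fit <- stats::lm(y ~ x, weights = weights)
  sm <- suppressWarnings(summary(fit))
  resid_w <- stats::residuals(fit) * sqrt(weights)
  # Lilliefors = KS test with estimated mean/sd; needs > 4 residuals and
  # non-degenerate spread
  ks_p <- if (length(resid_w) >= 5L && stats::sd(resid_w) > 0) {
    suppressWarnings(nortest::lillie.test(resid_w)$p.value)
  } else NA_real_
  f <- sm$fstatistic
  f_p <- if (!is.null(f)) unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE))
         else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_sd = sm$coefficients[2, 2],
                 r2 = sm$r.squared,
                 ks_stat_p = ks_p,
                 f_p = f_p,
                 weights_used = !all(weights == weights[1]),
                 residuals = unname(resid_w)),
            class = "line_fit")
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf("Line fit: slope = %.5g (sd %.3g), intercept = %.5g, r2 = %.4f\n",
              x$slope, x$slope_sd, x$intercept, x$r2))
  cat(sprintf("  residual normality p = %.3g, regression F p = %.3g%s\n",
              x$ks_stat_p, x$f_p,
              if (x$weights_used) " [weighted]" else " [OLS]"))
  invisible(x)
}

#' Noise-masking experiment on the m-Tau peak nonlinearity
#'
#' Repeats \code{\link{noisify_peaks}} plus \code{\link{weighted_line_fit}}
#' (weights = 1 / variance of the trial means) on the closed-form m-Tau peak
#' curve.  Noise proportional to the stimulus ratio blurs the nonlinear
#' character of the peak curve and can make it appear linear: a repeat is
#' counted "masked" when residual normality is not rejected (p > 0.05) and
#' the regression F test is significant.
#'
#' @param mu Leakage constant (rad/s).
#' @param x_values Ratios (s); default 10 log-spaced points over one decade.
#' @param noise_coeff_c Noise proportionality constant (default 0.15).
#' @param n_trials Trials averaged per ratio per repeat.
#' @param n_repeats Number of independent repeats.
#' @param seed Integer seed.
#' @return List with \code{fits} (data frame: repeat, slope, intercept, r2,
#'   ks_p, f_p) and \code{masked_fraction}.
#' @export
masking_experiment <- function(mu, x_values = 10^seq(-2, -1, length.out = 10),
                               noise_coeff_c = 0.15, n_trials = 25L,
                               n_repeats = 100L, seed = 1L) {
  delays <- m_tau_peak_curve(mu, x_values)
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    np <- noisify_peaks(delays, x_values, noise_coeff_c, n_trials,
                        seed = derive_seed(seed, r))
    w <- if (all(np$variances > 0)) n_trials / np$variances
         else rep(1, length(x_values))
    lf <- weighted_line_fit(x_values, np$means, w)
    rows[[r]] <- data.frame(rep = r, slope = lf$slope,
                            intercept = lf$intercept, r2 = lf$r2,
                            ks_p = lf$ks_stat_p, f_p = lf$f_p)
  }
  fits <- do.call(rbind, rows)
  masked <- fits$ks_p > 0.05 & fits$f_p < 0.05
  list(fits = fits, masked_fraction = mean(masked, na.rm = TRUE))
}

#' One-standard-deviation covariance ellipse of intercept-slope pairs
#'
#' Centre = componentwise mean; axes = eigenvectors of the 2x2 sample
#' covariance matrix of the pairs, with lengths scaled by the square roots of
#' the associated eigenvalues so the ellipse encloses one standard deviation.
#'
#' @param pairs Two-column matrix or data frame of (intercept, slope) pairs,
#'   >= 2 non-identical rows.
#' @return List of class \code{"ellipse_summary"}: \code{center},
#'   \code{axis_lengths} (descending), \code{axis_directions} (orthonormal
#'   columns).
#' @export
intercept_slope_ellipse <- function(pairs) {
  m <- as.matrix(pairs)
  if (ncol(m) != 2L) stop("pairs must have two columns (intercept, slope)")
  if (nrow(m) < 2L) stop("need >= 2 pairs")
  if (all(m[, 1] == m[1, 1]) && all(m[, 2] == m[1, 2]))
    stop("all pairs identical; covariance undefined")
  cv <- stats::cov(m)
  eg <- eigen(cv, symmetric = TRUE)
  structure(list(center = colMeans(m),
                 axis_lengths = sqrt(pmax(eg$values, 0)),
                 axis_directions = eg$vectors),
            class = "ellipse_summary")
}
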