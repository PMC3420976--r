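#' Numeric peak of a sampled signal
#'
#' Grid argmax refined by three-point parabolic interpolation.  Interior
#' maxima are preferred over boundary values; a maximum on the first or last
#' sample is returned unrefined with \code{boundary = TRUE}.  Ties between
#' equal interior maxima break to the earliest sample.
#'
#' @param series Numeric signal, length >= 3.
#' @param times Sample times matching \code{series}.
#' @return A list of class \code{"peak_result"}: \code{t_peak},
#'   \code{value_peak}, \code{index}, \code{boundary} and \code{degenerate}
#'   flags.
#' @export
numeric_peak <- function(series, times) {
  n <- length(series)
  if (n < 3L) stop("need at least 3 samples for a numeric peak")
  if (length(times) != n) stop("series and times must have equal length")
  if (diff(range(series)) == 0) {
    return(structure(list(t_peak = times[1], value_peak = series[1],
                          index = 1L, boundary = TRUE, degenerate = TRUE),
                     class = "peak_result"))
  }
  i <- which.max(series)  # earliest maximum on ties
  if (i == 1L || i == n) {
    return(structure(list(t_peak = times[i], value_peak = series[i],
                          index = i, boundary = TRUE, degenerate = FALSE),
                     class = "peak_result"))
  }
  # parabola through (i-1, i, i+1); vertex offset in grid units
  y0 <- series[i - 1L]; y1 <- series[i]; y2 <- series[i + 1L]
  denom <- y0 - 2 * y1 + y2
  off <- if (denom == 0) 0 else 0.5 * (y0 - y2) / denom
  off <- max(min(off, 0.5), -0.5)
  dt <- times[2] - times[1]
  structure(list(t_peak = times[i] + off * dt,
                 value_peak = y1 - 0.25 * (y0 - y2) * off,
                 index = i, boundary = FALSE, degenerate = FALSE),
            class = "peak_result")
}

#' @export
print.peak_result <- function(x, ...) {
  cat(sprintf("Peak at t = %g s, value = %g%s%s\n", x$t_peak, x$value_peak,
              if (x$boundary) " [boundary]" else "",
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Closed-form m-Tau peak (small-angle approximation)
#'
#' Under the small-angle approximation \code{tau ~ tc - t}, the m-Tau
#' function of a constant-velocity approach peaks at distance
#' \code{d_hat = sqrt(R^2 + 2 R v / mu)}, i.e. at
#' \code{t_peak = tc - d_hat / v}.  The peak moves toward contact as
#' \code{mu} grows (and its value decreases); larger objects peak earlier
#' (size effect) and faster approaches at fixed tc peak later (velocity
#' effect).
#'
#' @param stim An \code{\link{approach_stimulus}}.
#' @param mu Leakage constant (rad/s), positive.
#' @return A \code{"peak_result"} with additional fields \code{d_hat} and
#'   \code{theta_at_peak}; \code{before_onset} is \code{TRUE} when the peak
#'   would precede approach onset (\code{t_peak < 0}).
#' @export
m_tau_peak_closed_form <- function(stim, mu) {
  if (mu <= 0) stop("mu must be positive for a finite m-Tau peak")
  R <- stim$half_size_R; v <- stim$speed_v
  d_hat <- sqrt(R^2 + 2 * R * v / mu)
  t_peak <- stim$collision_time_tc - d_hat / v
  value <- (d_hat / v) * (2 * R * v / (d_hat^2 + R^2)) /
    (mu + 2 * R * v / (d_hat^2 + R^2))
  structure(list(t_peak = t_peak, value_peak = value, d_hat = d_hat,
                 theta_at_peak = 2 * atan(R / d_hat),
                 boundary = FALSE, degenerate = FALSE,
                 before_onset = t_peak < 0),
            class = "peak_result")
}

#' Closed-form eta peak
#'
#' The eta function of a constant-velocity approach peaks exactly where
#' \code{d = alpha * R}, i.e. at angular size
#' \code{theta_peak = 2 * atan(1 / alpha)} independent of the half-size /
#' speed ratio, and at time \code{tc - (alpha * R / v + delay_delta)}.
#'
#' @param stim An \code{\link{approach_stimulus}}.
#' @param p An \code{\link{eta_params}}.
#' @return A \code{"peak_result"} with \code{theta_at_peak} and
#'   \code{before_onset} flag.
#' @export
eta_peak_closed_form <- function(stim, p) {
  if (p$alpha <= 0) stop("alpha must be positive")
  R <- stim$half_size_R; v <- stim$speed_v
  lead <- p$alpha * R / v + p$delay_delta
  t_peak <- stim$collision_time_tc - lead
  d_hat <- p$alpha * R
  theta_pk <- 2 * atan(1 / p$alpha)
  value <- p$amplitude_C * (2 * R * v / (d_hat^2 + R^2)) *
    exp(-p$alpha * theta_pk) + p$baseline
  structure(list(t_peak = t_peak, value_peak = value, d_hat = d_hat,
                 theta_at_peak = theta_pk, boundary = FALSE,
                 degenerate = FALSE, before_onset = t_peak < 0),
            class = "peak_result")
}

#' Critical distance ratios of the alternative looming functions
#'
#' \code{tau_min_ratio()} returns the constant \code{k} solving
#' \code{2 k atan(1/k) = 1}: the tau function of a clean approach attains its
#' minimum (and inverse tau its maximum) at distance \code{d = k R}, about
#' \code{0.43034 R}.  \code{theta_ddot_peak_ratio()} returns \code{1/sqrt(3)},
#' the analogous ratio for the angular-acceleration peak.  Both imply peak
#' delays linear in \code{R/v} with the ratio as slope.
#'
#' @return A single numeric constant.
#' @export
tau_min_ratio <- function() {
  stats::uniroot(function(k) 2 * k * atan(1 / k) - 1,
                 c(0.1, 0.9), tol = 1e-14)$root
}

#' @rdname tau_min_ratio
#' @export
theta_ddot_peak_ratio <- function() 1 / sqrt(3)
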