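#' Tau function
#'
#' Ratio of angular size to angular expansion rate, \code{tau = theta /
#' theta_dot}.  For small angular sizes of a constant-velocity approach it
#' approximates the remaining time to contact \code{tc - t} and decreases
#' approximately linearly with time.
#'
#' @param theta Angular size (rad), vectorised.
#' @param theta_dot Angular velocity (rad/s), vectorised; must be positive.
#' @return Tau in seconds.
#' @export
tau_fun <- function(theta, theta_dot) {
  if (any(theta_dot <= 0))
    stop("tau is undefined for theta_dot <= 0; filter or guard noisy inputs first")
  theta / theta_dot
}

#' Modified tau (m-Tau)
#'
#' \code{m_tau = theta / (mu + theta_dot)} with leakage constant \code{mu}
#' (rad/s).  Equals \code{tau} multiplied by the gain factor
#' \code{theta_dot / (mu + theta_dot)}, so \code{m_tau <= tau} pointwise and
#' \code{m_tau -> tau} as \code{mu -> 0}.  Unlike tau it has a maximum before
#' contact.
#'
#' @inheritParams tau_fun
#' @param mu Leakage constant (rad/s), non-negative.
#' @return m-Tau in seconds.
#' @export
m_tau_fun <- function(theta, theta_dot, mu) {
  if (mu < 0) stop("mu must be >= 0")
  if (any(mu + theta_dot <= 0)) stop("m_tau requires mu + theta_dot > 0")
  theta / (mu + theta_dot)
}

#' Correction term of the corrected m-Tau model
#'
#' \code{rho = mu * theta / (theta_dot * (mu + theta_dot) + eps)}.  With
#' \code{eps = 0} this is exactly \code{tau - m_tau}, a non-negative
#' correction restoring the ttc-estimation property of tau; \code{eps > 0}
#' guards the denominator against vanishing angular velocity.
#'
#' @inheritParams m_tau_fun
#' @param eps Small non-negative denominator guard.
#' @return Correction in seconds.
#' @export
correction_rho <- function(theta, theta_dot, mu, eps = 1e-12) {
  if (mu < 0) stop("mu must be >= 0")
  if (eps < 0) stop("eps must be >= 0")
  mu * theta / (theta_dot * (mu + theta_dot) + eps)
}

#' Eta function
#'
#' \code{eta = C * theta_dot * exp(-alpha * theta) + baseline}: the classical
#' model of collision-sensitive (LGMD/DCMD-like) responses.  On a
#' constant-velocity approach it has a single interior maximum, always at
#' angular size \code{2 * atan(1 / alpha)} regardless of the
#' half-size-to-speed ratio.
#'
#' @inheritParams tau_fun
#' @param p An \code{\link{eta_params}} parameter set.
#' @return Response values (arbitrary units).
#' @export
eta_fun <- function(theta, theta_dot, p) {
  p$amplitude_C * theta_dot * exp(-p$alpha * theta) + p$baseline
}

#' Eta-function parameter set
#'
#' @param alpha Dimensionless decay constant of the angular-size exponential,
#'   positive; fixes the peak angular size at \code{2 * atan(1/alpha)}.
#' @param amplitude_C Response scale, positive.
#' @param delay_delta Temporal delay (s) shifting the response relative to the
#'   stimulus.
#' @param baseline Response offset (accounts for nonzero baseline firing).
#' @return An object of class \code{"eta_params"}.
#' @export
eta_params <- function(alpha = 1, amplitude_C = 1, delay_delta = 0, baseline = 0) {
  if (alpha <= 0) stop("alpha must be positive")
  if (amplitude_C <= 0) stop("amplitude_C must be positive")
  structure(list(alpha = alpha, amplitude_C = amplitude_C,
                 delay_delta = delay_delta, baseline = baseline),
            class = "eta_params")
}

#' Inverse tau
#'
#' \code{theta_dot / theta}, the relative rate of expansion (1/s).  Its peak
#' on a clean approach lies at distance \code{d = k * R} with \code{k} the
#' root of \code{2 k atan(1/k) = 1} (about 0.42898), coinciding with the tau
#' minimum.
#'
#' @inheritParams tau_fun
#' @return Inverse tau in 1/s.
#' @export
inverse_tau_fun <- function(theta, theta_dot) {
  if (any(theta <= 0)) stop("inverse_tau is undefined for theta <= 0")
  theta_dot / theta
}

#' First-order discrete low-pass filter
#'
#' Exponential smoothing with memory coefficient \code{xi} in [0, 1):
#' \code{xhat[1] = init}, \code{xhat[k] = xi * xhat[k-1] + (1 - xi) * x[k]}
#' for \code{k >= 2}.  \code{xi = 0} reproduces the input (no memory);
#' \code{xi -> 1} approaches infinite memory (the filter never leaves its
#' initial state).
#'
#' @param series Numeric input signal, non-empty.
#' @param xi Memory coefficient in [0, 1).
#' @param init Initial filter state; defaults to the first sample so that no
#'   initial transient occurs.
#' @return Filtered signal, same length as the input.
#' @export
lowpass_filter <- function(series, xi, init = series[1]) {
  if (length(series) < 1L) stop("series must be non-empty")
  if (!is.numeric(xi) || length(xi) != 1L || xi < 0 || xi >= 1)
    stop("xi must be a single value in [0, 1)")
  n <- length(series)
  out <- numeric(n)
  out[1] <- init
  if (n > 1L) {
    out[2:n] <- stats::filter((1 - xi) * series[2:n], filter = xi,
                              method = "recursive", init = init)
  }
  out
}

# Column-wise low-pass over a matrix of trial signals; init per column.
lowpass_filter_mat <- function(m, xi, init = m[1, ]) {
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  out[1, ] <- init
  if (n > 1L) {
    f <- stats::filter((1 - xi) * m[-1, , drop = FALSE], filter = xi,
                       method = "recursive", init = matrix(init, 1))
    out[2:n, ] <- as.matrix(f)
  }
  out
}

#' Corrected-m-Tau parameter set
#'
#' The parameter set of the corrected modified tau (Xi) observer.
#'
#' @param mu Leakage constant (rad/s), non-negative.  Small \code{mu} drives
#'   Xi toward the ordinary tau limit, large \code{mu} toward tau on low-pass
#'   filtered variables.
#' @param w Dimensionless weight on the low-pass-filtered correction term;
#'   \code{w = 0} recovers m-Tau (eta-like peaked behaviour), \code{w = 1}
#'   recovers tau in the no-filter limit (ttc estimation).
#' @param xi_theta,xi_theta_dot Filter memory coefficients in [0, 1) for
#'   angular size and angular velocity.
#' @param kappa Additive offset (s); negligible in practice, kept for the
#'   optimization module.
#' @param eps Small positive denominator guard (default 1e-12) avoiding
#'   division-by-zero in simulation.
#' @return An object of class \code{"xi_params"}.
#' @export
xi_params <- function(mu = 1, w = 1, xi_theta = 0.75, xi_theta_dot = 0.75,
                      kappa = 0, eps = 1e-12) {
  if (mu < 0) stop("mu must be >= 0")
  if (w < 0) stop("w must be >= 0")
  if (xi_theta < 0 || xi_theta >= 1) stop("xi_theta must be in [0, 1)")
  if (xi_theta_dot < 0 || xi_theta_dot >= 1) stop("xi_theta_dot must be in [0, 1)")
  if (eps <= 0) stop("eps must be positive")
  structure(list(mu = mu, w = w, xi_theta = xi_theta,
                 xi_theta_dot = xi_theta_dot, kappa = kappa, eps = eps),
            class = "xi_params")
}

#' @export
print.xi_params <- function(x, ...) {
  cat(sprintf(
    "Xi parameters: mu = %g rad/s, w = %g, xi_theta = %g, xi_theta_dot = %g, kappa = %g s, eps = %g\n",
    x$mu, x$w, x$xi_theta, x$xi_theta_dot, x$kappa, x$eps))
  invisible(x)
}

#' Corrected modified tau (Xi) on a trace
#'
#' Evaluates \code{Xi[k] = theta[k] / (mu + theta_dot[k]) +
#' w * mu * lp_theta[k] / (lp_theta_dot[k] * (mu + lp_theta_dot[k]) + eps) +
#' kappa}, where \code{lp_theta} and \code{lp_theta_dot} are the low-pass
#' filtered angular variables (filters initialised with the first trace
#' samples).  The m-Tau head term keeps the raw variables; only the
#' correction term sees filtered ones, which is what makes Xi noise-robust.
#'
#' Identities: with \code{w = 1}, \code{xi_theta = xi_theta_dot = 0},
#' \code{eps = 0-limit} and \code{kappa = 0}, Xi equals tau sample by sample;
#' with \code{w = 0}, \code{kappa = 0} it equals m-Tau.
#'
#' On noisy traces samples with \code{mu + theta_dot <= 0} are evaluated with
#' the eps-guarded denominator and flagged in the \code{"guarded"} attribute.
#'
#' @param trace An \code{\link{optical_trace}}.
#' @param params An \code{\link{xi_params}}.
#' @return Numeric vector of Xi values (seconds), one per trace sample, with
#'   attribute \code{"guarded"} giving indices where the head-term denominator
#'   needed guarding.
#' @export
corrected_m_tau <- function(trace, params) {
  stopifnot(inherits(trace, "optical_trace"), inherits(params, "xi_params"))
  th <- trace$theta; thd <- trace$theta_dot
  mu <- params$mu; eps <- params$eps
  den1 <- mu + thd
  bad <- which(den1 <= 0)
  if (length(bad)) den1[bad] <- eps
  lp_th <- lowpass_filter(th, params$xi_theta)
  lp_thd <- lowpass_filter(thd, params$xi_theta_dot)
  xi <- th / den1 +
    params$w * mu * lp_th / (lp_thd * (mu + lp_thd) + eps) +
    params$kappa
  attr(xi, "guarded") <- bad
  xi
}

# Vectorised-across-trials Xi on matrices of noisy angular variables.
corrected_m_tau_mat <- function(theta_m, theta_dot_m, params) {
  mu <- params$mu; eps <- params$eps
  den1 <- mu + theta_dot_m
  den1[den1 <= 0] <- eps
  lp_th <- lowpass_filter_mat(theta_m, params$xi_theta)
  lp_thd <- lowpass_filter_mat(theta_dot_m, params$xi_theta_dot)
  theta_m / den1 +
    params$w * mu * lp_th / (lp_thd * (mu + lp_thd) + eps) +
    params$kappa
}

#' Tau on low-pass filtered optical variables
#'
#' \code{lp_theta / lp_theta_dot} per sample: the large-\code{mu} limit
#' function of the corrected m-Tau model.  With strong filtering it has
#' excellent noise suppression; with \code{xi = 0} it reduces to ordinary
#' tau (whose noise suppression is poor).
#'
#' @param trace An \code{\link{optical_trace}}.
#' @param xi_theta,xi_theta_dot Filter memory coefficients in [0, 1).
#' @return Numeric vector in seconds.
#' @export
lp_tau <- function(trace, xi_theta, xi_theta_dot) {
  stopifnot(inherits(trace, "optical_trace"))
  lp_th <- lowpass_filter(trace$theta, xi_theta)
  lp_thd <- lowpass_filter(trace$theta_dot, xi_theta_dot)
  if (any(lp_thd <= 0))
    stop("filtered angular velocity non-positive; lp_tau undefined")
  lp_th / lp_thd
}

#' Evaluate looming functions on a trace
#'
#' Convenience wrapper returning a data frame with the requested function
#' columns evaluated sample-by-sample, in the trace CSV dialect.
#'
#' @param trace An \code{\link{optical_trace}}.
#' @param functions Character vector among \code{"tau"}, \code{"m_tau"},
#'   \code{"xi"}, \code{"eta"}, \code{"inv_tau"}.
#' @param xi An \code{\link{xi_params}} (for \code{m_tau} and \code{xi}).
#' @param eta An \code{\link{eta_params}} (for \code{eta}).
#' @return A data frame with \code{time_s}, the angular variables and one
#'   column per evaluated function (\code{tau_s}, \code{m_tau_s}, \code{xi_s},
#'   \code{eta_au}, \code{inv_tau_per_s}).
#' @export
evaluate_functions <- function(trace, functions = c("tau", "m_tau", "xi"),
                               xi = xi_params(), eta = eta_params()) {
  df <- as.data.frame(trace)
  for (f in functions) {
    df[[switch(f, tau = "tau_s", m_tau = "m_tau_s", xi = "xi_s",
               eta = "eta_au", inv_tau = "inv_tau_per_s",
               stop("unknown function: ", f))]] <-
      switch(f,
             tau = tau_fun(trace$theta, trace$theta_dot),
             m_tau = m_tau_fun(trace$theta, trace$theta_dot, xi$mu),
             xi = as.numeric(corrected_m_tau(trace, xi)),
             eta = eta_fun(trace$theta, trace$theta_dot, eta),
             inv_tau = inverse_tau_fun(trace$theta, trace$theta_dot))
  }
  df
}
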