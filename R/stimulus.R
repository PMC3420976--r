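#' Rigid-sphere approach stimulus
#'
#' Describes a rigid sphere of half-size (radius) \code{R} approaching the
#' observer on a direct collision course at constant speed \code{v}.  The
#' approach starts at \code{t = 0} and contact occurs at \code{t = tc}, so the
#' initial object-observer distance is \code{d0 = v * tc}.
#'
#' @param half_size_R Object half-size (radius) in metres; alternatively give
#'   \code{diameter} (converted as \code{R = diameter / 2}).
#' @param speed_v Approach speed in m/s, positive.
#' @param collision_time_tc Time of contact in seconds, positive.
#' @param dt Sampling step in seconds; default 1 ms, which resolves all filter
#'   dynamics used in this package.
#' @param diameter Object diameter in metres (used only when
#'   \code{half_size_R} is missing).
#'
#' @return An object of class \code{"approach_stimulus"}: a list with elements
#'   \code{half_size_R}, \code{speed_v}, \code{collision_time_tc}, \code{dt}
#'   and the derived \code{initial_distance_d0}.
#' @examples
#' stim <- approach_stimulus(half_size_R = 0.05, speed_v = 2, collision_time_tc = 3)
#' stim$initial_distance_d0  # 6 m
#' @export
approach_stimulus <- function(half_size_R = NULL, speed_v, collision_time_tc,
                              dt = 0.001, diameter = NULL) {
  if (is.null(half_size_R)) {
    if (is.null(diameter)) stop("give either 'half_size_R' or 'diameter'")
    half_size_R <- diameter / 2
  }
  stopifnot(is.numeric(half_size_R), length(half_size_R) == 1L,
            is.numeric(speed_v), length(speed_v) == 1L,
            is.numeric(collision_time_tc), length(collision_time_tc) == 1L,
            is.numeric(dt), length(dt) == 1L)
  if (half_size_R <= 0) stop("half_size_R must be positive")
  if (speed_v <= 0) stop("speed_v must be positive")
  if (collision_time_tc <= 0) stop("collision_time_tc must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (dt >= collision_time_tc) stop("dt must be smaller than collision_time_tc")
  structure(
    list(half_size_R = half_size_R,
         speed_v = speed_v,
         collision_time_tc = collision_time_tc,
         dt = dt,
         initial_distance_d0 = speed_v * collision_time_tc),
    class = "approach_stimulus")
}

#' @export
print.approach_stimulus <- function(x, ...) {
  cat("Approach stimulus (rigid sphere, constant velocity)\n")
  cat(sprintf("  half-size R : %g m   (diameter %g m)\n",
              x$half_size_R, 2 * x$half_size_R))
  cat(sprintf("  speed v     : %g m/s\n", x$speed_v))
  cat(sprintf("  contact tc  : %g s   (initial distance d0 = %g m)\n",
              x$collision_time_tc, x$initial_distance_d0))
  cat(sprintf("  dt          : %g s\n", x$dt))
  invisible(x)
}

check_pre_collision <- function(stim, t) {
  if (any(t < 0)) stop("time before approach onset (t < 0)")
  if (any(t >= stim$collision_time_tc)) stop("post-collision time (t >= tc)")
  invisible(TRUE)
}

#' Object-observer distance during the approach
#'
#' \code{d(t) = v * (tc - t)} for a constant-velocity direct approach.
#'
#' @param stim An \code{\link{approach_stimulus}}.
#' @param t Time(s) in seconds, \code{0 <= t < tc}.
#' @return Distance(s) in metres.
#' @export
distance <- function(stim, t) {
  check_pre_collision(stim, t)
  stim$speed_v * (stim$collision_time_tc - t)
}

#' Angular size of the approaching sphere
#'
#' The full visual angle subtended by a sphere of half-size \code{R} at
#' distance \code{d}: \code{theta(t) = 2 * atan(R / d(t))}, in radians.
#'
#' @inheritParams distance
#' @return Angular size(s) in radians, in (0, pi).
#' @export
angular_size <- function(stim, t) {
  2 * atan(stim$half_size_R / distance(stim, t))
}

#' Rate of angular expansion
#'
#' Time derivative of \code{\link{angular_size}}:
#' \code{theta_dot(t) = 2 R v / (d(t)^2 + R^2)}, in rad/s.
#'
#' @inheritParams distance
#' @return Angular velocity(ies) in rad/s, positive before contact.
#' @export
angular_velocity <- function(stim, t) {
  d <- distance(stim, t)
  2 * stim$half_size_R * stim$speed_v / (d^2 + stim$half_size_R^2)
}

#' Angular acceleration
#'
#' Time derivative of \code{\link{angular_velocity}}:
#' \code{theta_ddot(t) = 4 R v^2 d / (d^2 + R^2)^2}.  Along an approach it
#' peaks where \code{d = R / sqrt(3)}.
#'
#' @inheritParams distance
#' @return Angular acceleration(s) in rad/s^2.
#' @export
angular_acceleration <- function(stim, t) {
  d <- distance(stim, t)
  R <- stim$half_size_R
  4 * R * stim$speed_v^2 * d / (d^2 + R^2)^2
}

#' Sample a clean optical trace of an approach
#'
#' Evaluates the closed-form optical variables on a uniform time grid
#' \code{seq(t_start, t_end, by = stim$dt)}.
#'
#' @inheritParams distance
#' @param t_start,t_end Window bounds in seconds, \code{0 <= t_start < t_end < tc}.
#' @param include_ddot Also sample angular acceleration?
#' @return An \code{\link{optical_trace}} with \code{is_noisy = FALSE}.
#' @examples
#' stim <- approach_stimulus(0.05, 1, 2, dt = 0.01)
#' tr <- generate_trace(stim, 0, 1.5)
#' head(as.data.frame(tr))
#' @export
generate_trace <- function(stim, t_start = 0,
                           t_end = stim$collision_time_tc - stim$dt,
                           include_ddot = FALSE) {
  if (t_start < 0) stop("t_start must be >= 0")
  if (t_end >= stim$collision_time_tc) stop("t_end must be < collision_time_tc")
  if (t_end <= t_start) stop("empty time grid (t_end <= t_start)")
  times <- seq(t_start, t_end, by = stim$dt)
  optical_trace(
    times = times,
    theta = angular_size(stim, times),
    theta_dot = angular_velocity(stim, times),
    theta_ddot = if (include_ddot) angular_acceleration(stim, times) else NULL,
    is_noisy = FALSE,
    stim = stim)
}

#' Time-indexed optical trace
#'
#' Container for sampled angular size and angular velocity (optionally
#' angular acceleration) of an approach, clean or noisified.
#'
#' @param times Strictly increasing, uniformly spaced sample times (s).
#' @param theta Angular size per sample (rad).
#' @param theta_dot Angular velocity per sample (rad/s).
#' @param theta_ddot Optional angular acceleration per sample (rad/s^2).
#' @param is_noisy Has noise been applied to this trace?
#' @param stim Optional originating \code{\link{approach_stimulus}}.
#' @return An object of class \code{"optical_trace"}.
#' @export
optical_trace <- function(times, theta, theta_dot, theta_ddot = NULL,
                          is_noisy = FALSE, stim = NULL) {
  n <- length(times)
  if (n < 2L) stop("an optical trace needs at least 2 samples")
  if (length(theta) != n || length(theta_dot) != n)
    stop("times, theta and theta_dot must have equal length")
  if (!is.null(theta_ddot) && length(theta_ddot) != n)
    stop("theta_ddot must match the trace length")
  dts <- diff(times)
  if (any(dts <= 0)) stop("times must be strictly increasing")
  if (max(dts) - min(dts) > 1e-9 * max(dts))
    stop("times must be uniformly spaced")
  structure(
    list(times = times, theta = theta, theta_dot = theta_dot,
         theta_ddot = theta_ddot, is_noisy = isTRUE(is_noisy), stim = stim),
    class = "optical_trace")
}

#' @export
print.optical_trace <- function(x, ...) {
  cat(sprintf("Optical trace: %d samples, t in [%g, %g] s, dt = %g s%s%s\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              x$times[2] - x$times[1],
              if (x$is_noisy) ", noisy" else ", clean",
              if (is.null(x$theta_ddot)) "" else ", with theta_ddot"))
  invisible(x)
}

#' @export
as.data.frame.optical_trace <- function(x, ...) {
  df <- data.frame(time_s = x$times, theta_rad = x$theta,
                   theta_dot_rad_s = x$theta_dot)
  if (!is.null(x$theta_ddot)) df$theta_ddot_rad_s2 <- x$theta_ddot
  df
}
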