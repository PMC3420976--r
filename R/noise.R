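#' Noise specification for optical variables
#'
#' Describes how angular size and angular velocity are noisified, with
#' reproducible randomness.  Noise deviates are drawn per sample from a
#' centred normal distribution, independently for the two channels.
#'
#' In \code{"relative"} mode (default) \code{x_noisy = x * (1 + p * N)}:
#' the noise level scales with the signal, so the signal-to-noise ratio is
#' constant along the approach and smaller objects carry proportionally the
#' same blur at every distance.  In \code{"absolute"} mode
#' \code{x_noisy = x + p * N}: the SNR improves as the object looms.
#'
#' @param p_theta Noise level for angular size, in [0, 1].
#' @param p_theta_dot Noise level for angular velocity, in [0, 1].
#' @param mode \code{"relative"} (multiplicative) or \code{"absolute"}
#'   (additive).
#' @param seed Integer seed; the per-trial, per-channel streams are derived
#'   deterministically from it.
#' @param floor_at_zero Clip noisified values at zero?
#' @return An object of class \code{"noise_spec"}.
#' @export
noise_spec <- function(p_theta = 0, p_theta_dot = 0,
                       mode = c("relative", "absolute"),
                       seed = 1L, floor_at_zero = FALSE) {
  mode <- match.arg(mode)
  if (p_theta < 0 || p_theta > 1) stop("p_theta must be in [0, 1]")
  if (p_theta_dot < 0 || p_theta_dot > 1) stop("p_theta_dot must be in [0, 1]")
  structure(list(p_theta = p_theta, p_theta_dot = p_theta_dot, mode = mode,
                 seed = as.integer(seed), floor_at_zero = isTRUE(floor_at_zero)),
            class = "noise_spec")
}

# Deterministic 31-bit sub-seed from a base seed and stream indices.
# SplitMix-style integer mixing in double arithmetic (exact below 2^53).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.numeric(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(s)
}

#' Noisify an optical trace
#'
#' Applies the noise model of a \code{\link{noise_spec}} to a clean trace,
#' independently per channel.  The same spec (same seed) always produces an
#' identical output; noisifying an already-noisy trace is an error.
#'
#' @param trace A clean \code{\link{optical_trace}}.
#' @param spec A \code{\link{noise_spec}}.
#' @param trial_index Optional trial number; distinct trials get
#'   deterministically split, reproducible sub-streams.
#' @return A noisified \code{\link{optical_trace}} (\code{is_noisy = TRUE}).
#' @export
noisify_trace <- function(trace, spec, trial_index = 0L) {
  stopifnot(inherits(trace, "optical_trace"), inherits(spec, "noise_spec"))
  if (trace$is_noisy) stop("trace is already noisy; refusing double noisification")
  n <- length(trace$times)
  th <- noisify_channel(trace$theta, spec$p_theta, spec$mode,
                        derive_seed(spec$seed, trial_index, 1L), n)
  thd <- noisify_channel(trace$theta_dot, spec$p_theta_dot, spec$mode,
                         derive_seed(spec$seed, trial_index, 2L), n)
  if (spec$floor_at_zero) {
    th <- pmax(th, 0)
    thd <- pmax(thd, 0)
  }
  optical_trace(trace$times, th, thd, theta_ddot = NULL,
                is_noisy = TRUE, stim = trace$stim)
}

noisify_channel <- function(x, p, mode, seed, n) {
  if (p == 0) return(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nrm <- stats::rnorm(n)
  if (mode == "relative") x * (1 + p * nrm) else x + p * nrm
}

# Save/restore the global RNG state so seeded helpers do not disturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Matrix of noisified channel values for n_trials trials (columns), each
# trial with its own derived sub-stream; used by the vectorised simulator.
noisify_channel_trials <- function(x, p, mode, spec_seed, channel_id,
                                   trial_indices) {
  n <- length(x)
  m <- matrix(x, n, length(trial_indices))
  if (p == 0) return(m)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (j in seq_along(trial_indices)) {
    set.seed(derive_seed(spec_seed, trial_indices[j], channel_id))
    nrm <- stats::rnorm(n)
    m[, j] <- if (mode == "relative") x * (1 + p * nrm) else x + p * nrm
  }
  m
}
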