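test_that("tau, m_tau and rho satisfy their algebraic identities", {
  expect_equal(tau_fun(0.1, 0.05), 2)
  expect_equal(m_tau_fun(0.1, 0.05, 0.05), 1)
  expect_equal(correction_rho(0.1, 0.05, 0.05, eps = 0), 1)
  expect_equal(m_tau_fun(0.1, 0.05, 0), tau_fun(0.1, 0.05))
  expect_equal(correction_rho(0.3, 0.1, 0, eps = 0), 0)
  # guard behaviour: zero angular velocity stays finite with eps > 0
  expect_true(is.finite(correction_rho(0.1, 0, 0.5, eps = 1e-12)))
  expect_error(tau_fun(0.1, 0), "undefined")

  # pointwise on a whole trace: m_tau <= tau, rho >= 0, rho = tau - m_tau
  tr <- generate_trace(std_stim(), 0, 2.9)
  tau <- tau_fun(tr$theta, tr$theta_dot)
  for (mu in c(0.1, 1, 10)) {
    mt <- m_tau_fun(tr$theta, tr$theta_dot, mu)
    rho <- correction_rho(tr$theta, tr$theta_dot, mu, eps = 0)
    expect_true(all(mt <= tau))
    expect_true(all(rho >= 0))
    expect_equal(rho, tau - mt, tolerance = 1e-12)
  }
})

test_that("tau of a small-angle clean trace approximates remaining time", {
  s <- approach_stimulus(0.01, 1, 2, dt = 1e-3)
  t <- 1
  tau <- tau_fun(angular_size(s, t), angular_velocity(s, t))
  # closed-form oracle: 2*atan(R/d)*(d^2+R^2)/(2Rv) at R=0.01, d=1, v=1
  expect_equal(tau, 2 * atan(0.01) * 1.0001 / 0.02, tolerance = 1e-12)
  expect_equal(tau, 1.0000667, tolerance = 1e-6)
  expect_equal(tau, s$collision_time_tc - t, tolerance = 1e-4)
})

test_that("low-pass filter implements the stated recursion", {
  x <- c(1, 2, 3, 4)
  expect_equal(lowpass_filter(x, 0), x)
  expect_equal(lowpass_filter(rep(3, 10), 0.7), rep(3, 10))
  # unit step from init = 0: xhat[k] = 1 - xi^k  (independent loop oracle)
  xi <- 0.8; n <- 50
  ref <- numeric(n); ref[1] <- 0
  for (k in 2:n) ref[k] <- xi * ref[k - 1] + (1 - xi) * 1
  expect_equal(lowpass_filter(rep(1, n), xi, init = 0), ref, tolerance = 1e-14)
  expect_equal(ref[n], 1 - xi^(n - 1), tolerance = 1e-12)
  expect_error(lowpass_filter(x, 1), "\\[0, 1\\)")
  expect_error(lowpass_filter(x, -0.1), "\\[0, 1\\)")
})

test_that("matrix low-pass agrees with the per-column scalar filter", {
  set.seed(5)
  m <- matrix(rnorm(60), 20, 3)
  out <- loomtau:::lowpass_filter_mat(m, 0.6)
  for (j in 1:3) expect_equal(out[, j], lowpass_filter(m[, j], 0.6))
})

test_that("corrected m-Tau reduces to tau and m-Tau in its limit cases", {
  tr <- generate_trace(std_stim(R = 0.03, v = 1.5, tc = 2.5), 0, 2.4)
  tau <- tau_fun(tr$theta, tr$theta_dot)
  # w = 1, no filtering, eps negligible, kappa = 0  ->  tau
  xi1 <- corrected_m_tau(tr, xi_params(mu = 0.7, w = 1, xi_theta = 0,
                                       xi_theta_dot = 0, eps = 1e-300))
  expect_equal(as.numeric(xi1), tau, tolerance = 1e-12)
  # w = 0, kappa = 0  ->  m_tau
  xi0 <- corrected_m_tau(tr, xi_params(mu = 0.7, w = 0))
  expect_equal(as.numeric(xi0), m_tau_fun(tr$theta, tr$theta_dot, 0.7),
               tolerance = 1e-12)
  # kappa shifts additively
  xik <- corrected_m_tau(tr, xi_params(mu = 0.7, w = 0, kappa = 0.25))
  expect_equal(as.numeric(xik) - as.numeric(xi0), rep(0.25, length(tau)))
})

test_that("large mu drives Xi to the filtered-tau limit function", {
  tr <- generate_trace(std_stim(), 0.5, 2.8)
  mu_big <- 1e3 * max(tr$theta_dot)
  xi <- corrected_m_tau(tr, xi_params(mu = mu_big, w = 1, xi_theta = 0.9,
                                      xi_theta_dot = 0.9))
  ref <- lp_tau(tr, 0.9, 0.9)
  rel <- abs(as.numeric(xi) - ref) / ref
  expect_lt(max(rel), 10 * max(tr$theta_dot) / mu_big)
})

test_that("lp_tau reduces to tau without filtering and lags with it", {
  tr <- generate_trace(std_stim(), 0, 2.9)
  expect_equal(lp_tau(tr, 0, 0), tau_fun(tr$theta, tr$theta_dot))
  # filter lag: lp_tau >= tau while tau shrinks
  lt <- lp_tau(tr, 0.9, 0.9)
  tau <- tau_fun(tr$theta, tr$theta_dot)
  expect_true(all(lt[-1] >= tau[-1]))
})

test_that("noise suppression: variance ordering lp_tau < Xi < tau", {
  s <- std_stim(R = 0.05, v = 2, tc = 3)
  tr <- generate_trace(s, 1.0, 2.5)
  nz <- noise_spec(0.1, 0.1, seed = 21)
  i_win <- seq(round(length(tr$times) * 0.4), round(length(tr$times) * 0.9))
  # probe mu values spanning small -> large relative to the theta_dot scale
  mus <- c(0.002, 0.02, 0.2)
  v_tau <- v_lp <- numeric(100)
  v_xi <- matrix(0, 100, length(mus))
  for (k in 1:100) {
    ntr <- noisify_trace(tr, nz, trial_index = k)
    thd_ok <- pmax(ntr$theta_dot, 1e-9)
    v_tau[k] <- stats::var((ntr$theta / thd_ok)[i_win])
    v_lp[k] <- stats::var(lp_tau(ntr, 0.99, 0.99)[i_win])
    for (j in seq_along(mus)) {
      xi <- corrected_m_tau(ntr, xi_params(mu = mus[j], w = 1,
                                           xi_theta = 0.99,
                                           xi_theta_dot = 0.99))
      v_xi[k, j] <- stats::var(as.numeric(xi)[i_win])
    }
  }
  # Xi variance decreases monotonically in mu, from the tau limit toward
  # the filtered-tau limit
  expect_true(all(diff(colMeans(v_xi)) < 0))
  expect_lt(mean(v_lp), mean(v_xi[, 2]))
  expect_lt(mean(v_xi[, 2]), mean(v_tau))
  expect_lt(max(colMeans(v_xi)), mean(v_tau))
  expect_gt(min(colMeans(v_xi)), mean(v_lp) * 0.99)
})

test_that("eta degenerates to theta_dot as alpha -> 0 and peaks correctly", {
  tr <- generate_trace(std_stim(), 0, 2.9)
  p0 <- eta_params(alpha = 1e-300, amplitude_C = 1, baseline = 0)
  expect_equal(eta_fun(tr$theta, tr$theta_dot, p0), tr$theta_dot,
               tolerance = 1e-12)
  expect_equal(inverse_tau_fun(0.2, 0.1), 0.5)
})

test_that("eta peak occurs at distance alpha*R, theta independent of speed", {
  for (alpha in c(1, 2)) {
    p <- eta_params(alpha = alpha)
    for (v in c(1, 3)) {
      s <- approach_stimulus(0.05, v, 3, dt = 1e-4)
      R <- s$half_size_R
      # independent brute-force oracle over distance
      d_star <- brute_force_argmax_d(function(d) {
        th <- 2 * atan(R / d); thd <- 2 * R * v / (d^2 + R^2)
        thd * exp(-alpha * th)
      }, d_max = 10 * R, n = 1e4)
      expect_equal(d_star, alpha * R, tolerance = 2e-3)
      pk <- eta_peak_closed_form(s, p)
      expect_equal(pk$theta_at_peak, 2 * atan(1 / alpha), tolerance = 1e-12)
      expect_equal(s$collision_time_tc - pk$t_peak, alpha * R / v,
                   tolerance = 1e-12)
    }
  }
  # alpha = 1, R = 0.05, v = 1: theta_peak = pi/2, lead time 0.05 s
  pk <- eta_peak_closed_form(approach_stimulus(0.05, 1, 3), eta_params(1))
  expect_equal(pk$theta_at_peak, pi / 2)
  expect_equal(3 - pk$t_peak, 0.05)
  # alpha = 2, R = 0.04, v = 1: lead 0.08 s
  pk2 <- eta_peak_closed_form(approach_stimulus(0.04, 1, 3), eta_params(2))
  expect_equal(3 - pk2$t_peak, 0.08)
})

test_that("m-Tau closed-form peak matches the numeric argmax and effect signs", {
  s <- approach_stimulus(0.05, 2, 3, dt = 1e-4)
  pk <- m_tau_peak_closed_form(s, mu = 1)
  expect_equal(pk$d_hat, 0.45)
  expect_equal(s$collision_time_tc - pk$t_peak, 0.225)
  # numeric argmax of the small-angle series within one dt
  tr <- generate_trace(s, 0, 3 - s$dt)
  sa <- (s$collision_time_tc - tr$times) * tr$theta_dot / (1 + tr$theta_dot)
  np <- numeric_peak(sa, tr$times)
  expect_lt(abs(np$t_peak - pk$t_peak), s$dt)
  # size effect: doubling R advances the peak
  pk_2R <- m_tau_peak_closed_form(approach_stimulus(0.10, 2, 3), 1)
  expect_lt(pk_2R$t_peak, pk$t_peak)
  # velocity effect: doubling v (and d0) at fixed tc delays the peak
  pk_2v <- m_tau_peak_closed_form(approach_stimulus(0.05, 4, 3), 1)
  expect_gt(pk_2v$t_peak, pk$t_peak)
  # mu monotonicity: later peaks are lower
  mus <- c(0.25, 0.5, 1, 2, 4)
  pks <- lapply(mus, function(m) m_tau_peak_closed_form(s, m))
  expect_true(all(diff(sapply(pks, `[[`, "t_peak")) > 0))
  expect_true(all(diff(sapply(pks, `[[`, "value_peak")) < 0))
  # peak preceding onset is flagged
  expect_true(m_tau_peak_closed_form(approach_stimulus(0.5, 0.1, 1), 1e-4)$before_onset)
})

test_that("tau minimum and inverse-tau maximum share the critical distance", {
  k <- tau_min_ratio()
  expect_equal(2 * k * atan(1 / k), 1, tolerance = 1e-12)
  R <- 0.05; v <- 1
  d_min_tau <- brute_force_argmax_d(function(d) {
    -(2 * atan(R / d)) * (d^2 + R^2) / (2 * R * v)
  }, d_max = 3 * R, n = 1e4)
  d_max_inv <- brute_force_argmax_d(function(d) {
    (2 * R * v / (d^2 + R^2)) / (2 * atan(R / d))
  }, d_max = 3 * R, n = 1e4)
  expect_equal(d_min_tau, k * R, tolerance = 2e-3)
  expect_equal(d_max_inv, k * R, tolerance = 2e-3)
  expect_equal(d_min_tau, d_max_inv, tolerance = 1e-9)
})

test_that("numeric_peak refines parabolic vertices and flags edge cases", {
  # parabola with vertex between grid points
  t <- seq(0, 1, by = 0.01)
  vertex <- 0.5037
  y <- -(t - vertex)^2
  pk <- numeric_peak(y, t)
  expect_lt(abs(pk$t_peak - vertex), 0.001)  # < 0.1 * dt
  expect_false(pk$boundary)
  # monotone series -> boundary flag
  pk_b <- numeric_peak(t, t)
  expect_true(pk_b$boundary)
  # tie between equal interior maxima -> earliest
  y2 <- c(0, 1, 0, 1, 0)
  expect_equal(numeric_peak(y2, 1:5)$index, 2L)
  # all-equal series -> degenerate
  expect_true(numeric_peak(rep(2, 5), 1:5)$degenerate)
})

test_that("slope of the m-Tau peak delay vs R/v tends to one as mu grows", {
  # local slope d(tc - t_hat)/dx at x, from the closed form, over 4 decades
  x <- 0.05
  slopes <- sapply(10^(1:4), function(mu) {
    h <- 1e-6
    (m_tau_peak_curve(mu, x + h) - m_tau_peak_curve(mu, x - h)) / (2 * h)
  })
  expect_true(all(diff(slopes) < 0))      # monotone in mu toward 1
  expect_equal(slopes[4], 1, tolerance = 0.01)
})

test_that("function evaluation exports the documented columns", {
  tr <- generate_trace(std_stim(dt = 0.01), 0, 2)
  df <- evaluate_functions(tr, c("tau", "m_tau", "xi", "eta", "inv_tau"))
  expect_true(all(c("tau_s", "m_tau_s", "xi_s", "eta_au", "inv_tau_per_s")
                  %in% names(df)))
  expect_equal(df$tau_s, tau_fun(tr$theta, tr$theta_dot))
})
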