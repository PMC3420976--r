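test_that("rmse and robe score measures match hand arithmetic", {
  expect_equal(score_rmse(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(score_rmse(c(0.3, 0.7), c(0.2, 0.8)), 0.1)
  expect_equal(score_rmse(c(0, 1), c(1, 0)), 1)
  expect_equal(score_robe(c(0.2, 0.8), c(0.2, 0.8)), 0)
  # outlier insensitivity: residuals (0,0,0,1)
  pred <- c(0, 0, 0, 1); obs <- c(0, 0, 0, 0)
  expect_equal(score_robe(pred, obs), 0)
  expect_equal(score_rmse(pred, obs), 0.5)
  # symmetric residuals +/- c
  expect_equal(score_robe(c(0.4, 0.6), c(0.5, 0.5)), 0.1)
  expect_error(score_rmse(c(0.5), c(0.5, 0.5)), "equal length")
  expect_error(score_rmse(c(1.2), c(0.5)), "\\[0, 1\\]")
})

test_that("grid enumeration is lexicographic and validates entries", {
  g <- grid_spec(mu = c(1, 2, 1), w = c(0, 1, 1))
  cells <- loomtau:::grid_expand(g)
  expect_equal(nrow(cells), 4L)
  # mu varies slowest (lexicographic over the documented parameter order)
  expect_equal(cells$mu, c(1, 1, 2, 2))
  expect_equal(cells$w, c(0, 1, 0, 1))
  expect_error(grid_spec(bogus = c(0, 1, 1)), "unknown")
  expect_error(grid_spec(mu = c(1, 2, 0)), "step")
  expect_error(grid_spec(mu = c(2, 1, 1)), "min")
})

test_that("grid search ranks the generating truth first on zero-noise data", {
  dsn <- tiny_design()
  truth_xi <- xi_params(mu = 1, w = 1, xi_theta = 0, xi_theta_dot = 0)
  nz0 <- noise_spec(0, 0, seed = 1)
  obs_small <- loomtau:::proportion_later_single_size(dsn, "small", truth_xi,
                                                     nz0, 10L, 1L)
  obs_big <- loomtau:::proportion_later_single_size(dsn, "big", truth_xi,
                                                    nz0, 10L, 1L)
  # grid varies parameters the zero-noise data can distinguish (w, p_theta);
  # the generating cell (w = 1, p = 0) is the unique exact scorer
  grid <- grid_spec(mu = 1, w = c(0, 1, 0.5),
                    xi_theta = 0, xi_theta_dot = 0,
                    p_theta = c(0, 0.5, 0.25), p_theta_dot = 0, n_avg = 10)
  res <- grid_search(dsn, obs_small, obs_big, grid, sim_seed = 1L,
                     n_trials = 30L)
  for (tab in res) {
    best <- tab[tab$rank_rmse == 1L, ]
    expect_equal(best$w, 1)
    expect_equal(best$p_theta, 0)
    expect_equal(best$rmse, 0)
    expect_equal(sort(tab$rank_rmse), seq_len(nrow(tab)))
    expect_equal(sort(tab$rank_robe), seq_len(nrow(tab)))
    expect_equal(sum(tab$rmse == 0), 1L)
  }
})

test_that("combined ranking averages scores and is order-symmetric", {
  tab <- data.frame(mu = c(1, 2), w = 1,
                    rmse = c(0.1, 0.3), robe = c(0.1, 0.2),
                    rank_rmse = c(1L, 2L), rank_robe = c(1L, 2L),
                    size_label = "small")
  tab2 <- tab; tab2$rmse <- c(0.5, 0.1); tab2$robe <- c(0.4, 0.1)
  tab2$size_label <- "big"
  comb <- combine_rank(tab, tab2)
  expect_equal(comb$rmse, c(0.3, 0.2))
  expect_equal(comb$rank_rmse, c(2L, 1L))
  comb_swapped <- combine_rank(tab2, tab)
  expect_equal(comb$rmse, comb_swapped$rmse)
  expect_equal(comb$rank_rmse, comb_swapped$rank_rmse)
  # identical tables -> combined equals either
  same <- combine_rank(tab, tab)
  expect_equal(same$rmse, tab$rmse)
  # trade-off: combined best score >= each size's own minimum
  expect_gte(min(comb$rmse), min(min(tab$rmse), min(tab2$rmse)))
})

test_that("ranking is invariant under monotone score transformation", {
  set.seed(4)
  scores <- runif(10)
  r1 <- rank(scores, ties.method = "first")
  r2 <- rank(scores^3 + 2, ties.method = "first")
  expect_identical(r1, r2)
  # within a grid_search table the rank columns are permutations
  tabs <- data.frame(rmse = scores)
  expect_setequal(rank(tabs$rmse, ties.method = "first"), 1:10)
})

test_that("median noise by rank summarises top-k entries with MAD spread", {
  tab <- data.frame(p_theta = c(0.1, 0.3, 0.5, 0.7),
                    p_theta_dot = c(0.2, 0.2, 0.4, 0.8),
                    rank_rmse = 1:4, rank_robe = 1:4)
  s <- median_noise_by_rank(tab, k_values = c(1, 4))
  expect_equal(s$median_p_theta[s$k == 1], 0.1)
  expect_equal(s$mad_p_theta[s$k == 1], 0)
  expect_equal(s$median_p_theta[s$k == 4], stats::median(tab$p_theta))
  expect_equal(s$mad_p_theta[s$k == 4], stats::mad(tab$p_theta))
})

test_that("noisy parameter recovery places the truth near the top", {
  # small grid around a known generating observer; noisy data, seeded repeats
  dsn <- tiny_design()
  dsn$presentation_levels <- c(0.5, 1.0)
  truth_xi <- xi_params(mu = 1, w = 1)
  grid <- grid_spec(mu = c(0.25, 1.75, 0.75), w = c(0, 1, 0.5),
                    p_theta = c(0.1, 0.5, 0.2), n_avg = 10)
  cells <- loomtau:::grid_expand(grid)
  truth_row <- which(abs(cells$mu - 1) < 1e-9 & abs(cells$w - 1) < 1e-9 &
                       abs(cells$p_theta - 0.3) < 1e-9)
  expect_length(truth_row, 1L)
  n_rep <- 5L
  top_decile <- 0L
  for (r in seq_len(n_rep)) {
    nz <- noise_spec(0.3, 0, seed = 5000 + r)
    obs_small <- loomtau:::proportion_later_single_size(dsn, "small", truth_xi,
                                                        nz, 10L, 60L)
    obs_big <- loomtau:::proportion_later_single_size(dsn, "big", truth_xi,
                                                      nz, 10L, 60L)
    res <- grid_search(dsn, obs_small, obs_big, grid, sim_seed = 77L,
                       n_trials = 60L)
    comb <- combine_rank(res$table_small, res$table_big)
    cutoff <- ceiling(nrow(comb) / 10) + 1L
    if (comb$rank_rmse[truth_row] <= cutoff) top_decile <- top_decile + 1L
  }
  expect_gte(top_decile, n_rep - 1L)
})

test_that("full model beats its reduced variants on filtered generating data", {
  dsn <- tiny_design()
  dsn$presentation_levels <- c(0.5, 1.0)
  truth_xi <- xi_params(mu = 1, w = 1, xi_theta = 0.75, xi_theta_dot = 0.75)
  nz <- noise_spec(0.4, 0.4, seed = 101)
  obs_small <- loomtau:::proportion_later_single_size(dsn, "small", truth_xi,
                                                      nz, 10L, 80L)
  obs_big <- loomtau:::proportion_later_single_size(dsn, "big", truth_xi,
                                                    nz, 10L, 80L)
  run_best <- function(grid) {
    res <- grid_search(dsn, obs_small, obs_big, grid, sim_seed = 55L,
                       n_trials = 80L)
    comb <- combine_rank(res$table_small, res$table_big)
    min(comb$rmse)
  }
  # full model grid contains the truth
  full <- grid_spec(mu = c(0.5, 1.5, 0.5), xi_theta = c(0, 0.75, 0.75),
                    xi_theta_dot = c(0, 0.75, 0.75), n_avg = 10,
                    p_theta = c(0.2, 0.4, 0.2), p_theta_dot = c(0.2, 0.4, 0.2))
  # reduced (i): no correction term (w = 0)
  red_w0 <- grid_spec(mu = c(0.5, 1.5, 0.5), w = 0,
                      xi_theta = c(0, 0.75, 0.75),
                      xi_theta_dot = c(0, 0.75, 0.75), n_avg = 10,
                      p_theta = c(0.2, 0.4, 0.2), p_theta_dot = c(0.2, 0.4, 0.2))
  # reduced (ii): both filter memories forced to zero
  red_nofilt <- grid_spec(mu = c(0.5, 1.5, 0.5), xi_theta = 0, xi_theta_dot = 0,
                          n_avg = 10, p_theta = c(0.2, 0.4, 0.2),
                          p_theta_dot = c(0.2, 0.4, 0.2))
  best_full <- run_best(full)
  expect_lte(best_full, run_best(red_w0))
  expect_lte(best_full, run_best(red_nofilt))
})
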