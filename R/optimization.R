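#' Score measures for psychometric predictions
#'
#' \code{score_rmse} is the unweighted root mean square error between
#' predicted and observed proportion-of-later values; \code{score_robe} is an
#' outlier-insensitive robust error, by default the median absolute residual
#' (alternatives: mean absolute deviation, 20%-trimmed mean of absolute
#' residuals).
#'
#' @param pred,obs Equal-length vectors of proportions in [0, 1].
#' @param aggregate Robust aggregate for \code{score_robe}.
#' @return A single non-negative score.
#' @export
score_rmse <- function(pred, obs) {
  check_proportions(pred, obs)
  sqrt(mean((pred - obs)^2))
}

#' @rdname score_rmse
#' @export
score_robe <- function(pred, obs,
                       aggregate = c("median", "mean_abs", "trimmed_mean")) {
  check_proportions(pred, obs)
  aggregate <- match.arg(aggregate)
  a <- abs(pred - obs)
  switch(aggregate,
         median = stats::median(a),
         mean_abs = mean(a),
         trimmed_mean = mean(a, trim = 0.2))
}

check_proportions <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs must have equal length")
  if (any(pred < 0 | pred > 1 | obs < 0 | obs > 1))
    stop("proportions must lie in [0, 1]")
  invisible(TRUE)
}

#' Constant-step grid specification
#'
#' One \code{c(min, max, step)} triple (or a single fixed value) per searched
#' parameter.  Valid parameter names: \code{mu, w, xi_theta, xi_theta_dot,
#' kappa, p_theta, p_theta_dot, n_avg} — the eight free parameters of the
#' corrected m-Tau observer.
#'
#' @param ... Named triples \code{c(min, max, step)} or single fixed values.
#' @return An object of class \code{"grid_spec"}.
#' @examples
#' grid_spec(mu = c(0.5, 2, 0.5), w = 1, p_theta = c(0, 0.1, 0.05))
#' @export
grid_spec <- function(...) {
  spec <- list(...)
  valid <- c("mu", "w", "xi_theta", "xi_theta_dot", "kappa",
             "p_theta", "p_theta_dot", "n_avg")
  bad <- setdiff(names(spec), valid)
  if (length(bad)) stop("unknown grid parameter(s): ", paste(bad, collapse = ", "))
  levels <- lapply(spec, function(v) {
    if (length(v) == 1L) return(v)
    if (length(v) != 3L) stop("each grid entry is c(min, max, step) or a single value")
    if (v[3] <= 0) stop("step must be positive")
    if (v[1] > v[2]) stop("min must be <= max")
    seq(v[1], v[2], by = v[3])
  })
  structure(levels, class = "grid_spec")
}

# Deterministic lexicographic enumeration of the grid as a data frame.
grid_expand <- function(grid, defaults = xi_params(), noise_defaults = NULL,
                        n_avg_default = 50L) {
  base <- list(mu = defaults$mu, w = defaults$w, xi_theta = defaults$xi_theta,
               xi_theta_dot = defaults$xi_theta_dot, kappa = defaults$kappa,
               p_theta = if (is.null(noise_defaults)) 0 else noise_defaults$p_theta,
               p_theta_dot = if (is.null(noise_defaults)) 0 else noise_defaults$p_theta_dot,
               n_avg = n_avg_default)
  for (nm in names(grid)) base[[nm]] <- grid[[nm]]
  # expand.grid varies the first factor fastest; reverse for lexicographic
  # order over the documented parameter sequence
  g <- expand.grid(rev(base), KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(names(g)), drop = FALSE]
  g
}

#' Exhaustive grid-search optimization of the Xi observer
#'
#' Enumerates a constant-step parameter grid (deterministic lexicographic
#' order), simulates the proportion-of-later curve for every parameter set
#' with common random numbers across cells, scores the prediction against
#' the small- and big-object observations with both score measures, and
#' ranks ascending (rank one = smallest score).  Ties keep the enumeration
#' order.
#'
#' @param design An \code{\link{experiment_design}}.
#' @param obs_small,obs_big Observed psychometric tables (data frames with
#'   \code{ttc_s, tp_s, prop_later}) for the two sizes.
#' @param grid A \code{\link{grid_spec}}.
#' @param eps Fixed denominator guard (not searched).
#' @param sim_seed Base seed for the common-random-number simulations.
#' @param n_trials Trials per condition per grid cell.
#' @param robe_aggregate Robust aggregate used by \code{\link{score_robe}}.
#' @return List with \code{table_small} and \code{table_big}: score tables
#'   (one row per parameter set) with columns for all parameters,
#'   \code{rmse}, \code{robe}, \code{rank_rmse}, \code{rank_robe},
#'   \code{size_label}.
#' @export
grid_search <- function(design, obs_small, obs_big, grid,
                        eps = 1e-12, sim_seed = 1L, n_trials = 50L,
                        robe_aggregate = "median") {
  cells <- grid_expand(grid)
  if (nrow(cells) == 0L) stop("empty grid")
  key <- function(df) paste(df$ttc_s, df$tp_s, sep = "|")
  score_one <- function(lab, obs) {
    ok <- order(obs$tp_s, obs$ttc_s)
    obs <- obs[ok, , drop = FALSE]
    rmse <- robe <- numeric(nrow(cells))
    for (i in seq_len(nrow(cells))) {
      p <- cells[i, ]
      xi <- xi_params(mu = p$mu, w = p$w, xi_theta = p$xi_theta,
                      xi_theta_dot = p$xi_theta_dot, kappa = p$kappa,
                      eps = eps)
      nz <- noise_spec(p_theta = p$p_theta, p_theta_dot = p$p_theta_dot,
                       seed = sim_seed)  # common random numbers across cells
      pred <- proportion_later_single_size(design, lab, xi, nz,
                                           n_avg = as.integer(p$n_avg),
                                           n_trials = n_trials)
      m <- match(key(obs), key(pred))
      if (anyNA(m)) stop("observations do not match the design conditions")
      rmse[i] <- score_rmse(pred$prop_later[m], obs$prop_later)
      robe[i] <- score_robe(pred$prop_later[m], obs$prop_later,
                            aggregate = robe_aggregate)
    }
    bad <- !is.finite(rmse) | !is.finite(robe)
    if (any(bad)) {
      warning(sum(bad), " grid cell(s) with non-finite scores excluded")
      rmse[bad] <- Inf; robe[bad] <- Inf
    }
    tab <- cbind(cells,
                 data.frame(rmse = rmse, robe = robe,
                            rank_rmse = rank(rmse, ties.method = "first"),
                            rank_robe = rank(robe, ties.method = "first"),
                            size_label = lab))
    tab
  }
  list(table_small = score_one("small", obs_small),
       table_big = score_one("big", obs_big))
}

#' Combine per-size score tables
#'
#' Averages the two sizes' score measures per parameter set and re-ranks the
#' averaged scores ascending.  Optimizing the combined diameter naturally
#' implies a trade-off: the combined best score cannot beat either size's
#' individual best.
#'
#' @param table_small,table_big Score tables from \code{\link{grid_search}},
#'   indexed by the same parameter sets.
#' @return Combined score table (\code{size_label = "combined"}).
#' @export
combine_rank <- function(table_small, table_big) {
  par_cols <- setdiff(names(table_small),
                      c("rmse", "robe", "rank_rmse", "rank_robe", "size_label"))
  if (!identical(table_small[par_cols], table_big[par_cols]))
    stop("tables are not indexed by the same parameter sets")
  rmse <- (table_small$rmse + table_big$rmse) / 2
  robe <- (table_small$robe + table_big$robe) / 2
  cbind(table_small[par_cols],
        data.frame(rmse = rmse, robe = robe,
                   rank_rmse = rank(rmse, ties.method = "first"),
                   rank_robe = rank(robe, ties.method = "first"),
                   size_label = "combined"))
}

#' Median noise level across the top-ranked parameter sets
#'
#' For each \code{k} in \code{k_values}, the median of the noise levels
#' \code{p_theta} and \code{p_theta_dot} over ranks 1..k of a ranked score
#' table, with a robust spread (median absolute deviation scaled to normal
#' consistency).
#'
#' @param table A ranked score table.
#' @param k_values Rank cutoffs.
#' @param rank_by \code{"rmse"} or \code{"robe"}.
#' @return Data frame with one row per k: medians and MAD spreads of both
#'   noise levels.
#' @export
median_noise_by_rank <- function(table, k_values, rank_by = c("rmse", "robe")) {
  rank_by <- match.arg(rank_by)
  rk <- table[[paste0("rank_", rank_by)]]
  out <- lapply(k_values, function(k) {
    sel <- table[rk <= k, , drop = FALSE]
    data.frame(k = k,
               median_p_theta = stats::median(sel$p_theta),
               mad_p_theta = stats::mad(sel$p_theta),
               median_p_theta_dot = stats::median(sel$p_theta_dot),
               mad_p_theta_dot = stats::mad(sel$p_theta_dot))
  })
  do.call(rbind, out)
}
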