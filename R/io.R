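#' Read and write trace CSV files
#'
#' Two dialects are supported.  Optical traces carry columns
#' \code{time_s, theta_rad, theta_dot_rad_s[, theta_ddot_rad_s2]} (or the
#' degree-labelled variants \code{theta_deg, theta_dot_deg_s}, converted by
#' pi/180 on ingestion).  Firing-rate traces carry \code{t_rel_s, rate} with
#' stimulus metadata passed separately or stored in \code{# key: value}
#' comment headers (\code{half_size_m}, \code{speed_m_s}).
#'
#' @param path File path.
#' @param half_size_m,speed_m_s Stimulus metadata for a firing-rate trace
#'   when not present as comment headers.
#' @return \code{read_trace_csv}: an \code{\link{optical_trace}} or
#'   \code{\link{firing_rate_trace}} depending on the header.
#' @export
read_trace_csv <- function(path, half_size_m = NULL, speed_m_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 200L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), ":\\s*")[[1]]
    if (length(kv) == 2L) meta[[kv[1]]] <- suppressWarnings(as.numeric(kv[2]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (anyNA(df)) stop("NA values are not allowed in trace files")
  cn <- names(df)
  if (all(c("t_rel_s", "rate") %in% cn)) {
    R <- half_size_m %||% meta$half_size_m
    v <- speed_m_s %||% meta$speed_m_s
    if (is.null(R) || is.null(v))
      stop("firing-rate trace needs half_size_m and speed_m_s metadata")
    return(firing_rate_trace(df$t_rel_s, df$rate, R, v))
  }
  if (!"time_s" %in% cn) stop("missing column: time_s")
  deg <- "theta_deg" %in% cn
  if (deg) {
    th <- df$theta_deg * pi / 180
    thd <- df$theta_dot_deg_s * pi / 180
  } else {
    if (!all(c("theta_rad", "theta_dot_rad_s") %in% cn))
      stop("missing columns: theta_rad, theta_dot_rad_s (or theta_deg, theta_dot_deg_s)")
    th <- df$theta_rad
    thd <- df$theta_dot_rad_s
  }
  if (any(diff(df$time_s) <= 0)) stop("non-monotone time column")
  optical_trace(df$time_s, th, thd,
                theta_ddot = df$theta_ddot_rad_s2, is_noisy = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_trace_csv
#' @param trace An \code{\link{optical_trace}} or
#'   \code{\link{firing_rate_trace}} to write.
#' @export
write_trace_csv <- function(trace, path) {
  if (inherits(trace, "optical_trace")) {
    df <- as.data.frame(trace)
  } else if (inherits(trace, "firing_rate_trace")) {
    cat(sprintf("# half_size_m: %.12g\n# speed_m_s: %.12g\n",
                trace$stim_half_size, trace$stim_speed), file = path)
    df <- data.frame(t_rel_s = trace$times, rate = trace$rate)
    suppressWarnings(utils::write.table(
      format(df, digits = 15, scientific = FALSE, trim = TRUE),
      path, sep = ",", row.names = FALSE, quote = FALSE, append = TRUE))
    return(invisible(path))
  } else stop("unsupported trace object")
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write psychometric point tables
#'
#' CSV dialect: \code{ttc_s, tp_s, size_label, prop_later, n_trials[,
#' est_sd_s]}.
#'
#' @param path File path.
#' @param points Psychometric data frame to write.
#' @return \code{read_psychometric_csv}: a validated data frame.
#' @export
read_psychometric_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("ttc_s", "tp_s", "size_label", "prop_later", "n_trials")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$prop_later < 0 | df$prop_later > 1))
    stop("prop_later must lie in [0, 1]")
  df
}

#' @rdname read_psychometric_csv
#' @export
write_psychometric_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat run configuration
#'
#' YAML key/value document with blocks for the owning modules:
#' \code{stimulus} (\code{half_size_m} or \code{diameter_m},
#' \code{speed_m_s}, \code{ttc_s}, \code{dt_s}), \code{xi} (\code{mu, w,
#' xi_theta, xi_theta_dot, kappa, eps}), \code{noise} (\code{p_theta,
#' p_theta_dot, noise_mode, seed, floor_at_zero}), plus pipeline-specific
#' blocks.  Unknown units or missing mandatory keys give descriptive errors.
#'
#' @param path YAML file path.
#' @return Named list of configuration blocks.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a key/value document")
  cfg
}

config_stimulus <- function(block) {
  if (is.null(block)) stop("config validation error: missing block 'stimulus'")
  approach_stimulus(half_size_R = block$half_size_m,
                    diameter = block$diameter_m,
                    speed_v = block$speed_m_s %||%
                      stop("config validation error: missing key 'speed_m_s'"),
                    collision_time_tc = block$ttc_s %||%
                      stop("config validation error: missing key 'ttc_s'"),
                    dt = block$dt_s %||% 0.001)
}

config_xi <- function(block) {
  block <- block %||% list()
  xi_params(mu = block$mu %||% 1, w = block$w %||% 1,
            xi_theta = block$xi_theta %||% 0.75,
            xi_theta_dot = block$xi_theta_dot %||% 0.75,
            kappa = block$kappa %||% 0, eps = block$eps %||% 1e-12)
}

config_noise <- function(block, seed = 1L) {
  block <- block %||% list()
  noise_spec(p_theta = block$p_theta %||% 0,
             p_theta_dot = block$p_theta_dot %||% 0,
             mode = block$noise_mode %||% "relative",
             seed = block$seed %||% seed,
             floor_at_zero = block$floor_at_zero %||% FALSE)
}

#' Run a configured pipeline and write an artifact bundle
#'
#' Executes one of the named pipelines — \code{kinematics} (sample a clean
#' trace and function evaluations), \code{simulate} (psychometric
#' proportion-of-later table), \code{mask} (noise-masked linearity
#' experiment), or \code{fit} (looming-function fit to a firing-rate CSV) —
#' and writes CSV/JSON outputs plus a \code{manifest.json} recording the
#' resolved config file hash, seed and package version.  Identical config
#' and seed reproduce identical outputs.
#'
#' @param config_path Path to the YAML run configuration (must contain a
#'   \code{pipeline} key).
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed; overrides the config's seed when given.
#' @return Invisibly, the manifest as a list.
#' @export
run_experiment <- function(config_path, out_dir, seed = NULL) {
  cfg <- read_run_config(config_path)
  pipeline <- cfg$pipeline %||%
    stop("config validation error: missing key 'pipeline'")
  seed <- seed %||% cfg$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()

  if (pipeline == "kinematics") {
    stim <- config_stimulus(cfg$stimulus)
    tr <- generate_trace(stim, include_ddot = TRUE)
    df <- evaluate_functions(tr, functions = c("tau", "m_tau", "xi"),
                             xi = config_xi(cfg$xi))
    out <- file.path(out_dir, "trace.csv")
    utils::write.csv(df, out, row.names = FALSE, quote = FALSE)
    outputs <- out
  } else if (pipeline == "simulate") {
    dsn <- do.call(experiment_design, cfg$design %||% list())
    pts <- proportion_later(dsn, config_xi(cfg$xi),
                            config_noise(cfg$noise, seed),
                            n_avg = cfg$n_avg %||% 50L,
                            n_trials = cfg$n_trials %||% 200L)
    out <- file.path(out_dir, "points.csv")
    write_psychometric_csv(pts, out)
    outputs <- out
  } else if (pipeline == "mask") {
    mk <- masking_experiment(mu = cfg$mu %||% 1,
                             noise_coeff_c = cfg$c %||% 0.15,
                             n_trials = cfg$trials %||% 25L,
                             n_repeats = cfg$repeats %||% 100L,
                             seed = seed)
    out <- file.path(out_dir, "mask.csv")
    utils::write.csv(mk$fits, out, row.names = FALSE, quote = FALSE)
    out2 <- file.path(out_dir, "mask_summary.json")
    jsonlite::write_json(list(masked_fraction = mk$masked_fraction), out2,
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(out, out2)
  } else if (pipeline == "fit") {
    tr <- read_trace_csv(cfg$trace %||%
                           stop("config validation error: missing key 'trace'"),
                         half_size_m = cfg$half_size_m,
                         speed_m_s = cfg$speed_m_s)
    fit <- fit_model_to_trace(tr, model_name = cfg$model %||% "eta")
    out <- file.path(out_dir, "fit.json")
    jsonlite::write_json(
      list(model = fit$model_name, params = fit$fitted_params,
           rmse = fit$rmse, r2 = fit$r2, f_stat = fit$f_stat,
           t_peak_pred = fit$t_peak_pred, t_peak_obs = fit$t_peak_obs),
      out, auto_unbox = TRUE, digits = NA)
    outputs <- out
  } else {
    stop("unknown pipeline: ", pipeline)
  }

  manifest <- list(
    pipeline = pipeline,
    config_md5 = unname(tools::md5sum(config_path)),
    seed = seed,
    package_version = as.character(utils::packageVersion("loomtau")),
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
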