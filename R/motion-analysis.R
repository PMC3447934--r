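# Local MSD analysis. For every trajectory point a centered window of
# `window_frames` points yields a local MSD curve over lags 1..n_max; the
# log-log slope of that curve is the local anomalous exponent alpha, its
# initial linear slope gives the diffusion constant D, and the mean cosine
# of the turning angles in the same window gives the directional
# persistence phi. A point is in the "directed state" when alpha and phi
# both exceed their thresholds.

#' Analysis configuration
#'
#' All tunable parameters of the trajectory analysis. Defaults correspond
#' to 10 Hz quantum-dot tracking: the local MSD is computed over a
#' 20-frame window and fitted over its first 10 lags, the diffusion
#' constant over the first 5 lags; a directed segment must last at least
#' 5 frames and displace more than one 267 nm pixel per 0.5 s.
#'
#' @param window_frames Width (points) of the centered local-MSD window.
#' @param n_max Number of MSD lags entering the power-law fit.
#' @param d_fit_points Number of initial lags for the linear D fit.
#' @param alpha_dir Minimum local alpha for the directed state.
#' @param phi_min Minimum directional persistence for the directed state.
#' @param alpha_constrained Upper alpha bound of constrained motion
#'   (trajectory modes use half-open intervals `[lo, hi)`).
#' @param alpha_super Lower alpha bound of super-diffusive motion.
#' @param min_directed_frames Minimum length (points) of a directed
#'   segment.
#' @param min_displacement_um Minimum displacement per `displacement_window_s`
#'   for a directed segment (default one pixel, 0.267 um).
#' @param displacement_window_s Time span of the rolling displacement
#'   check, seconds (default 0.5).
#' @param velocity_halfwidth Half-width h (frames) of the smoothed
#'   central-difference instantaneous velocity.
#' @param bin_5min,bin_15min Widths (seconds) of the velocity and
#'   mode-proportion time bins.
#' @param smooth_points Window (frames) of the moving-average smoother for
#'   single-cell time series.
#' @param ratio_method How the endocytic ratio aggregates over puncta:
#'   `"mean_of_ratios"` (mean of b/a) or `"ratio_of_means"`
#'   (mean b / mean a).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(window_frames = 20L,
                            n_max = 10L,
                            d_fit_points = 5L,
                            alpha_dir = 1.4,
                            phi_min = 0.7,
                            alpha_constrained = 0.4,
                            alpha_super = 1.0,
                            min_directed_frames = 5L,
                            min_displacement_um = 0.267,
                            displacement_window_s = 0.5,
                            velocity_halfwidth = 2L,
                            bin_5min = 300,
                            bin_15min = 900,
                            smooth_points = 20L,
                            ratio_method = c("mean_of_ratios", "ratio_of_means")) {
  ratio_method <- match.arg(ratio_method)
  if (!(alpha_constrained > 0 && alpha_constrained < alpha_super)) {
    stop("need 0 < alpha_constrained < alpha_super", call. = FALSE)
  }
  if (n_max >= window_frames) stop("`n_max` must be < `window_frames`", call. = FALSE)
  if (d_fit_points > n_max) stop("`d_fit_points` must be <= `n_max`", call. = FALSE)
  if (min_directed_frames < 2L) stop("`min_directed_frames` must be >= 2", call. = FALSE)
  structure(list(
    window_frames = as.integer(window_frames),
    n_max = as.integer(n_max),
    d_fit_points = as.integer(d_fit_points),
    alpha_dir = alpha_dir, phi_min = phi_min,
    alpha_constrained = alpha_constrained, alpha_super = alpha_super,
    min_directed_frames = as.integer(min_directed_frames),
    min_displacement_um = min_displacement_um,
    displacement_window_s = displacement_window_s,
    velocity_halfwidth = as.integer(velocity_halfwidth),
    bin_5min = bin_5min, bin_15min = bin_15min,
    smooth_points = as.integer(smooth_points),
    ratio_method = ratio_method
  ), class = "analysis_config")
}

# window index range for point i (1-based): [i - w/2, i + w/2), truncated
window_bounds <- function(i, n, w) {
  lo <- max(1L, i - w %/% 2L)
  hi <- min(n, i + w %/% 2L - 1L)
  c(lo, hi)
}

#' Local mean square displacement around one trajectory point
#'
#' MSD over lags `n = 1..n_max` computed from all ordered point pairs
#' `(j, j + n)` inside the centered window around point `i`; the window is
#' truncated at the trajectory ends. The curve is flagged invalid (not an
#' error) when fewer than `n_max + 1` points are available.
#'
#' @param traj Trajectory data.frame with columns `x_um`, `y_um` (and
#'   `t_s` or `frame`).
#' @param i Point index (1-based).
#' @param cfg An [analysis_config()].
#' @param dt Seconds per frame.
#' @return List of class `msd_curve`: `lag_s`, `msd_um2`, `n_pairs`,
#'   `valid`.
#' @export
local_msd <- function(traj, i, cfg = analysis_config(), dt = 0.1) {
  n <- nrow(traj)
  b <- window_bounds(i, n, cfg$window_frames)
  lo <- b[1L]; hi <- b[2L]
  npts <- hi - lo + 1L
  lags <- seq_len(cfg$n_max)
  if (npts < cfg$n_max + 1L) {
    return(structure(list(lag_s = lags * dt, msd_um2 = rep(NA_real_, cfg$n_max),
                          n_pairs = rep(0L, cfg$n_max), valid = FALSE),
                     class = "msd_curve"))
  }
  x <- traj$x_um[lo:hi]
  y <- traj$y_um[lo:hi]
  msd <- numeric(cfg$n_max)
  npairs <- integer(cfg$n_max)
  for (nn in lags) {
    j <- seq_len(npts - nn)
    dx <- x[j + nn] - x[j]
    dy <- y[j + nn] - y[j]
    msd[nn] <- mean(dx * dx + dy * dy)
    npairs[nn] <- length(j)
  }
  structure(list(lag_s = lags * dt, msd_um2 = msd, n_pairs = npairs,
                 valid = TRUE), class = "msd_curve")
}

#' Power-law fit of an MSD curve
#'
#' Least-squares line through `(log lag, log MSD)`; the slope is the
#' anomalous exponent alpha, `exp(intercept)` the prefactor. Zero MSD
#' entries are excluded; at least three positive points are required.
#'
#' @param curve An `msd_curve` from [local_msd()].
#' @return List `alpha`, `prefactor`, `valid`.
#' @export
fit_alpha <- function(curve) {
  if (!isTRUE(curve$valid)) return(list(alpha = NA_real_, prefactor = NA_real_, valid = FALSE))
  ok <- is.finite(curve$msd_um2) & curve$msd_um2 > 0
  if (sum(ok) < 3L) return(list(alpha = NA_real_, prefactor = NA_real_, valid = FALSE))
  x <- log(curve$lag_s[ok])
  y <- log(curve$msd_um2[ok])
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  list(alpha = slope, prefactor = exp(my - slope * mx), valid = TRUE)
}

#' Diffusion constant from the initial MSD slope
#'
#' Least-squares slope `s` of MSD versus lag time over the first
#' `d_fit_points` lags, with a free intercept that absorbs the static
#' localization-noise offset; `D = s / 4`, clamped at zero (with a flag)
#' if the slope is negative.
#'
#' @param curve An `msd_curve`.
#' @param cfg An [analysis_config()].
#' @return List `D` (um^2/s), `clamped`, `valid`.
#' @export
fit_diffusion_constant <- function(curve, cfg = analysis_config()) {
  if (!isTRUE(curve$valid)) return(list(D = NA_real_, clamped = FALSE, valid = FALSE))
  k <- seq_len(min(cfg$d_fit_points, length(curve$lag_s)))
  x <- curve$lag_s[k]
  y <- curve$msd_um2[k]
  ok <- is.finite(y)
  if (sum(ok) < 2L) return(list(D = NA_real_, clamped = FALSE, valid = FALSE))
  x <- x[ok]; y <- y[ok]
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  D <- slope / 4
  clamped <- D < 0
  list(D = max(D, 0), clamped = clamped, valid = TRUE)
}

#' Directional persistence around one trajectory point
#'
#' Mean cosine of the turning angles between consecutive displacement
#' vectors inside the centered window: 1 for perfectly straight motion,
#' -1 for a path that reverses every frame, ~0 for an isotropic walk.
#' Zero-length steps contribute no angle; at least two usable angles are
#' required.
#'
#' @inheritParams local_msd
#' @return List `phi`, `n_angles`, `valid`.
#' @export
local_persistence <- function(traj, i, cfg = analysis_config()) {
  n <- nrow(traj)
  b <- window_bounds(i, n, cfg$window_frames)
  lo <- b[1L]; hi <- b[2L]
  if (hi - lo + 1L < 3L) return(list(phi = NA_real_, n_angles = 0L, valid = FALSE))
  x <- traj$x_um[lo:hi]
  y <- traj$y_um[lo:hi]
  dx <- diff(x); dy <- diff(y)
  len <- sqrt(dx * dx + dy * dy)
  m <- length(dx)
  j <- seq_len(m - 1L)
  usable <- len[j] > 0 & len[j + 1L] > 0
  if (sum(usable) < 2L) return(list(phi = NA_real_, n_angles = sum(usable), valid = FALSE))
  cosang <- (dx[j] * dx[j + 1L] + dy[j] * dy[j + 1L]) / (len[j] * len[j + 1L])
  cosang <- pmin(pmax(cosang[usable], -1), 1)
  list(phi = mean(cosang), n_angles = length(cosang), valid = TRUE)
}

#' Per-point motion profile of one trajectory
#'
#' Computes, for every point with a sufficient window, the local anomalous
#' exponent, diffusion constant, directional persistence and smoothed
#' instantaneous speed, and flags points in the directed state
#' (`alpha >= alpha_dir` and `phi >= phi_min`).
#'
#' @param traj Trajectory data.frame (columns `frame`, `x_um`, `y_um`;
#'   optional `t_s`).
#' @param cfg An [analysis_config()].
#' @param dt Seconds per frame.
#' @return data.frame of class `motion_profile`: `frame`, `t_s`, `alpha`,
#'   `D_um2_s`, `phi`, `speed_um_s`, `directed`, `valid`.
#' @export
profile_trajectory <- function(traj, cfg = analysis_config(), dt = 0.1) {
  n <- nrow(traj)
  t_s <- if ("t_s" %in% names(traj)) traj$t_s else traj$frame * dt
  alpha <- D <- phi <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    curve <- local_msd(traj, i, cfg, dt)
    if (!curve$valid) next
    fa <- fit_alpha(curve)
    fp <- local_persistence(traj, i, cfg)
    if (!fa$valid || !fp$valid) next
    fd <- fit_diffusion_constant(curve, cfg)
    alpha[i] <- fa$alpha
    D[i] <- fd$D
    phi[i] <- fp$phi
    valid[i] <- TRUE
  }
  speed <- instantaneous_speed(traj, cfg, dt)
  directed <- valid & !is.na(alpha) & !is.na(phi) &
    alpha >= cfg$alpha_dir & phi >= cfg$phi_min
  out <- data.frame(
    frame = traj$frame, t_s = t_s, alpha = alpha, D_um2_s = D, phi = phi,
    speed_um_s = speed, directed = directed, valid = valid
  )
  if (!is.null(traj$traj_id)) out$traj_id <- traj$traj_id
  attr(out, "traj_id") <- attr(traj, "traj_id", exact = TRUE)
  class(out) <- c("motion_profile", "data.frame")
  out
}
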