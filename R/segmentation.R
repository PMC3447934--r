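# Directed-segment extraction and single-cell statistics. A directed
# segment is a maximal run of consecutive directed-state points that lasts
# at least `min_directed_frames` frames and displaces more than
# `min_displacement_um` over every rolling `displacement_window_s` window.
# Velocities are smoothed central differences; population statistics use a
# two-step average (per cell first, then across cells).

#' Smoothed instantaneous velocity at one point
#'
#' Central difference over `velocity_halfwidth` frames on each side,
#' per coordinate: `(coord(i+h) - coord(i-h)) / (2 h dt)`; the speed is
#' the Euclidean norm. The smoothing suppresses the frame-to-frame
#' localization error of the position measurement.
#'
#' @param traj Trajectory data.frame.
#' @param i Point index (1-based); must be at least `h` from both ends.
#' @param cfg An [analysis_config()].
#' @param dt Seconds per frame.
#' @return Speed in um/s, or `NA` when `i` is too close to an end.
#' @export
instantaneous_velocity <- function(traj, i, cfg = analysis_config(), dt = 0.1) {
  h <- cfg$velocity_halfwidth
  n <- nrow(traj)
  if (i <= h || i > n - h) return(NA_real_)
  vx <- (traj$x_um[i + h] - traj$x_um[i - h]) / (2 * h * dt)
  vy <- (traj$y_um[i + h] - traj$y_um[i - h]) / (2 * h * dt)
  sqrt(vx * vx + vy * vy)
}

# vectorized speeds for a whole trajectory (NA near the ends)
instantaneous_speed <- function(traj, cfg = analysis_config(), dt = 0.1) {
  h <- cfg$velocity_halfwidth
  n <- nrow(traj)
  v <- rep(NA_real_, n)
  if (n < 2L * h + 1L) return(v)
  i <- (h + 1L):(n - h)
  vx <- (traj$x_um[i + h] - traj$x_um[i - h]) / (2 * h * dt)
  vy <- (traj$y_um[i + h] - traj$y_um[i - h]) / (2 * h * dt)
  v[i] <- sqrt(vx * vx + vy * vy)
  v
}

#' Extract directed segments from a motion profile
#'
#' Maximal runs of consecutive directed-state points are kept when (a) the
#' run lasts at least `min_directed_frames` points and (b) the displacement
#' over every rolling `displacement_window_s` window inside the run exceeds
#' `min_displacement_um`. For runs shorter than the rolling window the
#' threshold is pro-rated to the run duration, so a slow crawl cannot pass
#' by virtue of being short.
#'
#' @param profile A `motion_profile` from [profile_trajectory()].
#' @param traj The corresponding trajectory data.frame.
#' @param cfg An [analysis_config()].
#' @param dt Seconds per frame.
#' @return List with
#'   \describe{
#'     \item{segments}{data.frame: `traj_id`, `start_frame`, `end_frame`,
#'       `n_frames`, `run_length_um`, `mean_velocity_um_s`, `t_mid_s`.}
#'     \item{points}{data.frame of the per-point samples inside segments:
#'       `traj_id`, `frame`, `t_s`, `speed_um_s` (smoothed instantaneous
#'       speeds where defined).}
#'   }
#' @export
extract_directed_segments <- function(profile, traj, cfg = analysis_config(),
                                      dt = 0.1) {
  id <- attr(profile, "traj_id", exact = TRUE)
  if (is.null(id)) id <- attr(traj, "traj_id", exact = TRUE)
  if (is.null(id)) id <- if (!is.null(traj$traj_id)) traj$traj_id[1L] else "traj"
  empty <- list(
    segments = data.frame(
      traj_id = character(0), start_frame = integer(0), end_frame = integer(0),
      n_frames = integer(0), run_length_um = numeric(0),
      mean_velocity_um_s = numeric(0), t_mid_s = numeric(0)
    ),
    points = data.frame(
      traj_id = character(0), frame = integer(0), t_s = numeric(0),
      speed_um_s = numeric(0)
    )
  )
  d <- profile$directed
  if (!any(d)) return(empty)

  # frames-per-rolling-window in frame intervals (5 at 10 Hz / 0.5 s)
  w_full <- max(1L, round(cfg$displacement_window_s / dt))

  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  pts <- list()
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    npts <- e - s + 1L
    if (npts < cfg$min_directed_frames) next
    w <- min(w_full, npts - 1L)
    required <- cfg$min_displacement_um * (w * dt / cfg$displacement_window_s)
    j <- s:(e - w)
    disp <- sqrt((traj$x_um[j + w] - traj$x_um[j])^2 +
                 (traj$y_um[j + w] - traj$y_um[j])^2)
    if (any(disp <= required)) next
    idx <- s:e
    step <- sqrt(diff(traj$x_um[idx])^2 + diff(traj$y_um[idx])^2)
    run_len <- sum(step)
    sp <- profile$speed_um_s[idx]
    mean_v <- if (any(is.finite(sp))) {
      mean(sp[is.finite(sp)])
    } else {
      run_len / ((npts - 1L) * dt)
    }
    segs[[length(segs) + 1L]] <- data.frame(
      traj_id = id,
      start_frame = traj$frame[s], end_frame = traj$frame[e],
      n_frames = npts, run_length_um = run_len,
      mean_velocity_um_s = mean_v,
      t_mid_s = (profile$t_s[s] + profile$t_s[e]) / 2
    )
    keep <- idx[is.finite(profile$speed_um_s[idx])]
    if (length(keep)) {
      pts[[length(pts) + 1L]] <- data.frame(
        traj_id = id, frame = traj$frame[keep], t_s = profile$t_s[keep],
        speed_um_s = profile$speed_um_s[keep]
      )
    }
  }
  if (!length(segs)) return(empty)
  list(
    segments = do.call(rbind, segs),
    points = if (length(pts)) do.call(rbind, pts) else empty$points
  )
}

#' Classify a trajectory's motion mode from its mean local exponent
#'
#' The trajectory-level `mean_alpha` (mean of valid per-point local
#' exponents) is mapped to half-open intervals: constrained for
#' `mean_alpha < alpha_constrained`, sub-diffusive for
#' `[alpha_constrained, alpha_super)`, super-diffusive for
#' `mean_alpha >= alpha_super`; boundary values fall in the upper
#' interval. Trajectories with no valid point are `"unclassified"`.
#'
#' @param profile A `motion_profile`.
#' @param cfg An [analysis_config()].
#' @return One-row data.frame: `traj_id`, `mean_alpha`, `mode`, `t_mid_s`.
#' @export
classify_mode <- function(profile, cfg = analysis_config()) {
  id <- attr(profile, "traj_id", exact = TRUE)
  if (is.null(id)) id <- if (!is.null(profile$traj_id)) profile$traj_id[1L] else "traj"
  a <- profile$alpha[profile$valid]
  if (!length(a)) {
    return(data.frame(traj_id = id, mean_alpha = NA_real_,
                      mode = "unclassified",
                      t_mid_s = stats::median(profile$t_s)))
  }
  ma <- mean(a)
  mode <- if (ma < cfg$alpha_constrained) {
    "constrained"
  } else if (ma < cfg$alpha_super) {
    "subdiffusive"
  } else {
    "superdiffusive"
  }
  data.frame(traj_id = id, mean_alpha = ma, mode = mode,
             t_mid_s = (profile$t_s[1L] + profile$t_s[nrow(profile)]) / 2)
}

# mean over cells of per-cell means, with the standard error across cells
two_step_mean <- function(values, cell) {
  per_cell <- tapply(values, cell, mean)
  per_cell <- per_cell[!is.na(per_cell)]
  n <- length(per_cell)
  list(mean = mean(per_cell),
       se = if (n > 1L) stats::sd(per_cell) / sqrt(n) else 0,
       n_cells = n)
}

#' Two-step binned velocity statistics
#'
#' Implements the two-step population average of directed-motion
#' velocities: within each time bin, (1) the mean over all directed-motion
#' point velocities is computed per cell (each point is one sample), then
#' (2) those per-cell means are averaged, unweighted, across cells with a
#' standard error. Cells with no samples in a bin are omitted from that
#' bin.
#'
#' @param points data.frame with columns `cell_id`, `t_s`, `speed_um_s`
#'   (directed-motion point samples from all cells, e.g. pooled
#'   `points` tables from [extract_directed_segments()]).
#' @param cfg An [analysis_config()]; `bin_5min` sets the bin width.
#' @return data.frame: `bin_start_s`, `bin_end_s`, `n_cells`,
#'   `mean_velocity_um_s`, `se_velocity_um_s`.
#' @export
binned_velocity_stats <- function(points, cfg = analysis_config()) {
  if (!nrow(points)) {
    return(data.frame(bin_start_s = numeric(0), bin_end_s = numeric(0),
                      n_cells = integer(0), mean_velocity_um_s = numeric(0),
                      se_velocity_um_s = numeric(0)))
  }
  bin <- floor(points$t_s / cfg$bin_5min)
  out <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    st <- two_step_mean(points$speed_um_s[sel], points$cell_id[sel])
    data.frame(bin_start_s = b * cfg$bin_5min,
               bin_end_s = (b + 1) * cfg$bin_5min,
               n_cells = st$n_cells,
               mean_velocity_um_s = st$mean,
               se_velocity_um_s = st$se)
  })
  do.call(rbind, out)
}

#' Per-bin motion-mode proportions with two-step averaging
#'
#' Each trajectory is assigned to the time bin containing its midpoint;
#' per cell and bin the fraction of trajectories in each mode is computed
#' (the three mode fractions sum to 1; unclassified trajectories are
#' excluded from the denominator and reported separately), then fractions
#' are averaged unweighted across cells.
#'
#' @param labels data.frame with columns `cell_id`, `traj_id`, `mode`,
#'   `t_mid_s` (pooled [classify_mode()] rows).
#' @param cfg An [analysis_config()]; `bin_15min` sets the bin width.
#' @return data.frame: `bin_start_s`, `mode`, `n_cells`, `proportion`,
#'   `se`; modes are the three diffusive classes plus `"unclassified"`.
#' @export
mode_proportions <- function(labels, cfg = analysis_config()) {
  modes <- c("constrained", "subdiffusive", "superdiffusive")
  if (!nrow(labels)) {
    return(data.frame(bin_start_s = numeric(0), mode = character(0),
                      n_cells = integer(0), proportion = numeric(0),
                      se = numeric(0)))
  }
  bin <- floor(labels$t_mid_s / cfg$bin_15min)
  out <- list()
  for (b in sort(unique(bin))) {
    sel <- labels[bin == b, , drop = FALSE]
    if (!nrow(sel)) {
      warning(sprintf("empty %g-s bin starting at %g s omitted",
                      cfg$bin_15min, b * cfg$bin_15min))
      next
    }
    for (m in c(modes, "unclassified")) {
      frac <- tapply(sel$mode, sel$cell_id, function(md) {
        cls <- md[md != "unclassified"]
        if (m == "unclassified") return(mean(md == "unclassified"))
        if (!length(cls)) return(NA_real_)
        mean(cls == m)
      })
      frac <- frac[!is.na(frac)]
      if (!length(frac)) next
      out[[length(out) + 1L]] <- data.frame(
        bin_start_s = b * cfg$bin_15min, mode = m,
        n_cells = length(frac), proportion = mean(frac),
        se = if (length(frac) > 1L) stats::sd(frac) / sqrt(length(frac)) else 0
      )
    }
  }
  do.call(rbind, out)
}

#' Mean segment velocity per run-length bin
#'
#' Buckets directed segments by run length into left-closed, right-open
#' bins and reports the mean and standard error of the per-segment mean
#' velocities in each bucket; segments beyond the last edge fall into an
#' overflow bucket.
#'
#' @param segments data.frame of directed segments (needs
#'   `run_length_um`, `mean_velocity_um_s`).
#' @param length_bin_edges Increasing numeric vector of bin edges (um).
#' @return data.frame: `bin_lo_um`, `bin_hi_um`, `n_segments`,
#'   `mean_velocity_um_s`, `se_velocity_um_s`.
#' @export
velocity_vs_runlength <- function(segments, length_bin_edges) {
  if (!nrow(segments)) stop("no segments supplied", call. = FALSE)
  edges <- sort(length_bin_edges)
  lo <- c(-Inf, edges[-length(edges)], edges[length(edges)])
  hi <- c(edges[1L], edges[-1L], Inf)
  out <- list()
  for (k in seq_along(lo)) {
    sel <- segments$run_length_um >= lo[k] & segments$run_length_um < hi[k]
    if (!any(sel)) next
    v <- segments$mean_velocity_um_s[sel]
    out[[length(out) + 1L]] <- data.frame(
      bin_lo_um = lo[k], bin_hi_um = hi[k], n_segments = sum(sel),
      mean_velocity_um_s = mean(v),
      se_velocity_um_s = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
    )
  }
  do.call(rbind, out)
}
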