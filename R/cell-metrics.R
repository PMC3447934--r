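# Single-cell trafficking metrics: the endocytic ratio time series (how
# deep the tracked cargo sits inside the cell) and the normalized mean
# puncta-intensity time series (which rises as quantum dots fuse into
# brighter aggregates).

#' Endocytic ratio of one frame
#'
#' For every punctum at distance `a` from the cell center, `b` is the
#' distance from the center to the first crossing of the ray through the
#' punctum with the cell boundary. The frame's endocytic ratio is the mean
#' of `b/a` (default), or `mean(b)/mean(a)` with
#' `ratio_method = "ratio_of_means"`. The ratio is 1 when all puncta sit
#' on the boundary and grows as cargo approaches the center; puncta
#' exactly at the center (`a = 0`) are excluded as the ratio is undefined
#' there.
#'
#' @param points Matrix or data.frame of punctum positions (columns x, y
#'   or `x_um`, `y_um`), micrometres.
#' @param geom A [cell_geometry()].
#' @param ratio_method `"mean_of_ratios"` or `"ratio_of_means"`.
#' @return List `R`, `n_points` (points used), `valid`.
#' @export
endocytic_ratio_frame <- function(points, geom,
                                  ratio_method = c("mean_of_ratios",
                                                   "ratio_of_means")) {
  ratio_method <- match.arg(ratio_method)
  stopifnot(inherits(geom, "cell_geometry"))
  if (is.data.frame(points)) {
    xc <- if ("x_um" %in% names(points)) points$x_um else points[[1L]]
    yc <- if ("y_um" %in% names(points)) points$y_um else points[[2L]]
    points <- cbind(xc, yc)
  }
  points <- matrix(as.numeric(points), ncol = 2L)
  if (!nrow(points)) return(list(R = NA_real_, n_points = 0L, valid = FALSE))
  rel <- sweep(points, 2L, geom$center)
  a <- sqrt(rowSums(rel^2))
  keep <- a > 1e-12
  if (!any(keep)) return(list(R = NA_real_, n_points = 0L, valid = FALSE))
  b <- ray_boundary_distance(geom$center, rel[keep, , drop = FALSE],
                             geom$boundary)
  ok <- is.finite(b)
  if (!any(ok)) return(list(R = NA_real_, n_points = 0L, valid = FALSE))
  a <- a[keep][ok]
  b <- b[ok]
  R <- switch(ratio_method,
    mean_of_ratios = mean(b / a),
    ratio_of_means = mean(b) / mean(a)
  )
  list(R = R, n_points = length(a), valid = TRUE)
}

#' Endocytic ratio time series of a recording
#'
#' Computes the per-frame endocytic ratio from all trajectory points
#' present in each frame and smooths the series with a centered moving
#' average of `smooth_points` adjacent frames (window truncated at the
#' ends). Frames with no points are carried as gaps (`NA`) and excluded
#' from the smoothing.
#'
#' @param recording A [cell_recording()] with geometry.
#' @param cfg An [analysis_config()]; uses `smooth_points` and
#'   `ratio_method`.
#' @return data.frame of class `endocytic_ratio_series`: `frame`, `t_s`,
#'   `n_points`, `R_raw`, `R_smooth`.
#' @export
endocytic_ratio_series <- function(recording, cfg = analysis_config()) {
  stopifnot(inherits(recording, "cell_recording"))
  if (is.null(recording$geometry)) {
    stop("recording has no geometry annotation", call. = FALSE)
  }
  tr <- recording$trajectories
  frames <- if (nrow(tr)) seq(min(tr$frame), max(tr$frame)) else integer(0)
  R <- rep(NA_real_, length(frames))
  npt <- integer(length(frames))
  idx <- split(seq_len(nrow(tr)), tr$frame)
  for (k in seq_along(frames)) {
    rows <- idx[[as.character(frames[k])]]
    if (is.null(rows)) next
    res <- endocytic_ratio_frame(
      cbind(tr$x_um[rows], tr$y_um[rows]), recording$geometry,
      cfg$ratio_method
    )
    if (res$valid) {
      R[k] <- res$R
      npt[k] <- res$n_points
    }
  }
  smooth <- rep(NA_real_, length(frames))
  obs <- which(!is.na(R))
  if (length(obs)) {
    smooth[obs] <- zoo::rollapply(R[obs], width = cfg$smooth_points,
                                  FUN = mean, partial = TRUE)
  }
  structure(
    data.frame(frame = frames, t_s = frames * recording$dt,
               n_points = npt, R_raw = R, R_smooth = smooth),
    class = c("endocytic_ratio_series", "data.frame")
  )
}

#' Normalized mean puncta-intensity time series
#'
#' Per frame, the mean intensity over all visible puncta (single or
#' aggregated quantum dots) in the cell; the series is normalized to its
#' value in the first frame that contains at least one punctum. Because
#' fusion conserves total intensity while reducing the punctum count, the
#' normalized series rises as endosomal fusion proceeds.
#'
#' @param puncta data.frame with columns `frame` and `intensity` (one row
#'   per visible punctum), e.g. `recording$puncta`.
#' @param dt Seconds per frame.
#' @return data.frame of class `intensity_series`: `frame`, `t_s`,
#'   `n_puncta`, `mean_intensity`, `normalized`. Frames with no puncta are
#'   gaps (`NA`).
#' @export
normalized_intensity_series <- function(puncta, dt = 0.1) {
  if (!all(c("frame", "intensity") %in% names(puncta))) {
    stop("`puncta` needs columns frame and intensity", call. = FALSE)
  }
  puncta <- puncta[puncta$intensity > 0, , drop = FALSE]
  if (!nrow(puncta)) stop("no visible puncta", call. = FALSE)
  frames <- seq(min(puncta$frame), max(puncta$frame))
  mi <- rep(NA_real_, length(frames))
  np <- integer(length(frames))
  agg_mean <- tapply(puncta$intensity, puncta$frame, mean)
  agg_n <- tapply(puncta$intensity, puncta$frame, length)
  pos <- match(as.integer(names(agg_mean)), frames)
  mi[pos] <- agg_mean
  np[pos] <- agg_n
  first <- which(!is.na(mi))[1L]
  if (!is.finite(mi[first]) || mi[first] <= 0) {
    stop("first observed frame has non-positive mean intensity", call. = FALSE)
  }
  structure(
    data.frame(frame = frames, t_s = frames * dt, n_puncta = np,
               mean_intensity = mi, normalized = mi / mi[first]),
    class = c("intensity_series", "data.frame")
  )
}
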