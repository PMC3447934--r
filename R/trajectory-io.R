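# Reading and writing trajectory tables and cell-geometry annotations.
#
# Two input dialects are supported: the ImageJ Particle Tracker report text
# (one "Trajectory k" block per particle, rows "frame x y z m0 ...", pixel
# units) and a plain CSV with columns cell_id, traj_id, frame, x_um, y_um,
# intensity. Frame indices are 0-based; positions are micrometres in the
# image convention (origin top-left, y downward).

#' Cell recording container
#'
#' One imaged cell: acquisition timing, optional geometry annotation, the
#' trajectory table, and optional per-frame puncta intensities.
#'
#' @param cell_id Identifier.
#' @param dt Seconds per frame (default 0.1, i.e. 10 Hz acquisition).
#' @param pixel_size Micrometres per pixel (default 0.267).
#' @param geometry A [cell_geometry()] or NULL.
#' @param trajectories data.frame with columns `cell_id`, `traj_id`,
#'   `frame`, `x_um`, `y_um` and optionally `intensity`.
#' @param puncta Optional data.frame of per-frame puncta intensities
#'   (columns `frame`, `punctum_id`, `intensity`, optionally positions).
#' @return Object of class `cell_recording`.
#' @export
cell_recording <- function(cell_id, dt = 0.1, pixel_size = 0.267,
                           geometry = NULL, trajectories = NULL,
                           puncta = NULL) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (pixel_size <= 0) stop("`pixel_size` must be positive", call. = FALSE)
  if (is.null(trajectories)) {
    trajectories <- data.frame(
      cell_id = character(0), traj_id = character(0), frame = integer(0),
      x_um = numeric(0), y_um = numeric(0), intensity = numeric(0)
    )
  }
  need <- c("traj_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(trajectories))) {
    stop("`trajectories` must have columns traj_id, frame, x_um, y_um",
         call. = FALSE)
  }
  if (!"cell_id" %in% names(trajectories)) trajectories$cell_id <- cell_id
  if (!all(is.finite(trajectories$x_um)) || !all(is.finite(trajectories$y_um))) {
    stop("non-finite trajectory coordinates", call. = FALSE)
  }
  ord <- order(trajectories$traj_id, trajectories$frame)
  trajectories <- trajectories[ord, , drop = FALSE]
  rownames(trajectories) <- NULL
  bad <- tapply(trajectories$frame, trajectories$traj_id,
                function(f) any(diff(f) <= 0))
  if (any(unlist(bad, use.names = FALSE))) {
    stop("frame indices must be strictly increasing within a trajectory",
         call. = FALSE)
  }
  structure(list(
    cell_id = cell_id, dt = dt, pixel_size = pixel_size,
    geometry = geometry, trajectories = trajectories, puncta = puncta
  ), class = "cell_recording")
}

#' @export
print.cell_recording <- function(x, ...) {
  cat(sprintf(
    "<cell_recording> %s: %d trajectories, %d points, dt = %g s%s\n",
    x$cell_id, length(unique(x$trajectories$traj_id)),
    nrow(x$trajectories), x$dt,
    if (is.null(x$geometry)) "" else ", with geometry"
  ))
  invisible(x)
}

#' Split a recording's trajectory table into per-trajectory data frames
#'
#' @param recording A [cell_recording()].
#' @return Named list of data.frames, one per trajectory, ordered by frame.
#' @export
split_trajectories <- function(recording) {
  tr <- recording$trajectories
  split(tr, tr$traj_id)
}

#' Read an ImageJ Particle Tracker report text file
#'
#' Parses the per-trajectory blocks of the Particle Tracker plugin report
#' ("Trajectory k" header followed by per-frame rows: frame, x, y, z and
#' optional intensity-moment columns; whitespace separated, pixel units).
#' The first numeric column after z, when present, is taken as the
#' zeroth-order intensity moment; remaining moment columns are parsed but
#' ignored. Pixel coordinates are converted to micrometres.
#'
#' @param path Path to the text file.
#' @param cell_id Identifier for the resulting recording.
#' @param dt Seconds per frame.
#' @param pixel_size Micrometres per pixel (default 0.267).
#' @return A [cell_recording()] (without geometry).
#' @export
read_particle_tracker_text <- function(path, cell_id = "cell1", dt = 0.1,
                                       pixel_size = 0.267) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    warning("empty tracker file: ", path)
    return(cell_recording(cell_id, dt = dt, pixel_size = pixel_size))
  }
  rows <- list()
  current <- NA_character_
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (!nzchar(s)) next
    if (grepl("^%+\\s*Trajectory\\s+\\d+", s, ignore.case = TRUE) ||
        grepl("^Trajectory\\s+\\d+", s, ignore.case = TRUE)) {
      current <- sub("^.*?Trajectory\\s+(\\d+).*$", "\\1", s, ignore.case = TRUE)
      next
    }
    if (grepl("^[%#]", s)) next                     # other comment lines
    if (grepl("^[A-Za-z]", s)) next                 # column header rows
    vals <- suppressWarnings(as.numeric(strsplit(s, "[\\s,]+", perl = TRUE)[[1]]))
    if (anyNA(vals) || length(vals) < 3L) {
      stop(sprintf("unparseable tracker row at line %d: '%s'", ln, s),
           call. = FALSE)
    }
    if (is.na(current)) {
      stop(sprintf("data row before any 'Trajectory' header at line %d", ln),
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      traj_id = paste0("t", current),
      frame = as.integer(vals[1L]),
      x_px = vals[2L],
      y_px = vals[3L],
      intensity = if (length(vals) >= 5L) vals[5L] else NA_real_
    )
  }
  if (!length(rows)) {
    warning("tracker file contained headers but no data rows: ", path)
    return(cell_recording(cell_id, dt = dt, pixel_size = pixel_size))
  }
  df <- do.call(rbind, rows)
  cell_recording(
    cell_id, dt = dt, pixel_size = pixel_size,
    trajectories = data.frame(
      cell_id = cell_id,
      traj_id = df$traj_id,
      frame = df$frame,
      x_um = df$x_px * pixel_size,
      y_um = df$y_px * pixel_size,
      intensity = df$intensity
    )
  )
}

#' Write / read the trajectory CSV interchange format
#'
#' Columns: cell_id, traj_id, frame, x_um, y_um, intensity. An optional
#' `#`-prefixed header line carries provenance (e.g. a config hash).
#'
#' @param recording A [cell_recording()].
#' @param path Output path.
#' @param header_comment Optional single comment line written before the
#'   CSV header (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(recording, path, header_comment = NULL) {
  tr <- recording$trajectories
  if (!"intensity" %in% names(tr)) tr$intensity <- NA_real_
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(
    tr[, c("cell_id", "traj_id", "frame", "x_um", "y_um", "intensity")],
    con, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param dt,pixel_size Acquisition parameters for the reconstructed
#'   recording.
#' @export
read_trajectory_csv <- function(path, dt = 0.1, pixel_size = 0.267) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  cell_id <- if (nrow(df)) df$cell_id[1L] else "cell1"
  cell_recording(cell_id, dt = dt, pixel_size = pixel_size, trajectories = df)
}

#' Select trajectories longer than a minimum number of frames
#'
#' Keeps trajectories with strictly more than `min_frames` points (the
#' selection used before any dynamics analysis; short tracks carry too few
#' points for windowed MSD statistics).
#'
#' @param recording A [cell_recording()].
#' @param min_frames Length threshold (default 50); a trajectory is kept
#'   iff its number of points exceeds this value.
#' @return The filtered [cell_recording()]; the number of removed
#'   trajectories is reported via `message()`.
#' @export
filter_trajectories <- function(recording, min_frames = 50L) {
  tr <- recording$trajectories
  len <- table(tr$traj_id)
  keep_ids <- names(len)[len > min_frames]
  removed <- length(len) - length(keep_ids)
  if (removed > 0L) {
    message(sprintf("filter_trajectories: removed %d of %d trajectories (<= %d frames)",
                    removed, length(len), min_frames))
  }
  recording$trajectories <- tr[tr$traj_id %in% keep_ids, , drop = FALSE]
  rownames(recording$trajectories) <- NULL
  recording
}

#' Read / write a cell-geometry annotation (JSON)
#'
#' The annotation stands in for the manual selection of the cell outline
#' and nucleus center on a DIC image. Format: a JSON object with fields
#' `units` (must be "um"), `boundary` (array of `[x, y]` vertices) and
#' `center` (`[x, y]`). Validation (simple closed polygon, center strictly
#' inside) happens in [cell_geometry()].
#'
#' @param path File path.
#' @return A [cell_geometry()].
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(g$units) || !identical(g$units, "um")) {
    stop("geometry file must declare units: \"um\"", call. = FALSE)
  }
  cell_geometry(matrix(as.numeric(g$boundary), ncol = 2L, byrow = FALSE),
                as.numeric(g$center))
}

#' @rdname read_geometry
#' @param geometry A [cell_geometry()].
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "cell_geometry"))
  jsonlite::write_json(
    list(units = "um",
         boundary = unname(geometry$boundary),
         center = geometry$center),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}
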