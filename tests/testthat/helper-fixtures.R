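# Shared fixture builders. Everything is generated in code; seeds are
# fixed so the suite is deterministic.

# trajectory data.frame from explicit coordinates
make_traj <- function(x, y, dt = 0.1, id = "t1") {
  n <- length(x)
  tr <- data.frame(
    frame = seq_len(n) - 1L,
    t_s = (seq_len(n) - 1L) * dt,
    x_um = x, y_um = y
  )
  attr(tr, "traj_id") <- id
  tr
}

# straight-line ballistic trajectory, speed v um/s at angle theta
ballistic_traj <- function(n, v = 1, theta = 0, dt = 0.1, id = "t1") {
  t <- (seq_len(n) - 1L) * dt
  make_traj(v * t * cos(theta), v * t * sin(theta), dt, id)
}

# recording holding one or more trajectory data.frames
make_recording <- function(..., cell_id = "cellA", dt = 0.1, geometry = NULL,
                           puncta = NULL) {
  trs <- list(...)
  long <- do.call(rbind, lapply(seq_along(trs), function(k) {
    tr <- trs[[k]]
    id <- attr(tr, "traj_id", exact = TRUE)
    if (is.null(id)) id <- paste0("t", k)
    data.frame(cell_id = cell_id, traj_id = id, frame = tr$frame,
               x_um = tr$x_um, y_um = tr$y_um)
  }))
  cell_recording(cell_id, dt = dt, geometry = geometry,
                 trajectories = long, puncta = puncta)
}

# square cell geometry fixture
square_geometry <- function(side = 10) {
  cell_geometry(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)),
                c(side / 2, side / 2))
}

# independent oracle for the boundary distance b: bisection along the ray
# using pracma::inpolygon (different algorithm and code path than the
# package's edge-intersection solver)
oracle_ray_distance <- function(origin, dir, poly, tol = 1e-9) {
  d <- dir / sqrt(sum(dir^2))
  hi <- 1
  while (pracma::inpolygon(origin[1] + hi * d[1], origin[2] + hi * d[2],
                           poly[, 1], poly[, 2])) {
    hi <- hi * 2
    if (hi > 1e6) stop("oracle: ray never leaves polygon")
  }
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pracma::inpolygon(origin[1] + mid * d[1], origin[2] + mid * d[2],
                          poly[, 1], poly[, 2])) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# random simple star-shaped polygon around a center
random_polygon <- function(seed, n_vertices = 12L, r_range = c(4, 10),
                           center = c(0, 0)) {
  withr::with_seed(seed, {
    theta <- sort(stats::runif(n_vertices, 0, 2 * pi))
    r <- stats::runif(n_vertices, r_range[1], r_range[2])
    cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
  })
}

# brute-force pixelwise M1 oracle (explicit double loop)
oracle_m1 <- function(red, green, thr) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(red))) {
    for (j in seq_len(ncol(red))) {
      den <- den + red[i, j]
      if (green[i, j] > thr) num <- num + red[i, j]
    }
  }
  num / den
}
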