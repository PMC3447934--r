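# Planar polygon utilities shared by the cell-geometry reader, the scene
# generator and the endocytic-ratio metric. Polygons are n x 2 matrices of
# vertices in order (open representation: the closing edge V[n] -> V[1] is
# implied). Coordinates follow the image convention: origin at the top-left,
# y increasing downward, units micrometres.

#' Construct a cell geometry
#'
#' Bundles a boundary polygon with a reference center point (in real cells
#' the manually annotated nucleus position). The polygon must be simple
#' (non-self-intersecting) and the center must lie strictly inside it.
#'
#' @param boundary Numeric matrix (n x 2) of polygon vertices in order, in
#'   micrometres. The polygon is treated as closed; do not repeat the first
#'   vertex. A closing duplicate vertex, if present, is dropped.
#' @param center Numeric length-2 vector, the cell center in micrometres.
#' @return An object of class `cell_geometry` with elements `boundary` and
#'   `center`.
#' @export
cell_geometry <- function(boundary, center) {
  boundary <- as.matrix(boundary)
  storage.mode(boundary) <- "double"
  if (ncol(boundary) != 2L || nrow(boundary) < 3L) {
    stop("`boundary` must be an n x 2 matrix with n >= 3", call. = FALSE)
  }
  n <- nrow(boundary)
  if (n > 3L && isTRUE(all(boundary[1L, ] == boundary[n, ]))) {
    boundary <- boundary[-n, , drop = FALSE]
  }
  if (!all(is.finite(boundary))) stop("non-finite boundary vertex", call. = FALSE)
  center <- as.numeric(center)
  if (length(center) != 2L || !all(is.finite(center))) {
    stop("`center` must be a finite length-2 numeric", call. = FALSE)
  }
  if (!polygon_is_simple(boundary)) {
    stop("boundary polygon is self-intersecting", call. = FALSE)
  }
  if (!point_in_polygon(center[1L], center[2L], boundary)) {
    stop("center lies outside the boundary polygon", call. = FALSE)
  }
  structure(list(boundary = boundary, center = center), class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "<cell_geometry> %d vertices, center (%.3f, %.3f) um\n",
    nrow(x$boundary), x$center[1L], x$center[2L]
  ))
  invisible(x)
}

# TRUE if no two non-adjacent edges intersect (shared endpoints between
# adjacent edges are allowed). O(n^2) over edges; cell outlines are small.
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      if (segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- cross2(q2 - q1, p1 - q1)
  d2 <- cross2(q2 - q1, p2 - q1)
  d3 <- cross2(p2 - p1, q1 - p1)
  d4 <- cross2(p2 - p1, q2 - p1)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  on_seg <- function(p, a, b) {
    min(a[1], b[1]) <= p[1] && p[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= p[2] && p[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p1, q1, q2)) || (d2 == 0 && on_seg(p2, q1, q2)) ||
    (d3 == 0 && on_seg(q1, p1, p2)) || (d4 == 0 && on_seg(q2, p1, p2))
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

#' Test whether points lie inside a polygon
#'
#' Even-odd (ray crossing) rule; points exactly on an edge count as inside.
#'
#' @param x,y Numeric vectors of point coordinates.
#' @param poly n x 2 vertex matrix.
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  px <- poly[, 1L]; py <- poly[, 2L]
  qx <- px[c(2:n, 1L)]; qy <- py[c(2:n, 1L)]
  vapply(seq_along(x), function(k) {
    xi <- x[k]; yi <- y[k]
    inside <- FALSE
    for (e in seq_len(n)) {
      x1 <- px[e]; y1 <- py[e]; x2 <- qx[e]; y2 <- qy[e]
      # on-edge check
      if (abs(cross2(c(x2 - x1, y2 - y1), c(xi - x1, yi - y1))) < 1e-12 &&
          xi >= min(x1, x2) - 1e-12 && xi <= max(x1, x2) + 1e-12 &&
          yi >= min(y1, y2) - 1e-12 && yi <= max(y1, y2) + 1e-12) {
        return(TRUE)
      }
      if ((y1 > yi) != (y2 > yi)) {
        xint <- x1 + (yi - y1) / (y2 - y1) * (x2 - x1)
        if (xi < xint) inside <- !inside
      }
    }
    inside
  }, logical(1L))
}

#' Distance from a point to the polygon boundary along given rays
#'
#' For each direction, returns the distance from `origin` to the first
#' crossing of the ray `origin + t * dir` (t > 0) with the polygon boundary.
#' This is the boundary radius "b" used by the endocytic ratio.
#'
#' @param origin Length-2 numeric, ray origin (must be inside the polygon).
#' @param dir m x 2 matrix of ray directions (need not be unit length).
#' @param poly n x 2 vertex matrix.
#' @return Numeric vector of m distances (in the units of the inputs).
#' @export
ray_boundary_distance <- function(origin, dir, poly) {
  dir <- matrix(as.numeric(dir), ncol = 2L)
  n <- nrow(poly)
  p <- poly
  q <- poly[c(2:n, 1L), , drop = FALSE]
  ex <- q[, 1L] - p[, 1L]
  ey <- q[, 2L] - p[, 2L]
  rx <- p[, 1L] - origin[1L]
  ry <- p[, 2L] - origin[2L]
  out <- numeric(nrow(dir))
  for (k in seq_len(nrow(dir))) {
    d <- dir[k, ]
    nd <- sqrt(sum(d^2))
    if (nd == 0) { out[k] <- NA_real_; next }
    d <- d / nd
    # solve origin + t d = p + u e  for each edge
    det <- d[1L] * (-ey) - d[2L] * (-ex)
    ok <- abs(det) > 1e-14
    t <- (rx * (-ey) - ry * (-ex)) / det
    u <- (d[1L] * ry - d[2L] * rx) / det
    hit <- ok & t > 1e-9 & u >= -1e-12 & u <= 1 + 1e-12
    out[k] <- if (any(hit)) min(t[hit]) else NA_real_
  }
  out
}

#' Regular or radially perturbed polygon approximating a cell outline
#'
#' @param radius Mean boundary radius (um).
#' @param center Length-2 center.
#' @param n_vertices Number of polygon vertices.
#' @param irregularity Relative amplitude of a smooth periodic radial
#'   perturbation (0 gives a regular polygon approximating a circle).
#' @param seed Integer seed for the perturbation phase/amplitudes.
#' @return n x 2 vertex matrix.
#' @export
make_cell_boundary <- function(radius, center = c(0, 0), n_vertices = 64L,
                               irregularity = 0, seed = 1L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- rep(radius, n_vertices)
  if (irregularity > 0) {
    withr::with_seed(as.integer(seed), {
      # low-order Fourier perturbation keeps the outline smooth and simple
      for (m in 2:4) {
        r <- r + radius * irregularity * stats::rnorm(1L, 0, 0.5) *
          cos(m * theta + stats::runif(1L, 0, 2 * pi)) / (m - 1)
      }
    })
    r <- pmax(r, 0.3 * radius)
  }
  cbind(center[1L] + r * cos(theta), center[2L] + r * sin(theta))
}
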