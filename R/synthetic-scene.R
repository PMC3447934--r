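# Whole-cell synthetic scenes: an ensemble of state-switching trajectories
# seeded near the cell boundary, drifting inward toward the center over the
# movie, with two-state quantum-dot blinking and pairwise vesicle fusion
# that conserves total intensity. Fused aggregates stop blinking, as
# aggregated quantum dots do.

#' Scene (whole-cell simulation) parameters
#'
#' @param n_trajectories Number of vesicle trajectories (>= 1).
#' @param n_frames Movie length in frames.
#' @param cell_radius Mean boundary radius, um.
#' @param boundary_irregularity Relative amplitude of the smooth radial
#'   perturbation of the boundary (0 = circular outline).
#' @param inward_drift_speed Radial drift toward the cell center, um/s.
#' @param on_rate,off_rate Per-frame blinking transition probabilities
#'   (OFF to ON, ON to OFF) for unfused quantum dots.
#' @param fusion_rate Per-frame merge probability for each pair of visible
#'   puncta closer than `fusion_radius`.
#' @param fusion_radius Maximum pair distance (um) at which fusion can
#'   occur.
#' @param base_intensity Emission intensity of a single unfused quantum dot
#'   (arbitrary units).
#' @param seed Integer seed for the whole scene.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(n_trajectories = 30L,
                         n_frames = 600L,
                         cell_radius = 15,
                         boundary_irregularity = 0,
                         inward_drift_speed = 0.01,
                         on_rate = 0.3,
                         off_rate = 0.1,
                         fusion_rate = 0.02,
                         fusion_radius = 0.3,
                         base_intensity = 1,
                         seed = 1L) {
  if (n_trajectories < 1L) stop("`n_trajectories` must be >= 1", call. = FALSE)
  if (n_frames < 2L) stop("`n_frames` must be >= 2", call. = FALSE)
  if (cell_radius <= 0) stop("`cell_radius` must be positive", call. = FALSE)
  for (r in c(on_rate, off_rate, fusion_rate)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (inward_drift_speed < 0) stop("`inward_drift_speed` must be >= 0", call. = FALSE)
  structure(list(
    n_trajectories = as.integer(n_trajectories),
    n_frames = as.integer(n_frames),
    cell_radius = cell_radius,
    boundary_irregularity = boundary_irregularity,
    inward_drift_speed = inward_drift_speed,
    on_rate = on_rate, off_rate = off_rate,
    fusion_rate = fusion_rate, fusion_radius = fusion_radius,
    base_intensity = base_intensity,
    seed = as.integer(seed)
  ), class = "scene_params")
}

#' Simulate a whole-cell scene with ground truth
#'
#' Trajectories start near the cell boundary and drift toward the center at
#' `inward_drift_speed` on top of their state-switching motion; positions
#' are reflected at the boundary so no vesicle leaves the cell. Per-frame
#' puncta intensities are produced by two-state blinking and by pairwise
#' fusion events: when two visible puncta closer than `fusion_radius`
#' merge, the absorbed trajectory ends, the surviving punctum carries the
#' summed base intensity, and the aggregate no longer blinks.
#'
#' @param scene A [scene_params()] object.
#' @param motion A [motion_params()] object.
#' @param cell_id Identifier stored in the recording.
#' @return A list with elements
#'   \describe{
#'     \item{recording}{a [cell_recording()]: geometry, observed trajectory
#'       table and per-frame puncta intensities.}
#'     \item{truth}{list with per-trajectory state labels, true directed
#'       segments, per-frame punctum counts, total base intensity, and the
#'       fusion event log.}
#'   }
#' @export
simulate_cell_scene <- function(scene, motion, cell_id = "cell1") {
  stopifnot(inherits(scene, "scene_params"), inherits(motion, "motion_params"))
  dt <- motion$dt
  max_step <- (scene$inward_drift_speed + motion$v_directed) * dt
  if (max_step > scene$cell_radius) {
    stop("per-frame drift exceeds the cell radius; reduce `inward_drift_speed`",
         call. = FALSE)
  }

  withr::with_seed(as.integer(scene$seed), {
    boundary <- make_cell_boundary(
      scene$cell_radius, c(0, 0), 64L,
      scene$boundary_irregularity, seed = stats::runif(1L, 1, 1e6)
    )
    geom <- cell_geometry(boundary, c(0, 0))

    drift_fun <- function(p) {
      r <- sqrt(sum(p^2))
      if (r < 1e-9) return(c(0, 0))
      -scene$inward_drift_speed * dt * p / r
    }
    reflect_fun <- function(p) {
      r <- sqrt(sum(p^2))
      if (r < 1e-9) return(p)
      b <- ray_boundary_distance(c(0, 0), matrix(p, 1L), boundary)
      if (is.na(b)) b <- scene$cell_radius
      if (r > b) {
        r_new <- max(min(2 * b - r, b * 0.999), 0)
        p <- p * r_new / r
      }
      p
    }

    n <- scene$n_trajectories
    nf <- scene$n_frames
    pos <- array(NA_real_, c(nf, 2L, n))
    states <- vector("list", n)
    for (k in seq_len(n)) {
      theta <- stats::runif(1L, 0, 2 * pi)
      b0 <- ray_boundary_distance(c(0, 0), cbind(cos(theta), sin(theta)), boundary)
      start <- c(cos(theta), sin(theta)) * b0 * stats::runif(1L, 0.75, 0.92)
      path <- simulate_path_engine(motion, nf, start, drift_fun, reflect_fun)
      pos[, , k] <- path$pos
      states[[k]] <- path$states
    }

    # blinking state per (frame, trajectory); start ON
    blink_on <- matrix(TRUE, nf, n)
    for (k in seq_len(n)) {
      on <- TRUE
      for (f in seq_len(nf)) {
        blink_on[f, k] <- on
        on <- if (on) stats::runif(1L) >= scene$off_rate
              else stats::runif(1L) < scene$on_rate
      }
    }

    # fusion bookkeeping: each trajectory belongs to a group; the group is
    # hosted by one live trajectory whose path the punctum follows
    host <- seq_len(n)          # group host per trajectory (union-find style)
    base <- rep(scene$base_intensity, n)  # base intensity per live host
    alive <- rep(TRUE, n)
    aggregated <- rep(FALSE, n)
    end_frame <- rep(nf - 1L, n)
    fusions <- list()

    puncta <- vector("list", nf)
    n_punctum <- integer(nf)
    total_base <- numeric(nf)
    for (f in seq_len(nf)) {
      live <- which(alive)
      # pairwise fusion among visible puncta
      if (scene$fusion_rate > 0 && length(live) > 1L) {
        for (a_i in seq_along(live)) {
          for (b_i in seq_along(live)) {
            if (b_i <= a_i) next
            i <- live[a_i]; j <- live[b_i]
            if (!alive[i] || !alive[j]) next
            dij <- sqrt(sum((pos[f, , i] - pos[f, , j])^2))
            if (dij <= scene$fusion_radius &&
                stats::runif(1L) < scene$fusion_rate) {
              base[i] <- base[i] + base[j]
              aggregated[i] <- TRUE
              alive[j] <- FALSE
              end_frame[j] <- f - 1L
              fusions[[length(fusions) + 1L]] <-
                data.frame(frame = f - 1L, survivor = i, absorbed = j)
            }
          }
        }
        live <- which(alive)
      }
      visible <- live[aggregated[live] | blink_on[f, live]]
      ints <- base[visible]
      puncta[[f]] <- data.frame(
        frame = f - 1L,
        punctum_id = visible,
        x_um = pos[f, 1L, visible],
        y_um = pos[f, 2L, visible],
        intensity = ints
      )
      n_punctum[f] <- length(visible)
      total_base[f] <- sum(base[live])
    }

    noise <- array(stats::rnorm(nf * 2L * n, 0, motion$loc_noise_sigma),
                   c(nf, 2L, n))
    obs <- pos + noise
    traj_list <- lapply(seq_len(n), function(k) {
      f <- 0:end_frame[k]
      data.frame(
        cell_id = cell_id,
        traj_id = sprintf("t%03d", k),
        frame = f,
        x_um = obs[f + 1L, 1L, k],
        y_um = obs[f + 1L, 2L, k],
        intensity = ifelse(aggregated[k] | blink_on[f + 1L, k], base[k], 0)
      )
    })
    trajectories <- do.call(rbind, traj_list)

    rec <- cell_recording(
      cell_id = cell_id, dt = dt, geometry = geom,
      trajectories = trajectories,
      puncta = do.call(rbind, puncta)
    )
    truth <- list(
      states = lapply(seq_len(n), function(k) states[[k]][1:(end_frame[k] + 1L)]),
      segments = do.call(rbind, lapply(seq_len(n), function(k) {
        seg <- state_runs(states[[k]][1:(end_frame[k] + 1L)], "directed",
                          motion$v_directed)
        if (nrow(seg)) seg$traj_id <- sprintf("t%03d", k)
        seg
      })),
      n_puncta = n_punctum,
      total_base_intensity = total_base,
      fusions = if (length(fusions)) do.call(rbind, fusions) else NULL,
      positions_true = pos
    )
    list(recording = rec, truth = truth)
  })
}

#' Two-state quantum-dot blinking intensity trace
#'
#' A telegraph process: ON frames emit `base_intensity` (plus optional
#' Gaussian shot noise), OFF frames emit zero. `n_fused` > 1 models an
#' aggregate of fused dots, which emits the summed base intensity and does
#' not blink off.
#'
#' @param on_rate Per-frame probability of switching OFF to ON.
#' @param off_rate Per-frame probability of switching ON to OFF.
#' @param base_intensity Emission of one dot (arbitrary units).
#' @param n_frames Trace length.
#' @param seed Integer seed.
#' @param start_on Initial blinking state.
#' @param n_fused Number of dots in the punctum (1 = single, blinking).
#' @param shot_noise_sd Gaussian noise added to ON frames (default 0).
#' @return Numeric vector of per-frame intensities.
#' @export
blinking_intensity_trace <- function(on_rate, off_rate, base_intensity,
                                     n_frames, seed, start_on = TRUE,
                                     n_fused = 1L, shot_noise_sd = 0) {
  if (on_rate < 0 || on_rate > 1 || off_rate < 0 || off_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (n_fused >= 2L) {
    # aggregates emit the sum of member intensities and do not blink
    return(withr::with_seed(as.integer(seed), {
      n_fused * base_intensity + stats::rnorm(n_frames, 0, shot_noise_sd)
    }))
  }
  withr::with_seed(as.integer(seed), {
    on <- start_on
    out <- numeric(n_frames)
    for (f in seq_len(n_frames)) {
      out[f] <- if (on) base_intensity + stats::rnorm(1L, 0, shot_noise_sd) else 0
      on <- if (on) stats::runif(1L) >= off_rate else stats::runif(1L) < on_rate
    }
    out
  })
}

#' Render a synthetic two-channel (red/green) image pair
#'
#' Builds a colocalization fixture with known ground truth: the green
#' channel is a uniform disk region, the red channel is a set of Gaussian
#' puncta placed so that exactly `overlap_fraction` of the total red
#' intensity falls on green pixels. Gaussian kernels are truncated at four
#' standard deviations and spots are kept clear of the region edge, so the
#' constructed fraction is exact up to the truncated tails.
#'
#' @param width,height Image size in pixels.
#' @param n_spots Total number of red puncta.
#' @param overlap_fraction Target fraction of red intensity on the green
#'   region, in `[0, 1]`.
#' @param seed Integer seed.
#' @param spot_sigma Gaussian spot standard deviation, pixels.
#' @param green_level Intensity of the green region (arbitrary units).
#' @param green_radius_frac Radius of the green disk as a fraction of the
#'   smaller image dimension.
#' @return List with matrices `red` and `green`, logical matrix `mask`
#'   (the green support), and `truth` (`overlap_fraction`, spot counts).
#' @export
render_two_channel_image <- function(width = 64L, height = 64L, n_spots = 12L,
                                     overlap_fraction = 0.5, seed = 1L,
                                     spot_sigma = 1.2, green_level = 600,
                                     green_radius_frac = 0.3) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("`overlap_fraction` must lie in [0, 1]", call. = FALSE)
  }
  cx <- width / 2; cy <- height / 2
  r_green <- green_radius_frac * min(width, height)
  margin <- 4 * spot_sigma + 1

  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), width), height, width)
  mask <- (xs - cx)^2 + (ys - cy)^2 <= r_green^2
  green <- matrix(0, height, width)
  green[mask] <- green_level

  n_in <- round(overlap_fraction * n_spots)
  if (overlap_fraction > 0 && n_in == 0L) n_in <- 1L
  if (overlap_fraction < 1 && n_in == n_spots) n_in <- n_spots - 1L
  if (overlap_fraction == 0) n_in <- 0L
  if (overlap_fraction == 1) n_in <- n_spots
  n_out <- n_spots - n_in

  if (r_green - margin <= 1 && n_in > 0L) {
    stop("green region too small to contain spots; enlarge the image",
         call. = FALSE)
  }

  withr::with_seed(as.integer(seed), {
    place <- function(n, inside) {
      out <- matrix(NA_real_, n, 2L)
      k <- 0L
      while (k < n) {
        px <- stats::runif(1L, margin, width - margin)
        py <- stats::runif(1L, margin, height - margin)
        d <- sqrt((px - cx)^2 + (py - cy)^2)
        ok <- if (inside) d <= r_green - margin else d >= r_green + margin
        if (ok) {
          k <- k + 1L
          out[k, ] <- c(px, py)
        }
      }
      out
    }
    spots_in <- if (n_in > 0L) place(n_in, TRUE) else matrix(0, 0L, 2L)
    spots_out <- if (n_out > 0L) place(n_out, FALSE) else matrix(0, 0L, 2L)

    red <- matrix(0, height, width)
    stamp <- function(px, py, amp) {
      x0 <- max(1L, floor(px - 4 * spot_sigma))
      x1 <- min(width, ceiling(px + 4 * spot_sigma))
      y0 <- max(1L, floor(py - 4 * spot_sigma))
      y1 <- min(height, ceiling(py + 4 * spot_sigma))
      gx <- x0:x1; gy <- y0:y1
      g <- amp * outer(
        exp(-(gy - py)^2 / (2 * spot_sigma^2)),
        exp(-(gx - px)^2 / (2 * spot_sigma^2))
      )
      rr <- sqrt(outer((gy - py)^2, (gx - px)^2, `+`))
      g[rr > 4 * spot_sigma] <- 0
      red[gy, gx] <<- red[gy, gx] + g
      sum(g)
    }
    amps_in <- stats::runif(max(n_in, 0L), 80, 200)
    amps_out <- stats::runif(max(n_out, 0L), 80, 200)
    tot_in <- 0
    for (k in seq_len(n_in)) {
      tot_in <- tot_in + stamp(spots_in[k, 1L], spots_in[k, 2L], amps_in[k])
    }
    tot_out <- 0
    for (k in seq_len(n_out)) {
      tot_out <- tot_out + stamp(spots_out[k, 1L], spots_out[k, 2L], amps_out[k])
    }
    # rescale the inside spots so the intensity fraction is exact
    if (n_in > 0L && n_out > 0L) {
      s <- overlap_fraction * tot_out / ((1 - overlap_fraction) * tot_in)
      red[mask] <- red[mask] * s
    }
    list(
      red = red, green = green, mask = mask,
      truth = list(overlap_fraction = overlap_fraction,
                   n_spots_in = n_in, n_spots_out = n_out)
    )
  })
}
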