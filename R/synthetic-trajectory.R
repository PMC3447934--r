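# Synthetic trajectory generator. Emulates the statistical structure of
# 10 Hz quantum-dot tracking data: per-frame Markov switching among a
# confined (near-immobile) state, a sub-diffusive state with a tunable
# anomalous exponent, and a directed (transport) state, plus independent
# Gaussian localization noise on every coordinate.

MOTION_STATES <- c("constrained", "subdiffusive", "directed")

#' Motion model parameters
#'
#' Parameters of the per-trajectory motion model. Defaults reflect the
#' acquisition regime the generator emulates: 10 Hz frame rate, 20 nm
#' localization noise (within the 10--30 nm precision range of quantum-dot
#' tracking), vesicle-scale diffusivity, near-immobile confinement, and
#' microtubule-transport speeds below 1 um/s.
#'
#' @param dt Seconds per frame (default 0.1, i.e. 10 Hz).
#' @param D_free Diffusion constant in um^2/s; also the generalized
#'   coefficient K of the sub-diffusive state (um^2/s^alpha) and the scale
#'   of the confined jitter.
#' @param confinement_radius Radius (um) of the confined state; the
#'   mean-reverting walk has stationary standard deviation
#'   `confinement_radius / 2` per coordinate, so excursions rarely exceed
#'   the radius. Default 0.05 um emulates near immobility.
#' @param alpha_sub Target anomalous exponent of the sub-diffusive state,
#'   in (0, 1]. The sub-diffusive increments are fractional Gaussian noise
#'   with Hurst index `alpha_sub / 2`, so the ensemble MSD grows as
#'   `4 * D_free * t^alpha_sub`; `alpha_sub = 1` degenerates to free
#'   Brownian diffusion with diffusion constant `D_free`.
#' @param v_directed Speed (um/s) of the directed state.
#' @param heading_jitter Standard deviation (radians/frame) of the heading
#'   random walk in the directed state.
#' @param D_directed_overlay Diffusive overlay (um^2/s) added to directed
#'   motion, modelling cargo wobble around the transport track.
#' @param switch_rates 3 x 3 row-stochastic matrix of per-frame transition
#'   probabilities among the states (rows/columns ordered constrained,
#'   subdiffusive, directed), or NULL for the default slowly-switching
#'   chain.
#' @param initial_state One of `"constrained"`, `"subdiffusive"`,
#'   `"directed"`, or NULL to draw from the uniform distribution.
#' @param loc_noise_sigma Localization noise standard deviation per
#'   coordinate, um (default 0.02).
#' @return A list of class `motion_params`.
#' @export
motion_params <- function(dt = 0.1,
                          D_free = 0.01,
                          confinement_radius = 0.05,
                          alpha_sub = 0.75,
                          v_directed = 0.8,
                          heading_jitter = 0.1,
                          D_directed_overlay = 0.002,
                          switch_rates = NULL,
                          initial_state = NULL,
                          loc_noise_sigma = 0.02) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (D_free < 0 || D_directed_overlay < 0) stop("diffusivities must be >= 0", call. = FALSE)
  if (confinement_radius <= 0) stop("`confinement_radius` must be positive", call. = FALSE)
  if (alpha_sub <= 0 || alpha_sub > 1) stop("`alpha_sub` must lie in (0, 1]", call. = FALSE)
  if (v_directed < 0) stop("`v_directed` must be >= 0", call. = FALSE)
  if (loc_noise_sigma < 0) stop("`loc_noise_sigma` must be >= 0", call. = FALSE)
  if (is.null(switch_rates)) {
    switch_rates <- matrix(c(
      0.98, 0.015, 0.005,
      0.015, 0.98, 0.005,
      0.025, 0.025, 0.95
    ), nrow = 3L, byrow = TRUE)
  }
  switch_rates <- as.matrix(switch_rates)
  if (!identical(dim(switch_rates), c(3L, 3L)) ||
      any(switch_rates < 0) || any(switch_rates > 1) ||
      any(abs(rowSums(switch_rates) - 1) > 1e-8)) {
    stop("`switch_rates` must be a 3 x 3 row-stochastic matrix", call. = FALSE)
  }
  dimnames(switch_rates) <- list(MOTION_STATES, MOTION_STATES)
  if (!is.null(initial_state)) {
    initial_state <- match.arg(initial_state, MOTION_STATES)
  }
  structure(list(
    dt = dt, D_free = D_free, confinement_radius = confinement_radius,
    alpha_sub = alpha_sub, v_directed = v_directed,
    heading_jitter = heading_jitter, D_directed_overlay = D_directed_overlay,
    switch_rates = switch_rates, initial_state = initial_state,
    loc_noise_sigma = loc_noise_sigma
  ), class = "motion_params")
}

#' Single-state motion parameters
#'
#' Convenience constructor for a model that never leaves one motion state;
#' used for pure-class simulations and mode-classification truth sets.
#'
#' @param state One of the three motion states.
#' @param ... Passed on to [motion_params()].
#' @export
pure_state_params <- function(state = c("constrained", "subdiffusive", "directed"),
                              ...) {
  state <- match.arg(state)
  motion_params(..., switch_rates = diag(3L), initial_state = state)
}

# Cholesky factors of the fractional-Gaussian-noise correlation matrix,
# cached by (n, alpha) because ensemble simulations reuse them heavily.
.fgn_cache <- new.env(parent = emptyenv())

# n correlated standard-normal increments with fGn autocorrelation
# rho(k) = ((k+1)^a - 2 k^a + (k-1)^a) / 2, a = alpha = 2H.
fgn_unit_increments <- function(n, alpha) {
  key <- sprintf("%d_%.10g", n, alpha)
  L <- .fgn_cache[[key]]
  if (is.null(L)) {
    k <- 0:(n - 1L)
    rho <- ((k + 1)^alpha - 2 * k^alpha + abs(k - 1)^alpha) / 2
    C <- stats::toeplitz(rho)
    # jitter guards against numerically semi-definite C at alpha near 1
    L <- t(chol(C + diag(1e-12, n)))
    .fgn_cache[[key]] <- L
  }
  as.numeric(L %*% stats::rnorm(n))
}

# Core path engine. Assumes the RNG state is already set by the caller.
# start: length-2 position; drift_fun(pos) returns an extra per-frame
# displacement; reflect_fun(pos) maps a proposed position back inside the
# domain; state_schedule optionally fixes the per-step state sequence.
# Returns true positions (no localization noise) and per-step states.
simulate_path_engine <- function(params, n_frames, start = c(0, 0),
                                 drift_fun = NULL, reflect_fun = NULL,
                                 state_schedule = NULL) {
  n_steps <- n_frames - 1L
  dt <- params$dt

  if (!is.null(state_schedule)) {
    states <- match(rep_len(state_schedule, n_steps), MOTION_STATES)
    if (anyNA(states)) stop("unknown state in `state_schedule`", call. = FALSE)
  } else {
    # state sequence (first-order Markov, one state per step)
    states <- integer(n_steps)
    P <- params$switch_rates
    s <- if (is.null(params$initial_state)) {
      sample.int(3L, 1L)
    } else {
      match(params$initial_state, MOTION_STATES)
    }
    for (i in seq_len(n_steps)) {
      states[i] <- s
      s <- sample.int(3L, 1L, prob = P[s, ])
    }
  }

  # pre-drawn sub-diffusive increments (consumed sequentially so that a
  # sub-diffusive stint carries the long-range increment correlation)
  sig_sub <- sqrt(2 * params$D_free * dt^params$alpha_sub)
  sub_x <- sig_sub * fgn_unit_increments(n_steps, params$alpha_sub)
  sub_y <- sig_sub * fgn_unit_increments(n_steps, params$alpha_sub)

  # confined state: discrete Ornstein-Uhlenbeck around a stint anchor
  sig_stat <- params$confinement_radius / 2
  tau <- sig_stat^2 / max(params$D_free, 1e-12)
  rho <- exp(-dt / tau)
  ou_sd <- sig_stat * sqrt(1 - rho^2)

  step_dir <- sqrt(2 * params$D_directed_overlay * dt)

  pos <- matrix(NA_real_, n_frames, 2L)
  pos[1L, ] <- start
  anchor <- start
  heading <- stats::runif(1L, 0, 2 * pi)
  prev_state <- 0L
  for (i in seq_len(n_steps)) {
    p <- pos[i, ]
    st <- states[i]
    if (st != prev_state) {
      if (st == 1L) anchor <- p
      if (st == 3L) heading <- stats::runif(1L, 0, 2 * pi)
    }
    nxt <- switch(st,
      anchor + rho * (p - anchor) + stats::rnorm(2L, 0, ou_sd),
      p + c(sub_x[i], sub_y[i]),
      {
        heading <- heading + stats::rnorm(1L, 0, params$heading_jitter)
        p + params$v_directed * dt * c(cos(heading), sin(heading)) +
          stats::rnorm(2L, 0, step_dir)
      }
    )
    if (!is.null(drift_fun)) nxt <- nxt + drift_fun(p)
    if (!is.null(reflect_fun)) nxt <- reflect_fun(nxt)
    pos[i + 1L, ] <- nxt
    prev_state <- st
  }
  list(pos = pos, states = MOTION_STATES[c(states, states[n_steps])])
}

#' Simulate one tracked trajectory with known motion states
#'
#' Generates a single 2-D trajectory under the state-switching motion model
#' and returns both the observed (noisy) trajectory and the ground truth
#' used by validation tests. Identical `params` and `seed` give
#' bit-identical output; the global RNG state is left untouched.
#'
#' @param params A [motion_params()] object.
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer seed; all randomness in the call derives from it.
#' @param id Trajectory identifier stored in the output.
#' @param state_schedule Optional character vector of per-frame motion
#'   states overriding the Markov chain (recycled to `n_frames - 1`
#'   steps); used to build trajectories with known embedded runs.
#' @return A list with elements
#'   \describe{
#'     \item{trajectory}{data.frame `frame` (0-based), `t_s`, `x_um`,
#'       `y_um` -- the noisy observed positions.}
#'     \item{truth}{list with `states` (per-frame labels), `segments`
#'       (data.frame of maximal directed runs: `start_frame`, `end_frame`,
#'       `speed_um_s`), and the noise-free positions `x_true`, `y_true`.}
#'   }
#' @export
simulate_trajectory <- function(params, n_frames, seed, id = "traj1",
                                state_schedule = NULL) {
  stopifnot(inherits(params, "motion_params"))
  if (n_frames < 2L) stop("`n_frames` must be >= 2", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    path <- simulate_path_engine(params, n_frames,
                                 state_schedule = state_schedule)
    noise <- matrix(stats::rnorm(2L * n_frames, 0, params$loc_noise_sigma),
                    ncol = 2L)
    obs <- path$pos + noise
    traj <- data.frame(
      frame = seq_len(n_frames) - 1L,
      t_s = (seq_len(n_frames) - 1L) * params$dt,
      x_um = obs[, 1L],
      y_um = obs[, 2L]
    )
    attr(traj, "traj_id") <- id
    attr(traj, "dt") <- params$dt
    truth <- list(
      states = path$states,
      segments = state_runs(path$states, "directed", params$v_directed),
      x_true = path$pos[, 1L],
      y_true = path$pos[, 2L]
    )
    list(trajectory = traj, truth = truth)
  })
}

# maximal runs of `state` in a per-frame label vector -> 0-based frame spans
state_runs <- function(states, state, speed) {
  r <- rle(states == state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    start_frame = starts[keep] - 1L,
    end_frame = ends[keep] - 1L,
    speed_um_s = if (any(keep)) speed else numeric(0)
  )
}
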