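# Generator properties: seeded determinism, analytic MSD behaviour of each
# motion state, blinking/fusion intensity bookkeeping, and the constructed
# overlap fraction of the two-channel image fixture.

ens_msd <- function(trajs, lags) {
  # brute-force ensemble MSD over all trajectories and ordered pairs
  sapply(lags, function(n) {
    mean(unlist(lapply(trajs, function(tr) {
      N <- nrow(tr)
      j <- seq_len(N - n)
      (tr$x_um[j + n] - tr$x_um[j])^2 + (tr$y_um[j + n] - tr$y_um[j])^2
    })))
  })
}

test_that("identical params and seed reproduce trajectories and scenes exactly", {
  p <- motion_params()
  a <- simulate_trajectory(p, 100, seed = 42)
  b <- simulate_trajectory(p, 100, seed = 42)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- simulate_trajectory(p, 100, seed = 43)
  expect_false(identical(a$trajectory$x_um, c$trajectory$x_um))

  sc <- scene_params(n_trajectories = 5L, n_frames = 80L, seed = 7L)
  s1 <- simulate_cell_scene(sc, p)
  s2 <- simulate_cell_scene(sc, p)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))

  # the calls must not disturb the session RNG
  set.seed(1); x1 <- stats::runif(1)
  set.seed(1); invisible(simulate_trajectory(p, 10, seed = 5)); x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("noise-free directed motion is a straight line at constant speed", {
  p <- pure_state_params("directed", v_directed = 1, heading_jitter = 0,
                         D_directed_overlay = 0, loc_noise_sigma = 0)
  tr <- simulate_trajectory(p, 10, seed = 1)$trajectory
  steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  expect_equal(steps, rep(0.1, 9), tolerance = 1e-12)
  # collinearity: cross products of consecutive steps vanish
  dx <- diff(tr$x_um); dy <- diff(tr$y_um)
  expect_equal(dx[-1] * dy[-9] - dy[-1] * dx[-9], rep(0, 8), tolerance = 1e-12)
})

test_that("free-diffusion ensemble MSD matches 4Dt within 10%", {
  D <- 0.01
  p <- pure_state_params("subdiffusive", alpha_sub = 1, D_free = D,
                         loc_noise_sigma = 0)
  trajs <- lapply(1:500, function(k) {
    simulate_trajectory(p, 200, seed = k)$trajectory
  })
  lags <- 1:10
  msd <- ens_msd(trajs, lags)
  expect_true(all(abs(msd / (4 * D * lags * 0.1) - 1) < 0.1))
})

test_that("sub-diffusive ensemble MSD exponent is within 0.1 of alpha_sub", {
  p <- pure_state_params("subdiffusive", alpha_sub = 0.75, loc_noise_sigma = 0)
  trajs <- lapply(1:500, function(k) {
    simulate_trajectory(p, 200, seed = 1000 + k)$trajectory
  })
  lags <- 1:10
  msd <- ens_msd(trajs, lags)
  fit <- stats::lm(log(msd) ~ log(lags * 0.1))
  expect_equal(unname(stats::coef(fit)[2]), 0.75, tolerance = 0.1 / 0.75)
})

test_that("parameter validation rejects impossible motion models", {
  expect_error(motion_params(dt = 0), "dt")
  expect_error(motion_params(loc_noise_sigma = -1), "loc_noise_sigma")
  expect_error(motion_params(alpha_sub = 1.2), "alpha_sub")
  expect_error(motion_params(switch_rates = matrix(1, 2, 2)), "switch_rates")
  expect_error(simulate_trajectory(motion_params(), 1, seed = 1), "n_frames")
})

test_that("blinking traces have absorbing limits and additive fusion", {
  # off_rate = 0, start ON: constant base intensity
  tr <- blinking_intensity_trace(0.5, 0, base_intensity = 3, n_frames = 50,
                                 seed = 1)
  expect_equal(tr, rep(3, 50))
  # on_rate = 0, start OFF: all zeros
  tr0 <- blinking_intensity_trace(0, 0.5, 1, 50, seed = 2, start_on = FALSE)
  expect_equal(tr0, rep(0, 50))
  # fused aggregate: summed base, never blinks off
  agg <- blinking_intensity_trace(0.2, 0.9, 1, 200, seed = 3, n_fused = 2L)
  expect_equal(agg, rep(2, 200))
})

test_that("fusion conserves total scene base intensity every frame", {
  sc <- scene_params(n_trajectories = 20L, n_frames = 300L, fusion_rate = 0.3,
                     fusion_radius = 1.5, off_rate = 0, seed = 11L)
  s <- simulate_cell_scene(sc, motion_params())
  expect_true(!is.null(s$truth$fusions) && nrow(s$truth$fusions) > 0)
  expect_equal(s$truth$total_base_intensity, rep(20, 300))
  # with no blinking the visible puncta carry the whole intensity
  tot <- tapply(s$recording$puncta$intensity, s$recording$puncta$frame, sum)
  expect_equal(as.numeric(tot), rep(20, 300))
})

test_that("single punctum without blinking or fusion is visible in every frame", {
  sc <- scene_params(n_trajectories = 1L, n_frames = 100L, fusion_rate = 0,
                     off_rate = 0, seed = 3L)
  s <- simulate_cell_scene(sc, motion_params())
  expect_equal(s$truth$n_puncta, rep(1L, 100))
})

test_that("scene positions stay inside the boundary and drift moves them inward", {
  p <- motion_params(v_directed = 0.4)
  sc0 <- scene_params(n_trajectories = 30L, n_frames = 300L,
                      inward_drift_speed = 0, fusion_rate = 0, off_rate = 0,
                      seed = 21L)
  s0 <- simulate_cell_scene(sc0, p)
  r0 <- apply(s0$truth$positions_true, c(1, 3), function(v) sqrt(sum(v^2)))
  bmax <- max(sqrt(rowSums(s0$recording$geometry$boundary^2)))
  expect_true(all(r0 <= bmax + 1e-9))
  # no drift: mean radius stays flat within sampling error
  mr0 <- rowMeans(r0)
  expect_lt(abs(mean(mr0[1:50]) - mean(mr0[251:300])), 0.5)

  # drift-dominated scene: smoothed mean radius strictly decreases
  sc1 <- scene_params(n_trajectories = 50L, n_frames = 300L,
                      inward_drift_speed = 0.05, fusion_rate = 0,
                      off_rate = 0, seed = 22L)
  s1 <- simulate_cell_scene(sc1, motion_params(D_free = 0.005,
                                               v_directed = 0.4))
  r1 <- rowMeans(apply(s1$truth$positions_true, c(1, 3),
                       function(v) sqrt(sum(v^2))))
  sm <- zoo::rollapply(r1, 20, mean, partial = TRUE)
  expect_true(all(diff(sm) < 0))

  # a drift step larger than the cell is rejected
  expect_error(
    simulate_cell_scene(scene_params(inward_drift_speed = 1e4, seed = 1L), p),
    "drift"
  )
})

test_that("rendered image pairs hit the requested red-on-green overlap", {
  # full overlap: every red-positive pixel is on the green support
  full <- render_two_channel_image(overlap_fraction = 1, seed = 1)
  expect_true(all(full$mask[full$red > 0]))
  # zero overlap: supports disjoint
  none <- render_two_channel_image(overlap_fraction = 0, seed = 2)
  expect_equal(sum(none$red[none$mask]), 0)
  # half overlap: pixel-sum oracle within one pixel's worth of intensity
  half <- render_two_channel_image(overlap_fraction = 0.5, seed = 3)
  frac <- sum(half$red[half$mask]) / sum(half$red)
  expect_equal(frac, 0.5, tolerance = 1e-3)
  expect_error(render_two_channel_image(overlap_fraction = 1.5, seed = 1),
               "overlap_fraction")
})
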