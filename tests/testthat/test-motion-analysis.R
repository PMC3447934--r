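# Local MSD machinery: closed-form cases, exact power-law recovery,
# rigid-motion invariances, and ensemble recovery against generator truth.

cfg <- analysis_config()

test_that("local MSD matches the ballistic closed form and flags short windows", {
  tr <- ballistic_traj(60, v = 1)          # step d = 0.1 um/frame
  curve <- local_msd(tr, 30, cfg)
  expect_true(curve$valid)
  expect_equal(curve$msd_um2, (1:10 * 0.1)^2, tolerance = 1e-12)

  # stationary trajectory: all-zero MSD
  st <- make_traj(rep(1, 60), rep(2, 60))
  expect_equal(local_msd(st, 30, cfg)$msd_um2, rep(0, 10))

  # too close to the end: invalid, not an error
  expect_false(local_msd(tr, 1, cfg)$valid)
  expect_true(local_msd(tr, 2, cfg)$valid)  # truncated but 11 points
})

test_that("fit_alpha recovers exact power laws to machine precision", {
  lags <- (1:10) * 0.1
  for (a in c(0.5, 1.0, 1.5, 2.0)) {
    curve <- structure(list(lag_s = lags, msd_um2 = 0.03 * lags^a,
                            n_pairs = rep(10L, 10), valid = TRUE),
                       class = "msd_curve")
    fit <- fit_alpha(curve)
    expect_equal(fit$alpha, a, tolerance = 1e-9)
    expect_equal(fit$prefactor, 0.03, tolerance = 1e-9)
  }
  # fewer than 3 positive points: invalid flag
  degenerate <- structure(list(lag_s = lags, msd_um2 = c(1, 2, rep(0, 8)),
                               n_pairs = rep(10L, 10), valid = TRUE),
                          class = "msd_curve")
  expect_false(fit_alpha(degenerate)$valid)
})

test_that("fit_diffusion_constant reads the initial slope with free intercept", {
  lags <- (1:10) * 0.1
  exact <- structure(list(lag_s = lags, msd_um2 = 4 * 0.02 * lags,
                          n_pairs = rep(10L, 10), valid = TRUE),
                     class = "msd_curve")
  expect_equal(fit_diffusion_constant(exact, cfg)$D, 0.02, tolerance = 1e-12)

  # a constant offset (static localization noise) must not bias D
  offset <- exact; offset$msd_um2 <- offset$msd_um2 + 0.0016
  expect_equal(fit_diffusion_constant(offset, cfg)$D, 0.02, tolerance = 1e-12)

  zero <- exact; zero$msd_um2 <- rep(0, 10)
  fz <- fit_diffusion_constant(zero, cfg)
  expect_equal(fz$D, 0)
  # negative slope clamps to zero with a flag
  neg <- exact; neg$msd_um2 <- rev(exact$msd_um2)
  fn <- fit_diffusion_constant(neg, cfg)
  expect_equal(fn$D, 0)
  expect_true(fn$clamped)
})

test_that("persistence is 1 on lines, -1 on reversals, ~0 for isotropic walks", {
  line <- ballistic_traj(40, v = 0.5, theta = 0.7)
  expect_equal(local_persistence(line, 20, cfg)$phi, 1.0, tolerance = 1e-12)

  zig <- make_traj(rep(c(0, 1), 20), rep(0, 40))
  expect_equal(local_persistence(zig, 20, cfg)$phi, -1.0, tolerance = 1e-12)

  # ensemble mean of phi over isotropic random walks is 0 +- 0.05
  phis <- vapply(1:500, function(k) {
    withr::with_seed(3000 + k, {
      tr <- make_traj(cumsum(stats::rnorm(21)), cumsum(stats::rnorm(21)))
    })
    local_persistence(tr, 11, cfg)$phi
  }, numeric(1))
  expect_lt(abs(mean(phis)), 0.05)

  # all steps zero-length: invalid
  st <- make_traj(rep(0, 40), rep(0, 40))
  expect_false(local_persistence(st, 20, cfg)$valid)
})

test_that("alpha and phi are invariant under rigid motion; phi under time reversal", {
  p <- motion_params(loc_noise_sigma = 0)
  tr <- simulate_trajectory(p, 80, seed = 9)$trajectory
  prof <- profile_trajectory(tr, cfg)

  th <- 0.83; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- cbind(tr$x_um, tr$y_um) %*% Rm
  moved <- make_traj(xy[, 1] + 5.2, xy[, 2] - 3.1)
  prof2 <- profile_trajectory(moved, cfg)
  expect_equal(prof2$alpha, prof$alpha, tolerance = 1e-9)
  expect_equal(prof2$phi, prof$phi, tolerance = 1e-9)

  # time reversal: with a window spanning the whole trajectory the set of
  # turning angles is identical, so phi is exactly invariant
  rev_tr <- make_traj(rev(tr$x_um), rev(tr$y_um))
  wide <- analysis_config(window_frames = 2L * nrow(tr))
  expect_equal(local_persistence(rev_tr, 40, wide)$phi,
               local_persistence(tr, 40, wide)$phi, tolerance = 1e-12)
})

test_that("profile flags directed points on ballistic but not confined motion", {
  ball <- ballistic_traj(80, v = 0.8)
  pb <- profile_trajectory(ball, cfg)
  expect_true(all(pb$directed[pb$valid]))
  expect_false(pb$valid[1])  # first point's window is one point short

  conf <- simulate_trajectory(
    pure_state_params("constrained", loc_noise_sigma = 0), 200, seed = 12
  )$trajectory
  pc <- profile_trajectory(conf, cfg)
  expect_equal(sum(pc$directed[pc$valid]), 0L)
  expect_lt(mean(pc$alpha[pc$valid]), 0.4)
})

test_that("ensemble exponent recovery brackets each motion class", {
  classes <- list(
    list(p = pure_state_params("subdiffusive", alpha_sub = 1,
                               loc_noise_sigma = 0), lo = 0.9, hi = 1.1),
    list(p = pure_state_params("directed", v_directed = 0.8,
                               heading_jitter = 0, D_directed_overlay = 0,
                               loc_noise_sigma = 0), lo = 1.9, hi = 2.05),
    list(p = pure_state_params("subdiffusive", alpha_sub = 0.75,
                               loc_noise_sigma = 0), lo = 0.65, hi = 0.85)
  )
  lags <- 1:10
  for (cl in classes) {
    trajs <- lapply(1:200, function(k) {
      simulate_trajectory(cl$p, 200, seed = 5000 + k)$trajectory
    })
    msd <- sapply(lags, function(n) {
      mean(unlist(lapply(trajs, function(tr) {
        j <- seq_len(nrow(tr) - n)
        (tr$x_um[j + n] - tr$x_um[j])^2 + (tr$y_um[j + n] - tr$y_um[j])^2
      })))
    })
    a <- unname(stats::coef(stats::lm(log(msd) ~ log(lags * 0.1)))[2])
    expect_gt(a, cl$lo)
    expect_lt(a, cl$hi)
  }
})
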