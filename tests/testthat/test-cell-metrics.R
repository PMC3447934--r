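# Endocytic ratio and intensity aggregation.

cfg <- analysis_config()

test_that("endocytic ratio is 1 on the boundary and b/a inside", {
  g <- square_geometry(10)
  # points on the boundary: R = 1 exactly
  on_b <- rbind(c(10, 5), c(5, 10), c(0, 5), c(5, 0))
  expect_equal(endocytic_ratio_frame(on_b, g)$R, 1.0, tolerance = 1e-9)

  # circle of radius 10, one point at half radius: R = 2
  circ <- cell_geometry(make_cell_boundary(10, n_vertices = 4096L), c(0, 0))
  r <- endocytic_ratio_frame(cbind(5, 0), circ)
  expect_equal(r$R, 2.0, tolerance = 1e-4)

  # a point exactly at the center (a = 0) is excluded; alone it leaves
  # the frame without usable points
  at_center <- endocytic_ratio_frame(matrix(g$center, 1, 2), g)
  expect_false(at_center$valid)
  expect_true(is.na(at_center$R))
})

test_that("frame ratio equals the dense-ray oracle on random polygons", {
  for (seed in 1:50) {
    poly <- random_polygon(seed)
    g <- cell_geometry(poly, c(0, 0))
    withr::with_seed(400 + seed, {
      theta <- stats::runif(4, 0, 2 * pi)
      rr <- stats::runif(4, 0.2, 0.9)
    })
    b_true <- vapply(theta, function(th) {
      oracle_ray_distance(c(0, 0), c(cos(th), sin(th)), poly)
    }, numeric(1))
    pts <- cbind(rr * b_true * cos(theta), rr * b_true * sin(theta))
    got <- endocytic_ratio_frame(pts, g)$R
    expect_equal(got, mean(b_true / (rr * b_true)), tolerance = 1e-6)
  }
})

test_that("ratio is invariant under rigid motion and uniform scaling", {
  poly <- random_polygon(3)
  g <- cell_geometry(poly, c(0, 0))
  withr::with_seed(77, {
    pts <- matrix(stats::rnorm(40, 0, 1.5), ncol = 2)
  })
  keep <- point_in_polygon(pts[, 1], pts[, 2], poly)
  pts <- pts[keep, , drop = FALSE]
  R0 <- endocytic_ratio_frame(pts, g)$R

  th <- 0.4; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  s <- 3.7; shift <- c(11, -4)
  poly2 <- sweep(s * poly %*% Rm, 2, shift, `+`)
  pts2 <- sweep(s * pts %*% Rm, 2, shift, `+`)
  g2 <- cell_geometry(poly2, shift)
  expect_equal(endocytic_ratio_frame(pts2, g2)$R, R0, tolerance = 1e-9)
})

test_that("moving a point toward the center of a convex cell raises R", {
  circ <- cell_geometry(make_cell_boundary(8, n_vertices = 256L), c(0, 0))
  radii <- c(6, 4, 2, 1, 0.5)
  Rs <- vapply(radii, function(r) {
    endocytic_ratio_frame(cbind(r, 0), circ)$R
  }, numeric(1))
  expect_true(all(diff(Rs) > 0))
})

test_that("ratio series smooths, keeps gaps, and rises under inward drift", {
  g <- square_geometry(10)
  # static points: constant series
  tr <- data.frame(cell_id = "c", traj_id = "a", frame = 0:59,
                   x_um = 7, y_um = 5)
  rec <- cell_recording("c", geometry = g, trajectories = tr)
  rs <- endocytic_ratio_series(rec, cfg)
  expect_equal(unique(rs$R_raw), rs$R_raw[1])
  expect_equal(rs$R_smooth, rs$R_raw)

  # boundary points throughout: constantly 1
  trb <- data.frame(cell_id = "c", traj_id = "a", frame = 0:59,
                    x_um = 10, y_um = 5)
  rsb <- endocytic_ratio_series(
    cell_recording("c", geometry = g, trajectories = trb), cfg
  )
  expect_equal(rsb$R_raw, rep(1, 60), tolerance = 1e-9)

  # drift-dominated scene: smoothed R strictly increases
  sc <- scene_params(n_trajectories = 50L, n_frames = 300L,
                     inward_drift_speed = 0.05, fusion_rate = 0,
                     off_rate = 0, seed = 31L)
  sim <- simulate_cell_scene(sc, motion_params(D_free = 0.005,
                                               v_directed = 0.4))
  rs2 <- endocytic_ratio_series(sim$recording, cfg)
  # the smoothed series rises clearly and near-monotonically; strict
  # frame-by-frame increase of the estimated ratio is seed-dependent
  # because the per-frame drift signal is small against ensemble noise
  expect_gt(rs2$R_smooth[nrow(rs2)], rs2$R_smooth[1])
  expect_gt(mean(diff(rs2$R_smooth) > 0), 0.9)
  expect_gt(min(rs2$R_raw), 1)
})

test_that("intensity series normalizes to the first frame and tracks fusion", {
  # constant puncta: flat at 1
  pk <- data.frame(frame = rep(0:9, each = 3), intensity = 2)
  s <- normalized_intensity_series(pk)
  expect_equal(s$normalized, rep(1, 10))

  # every punctum doubles at frame 5: series steps 1 -> 2
  pk2 <- data.frame(frame = rep(0:9, each = 2),
                    intensity = rep(c(1, 2), c(10, 10)))
  s2 <- normalized_intensity_series(pk2)
  expect_equal(s2$normalized, rep(c(1, 2), each = 5))

  # fusion without blinking: final mean = (n0 / n_final) * initial mean
  sc <- scene_params(n_trajectories = 20L, n_frames = 400L,
                     fusion_rate = 0.5, fusion_radius = 2, off_rate = 0,
                     seed = 13L)
  sim <- simulate_cell_scene(sc, motion_params())
  s3 <- normalized_intensity_series(sim$recording$puncta)
  n_first <- sim$truth$n_puncta[1]   # fusions may fire already in frame 0
  n_final <- sim$truth$n_puncta[400]
  expect_lt(n_final, n_first)
  # total intensity is conserved, so mean-per-punctum scales as 1/count
  expect_equal(s3$normalized[400], n_first / n_final, tolerance = 1e-9)
  expect_true(all(diff(s3$normalized) >= -1e-9))
})
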