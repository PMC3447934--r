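# Directed segments, mode labels and the two-step population statistics.

cfg <- analysis_config()

test_that("instantaneous velocity is exact on linear motion and NA at ends", {
  tr <- ballistic_traj(30, v = 0.5, theta = 1.1)
  for (h in 1:3) {
    c2 <- analysis_config(velocity_halfwidth = h)
    expect_equal(instantaneous_velocity(tr, 15, c2), 0.5, tolerance = 1e-12)
  }
  expect_true(is.na(instantaneous_velocity(tr, 1, cfg)))
  expect_true(is.na(instantaneous_velocity(tr, 30, cfg)))
  st <- make_traj(rep(1, 30), rep(1, 30))
  expect_equal(instantaneous_velocity(st, 15, cfg), 0)
})

fake_profile <- function(tr, directed_idx) {
  n <- nrow(tr)
  prof <- data.frame(
    frame = tr$frame, t_s = tr$t_s,
    alpha = rep(2, n), D_um2_s = 0.01, phi = rep(1, n),
    speed_um_s = instantaneous_velocity_vec(tr),
    directed = seq_len(n) %in% directed_idx,
    valid = TRUE
  )
  attr(prof, "traj_id") <- attr(tr, "traj_id", exact = TRUE)
  class(prof) <- c("motion_profile", "data.frame")
  prof
}

instantaneous_velocity_vec <- function(tr, cfg = analysis_config()) {
  vapply(seq_len(nrow(tr)), function(i) instantaneous_velocity(tr, i, cfg),
         numeric(1))
}

test_that("segment rule: >= 5 directed frames AND the 267 nm / 0.5 s displacement", {
  # 4 consecutive directed frames: below the frame minimum, no segment
  tr <- ballistic_traj(40, v = 1)
  seg4 <- extract_directed_segments(fake_profile(tr, 10:13), tr, cfg)
  expect_equal(nrow(seg4$segments), 0L)

  # 20-frame noise-free run at 1 um/s: one segment, mean velocity 1
  seg20 <- extract_directed_segments(fake_profile(tr, 11:30), tr, cfg)
  expect_equal(nrow(seg20$segments), 1L)
  expect_equal(seg20$segments$n_frames, 20L)
  expect_equal(seg20$segments$mean_velocity_um_s, 1.0, tolerance = 1e-9)
  expect_equal(seg20$segments$run_length_um, 19 * 0.1, tolerance = 1e-9)

  # directed-flagged crawl at 0.2 um/s: 0.1 um per 0.5 s < 0.267, rejected
  slow <- ballistic_traj(40, v = 0.2)
  segslow <- extract_directed_segments(fake_profile(slow, 11:30), slow, cfg)
  expect_equal(nrow(segslow$segments), 0L)

  # a stalled stretch inside an otherwise fast run fails the rolling check
  xs <- c(seq(0, 1.0, by = 0.1), rep(1.0, 10), seq(1.1, 2, by = 0.1))
  stall <- make_traj(xs, rep(0, length(xs)))
  segst <- extract_directed_segments(
    fake_profile(stall, seq_along(xs)), stall, cfg
  )
  expect_equal(nrow(segst$segments), 0L)
})

test_that("reported segments always satisfy the rule over random simulations", {
  p <- motion_params()
  viol <- 0L
  for (k in 1:30) {
    tr <- simulate_trajectory(p, 150, seed = 7000 + k)$trajectory
    prof <- profile_trajectory(tr, cfg)
    segs <- extract_directed_segments(prof, tr, cfg)$segments
    if (!nrow(segs)) next
    for (s in seq_len(nrow(segs))) {
      i0 <- match(segs$start_frame[s], tr$frame)
      i1 <- match(segs$end_frame[s], tr$frame)
      if (i1 - i0 + 1L < 5L) viol <- viol + 1L
      w <- min(5L, i1 - i0)
      req <- 0.267 * (w * 0.1 / 0.5)
      j <- i0:(i1 - w)
      disp <- sqrt((tr$x_um[j + w] - tr$x_um[j])^2 +
                   (tr$y_um[j + w] - tr$y_um[j])^2)
      if (any(disp <= req)) viol <- viol + 1L
    }
  }
  expect_equal(viol, 0L)
})

test_that("mode classification uses half-open alpha intervals", {
  mk_prof <- function(alpha) {
    prof <- data.frame(frame = 0:59, t_s = (0:59) * 0.1, alpha = alpha,
                       D_um2_s = 0.01, phi = 0, speed_um_s = NA_real_,
                       directed = FALSE, valid = TRUE)
    attr(prof, "traj_id") <- "t1"
    class(prof) <- c("motion_profile", "data.frame")
    prof
  }
  expect_equal(classify_mode(mk_prof(0.2), cfg)$mode, "constrained")
  expect_equal(classify_mode(mk_prof(0.73), cfg)$mode, "subdiffusive")
  expect_equal(classify_mode(mk_prof(2.0), cfg)$mode, "superdiffusive")
  # boundary values fall in the upper interval
  expect_equal(classify_mode(mk_prof(0.4), cfg)$mode, "subdiffusive")
  expect_equal(classify_mode(mk_prof(1.0), cfg)$mode, "superdiffusive")
  # no valid points: unclassified
  empty <- mk_prof(0.5); empty$valid <- FALSE
  expect_equal(classify_mode(empty, cfg)$mode, "unclassified")
})

test_that("two-step averaging weights cells, not points", {
  pts <- data.frame(
    cell_id = c("A", "A", "A", "B"),
    t_s = c(10, 20, 30, 15),
    speed_um_s = c(1, 1, 1, 2)
  )
  out <- binned_velocity_stats(pts, cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$mean_velocity_um_s, 1.5)  # NOT the pooled mean 1.25
  expect_equal(out$n_cells, 2L)

  # single cell, constant speeds
  one <- binned_velocity_stats(
    data.frame(cell_id = "A", t_s = c(1, 2), speed_um_s = 0.7), cfg
  )
  expect_equal(one$mean_velocity_um_s, 0.7)
  expect_equal(one$se_velocity_um_s, 0)

  # equals the brute-force mean-over-cells of per-cell means
  withr::with_seed(99, {
    pts2 <- data.frame(
      cell_id = sample(LETTERS[1:5], 200, TRUE),
      t_s = stats::runif(200, 0, 299),
      speed_um_s = stats::runif(200, 0.2, 1.5)
    )
  })
  out2 <- binned_velocity_stats(pts2, cfg)
  brute <- mean(tapply(pts2$speed_um_s, pts2$cell_id, mean))
  expect_equal(out2$mean_velocity_um_s, brute, tolerance = 1e-12)
})

test_that("mode proportions sum to one and respect bin assignment by midpoint", {
  labels <- data.frame(
    cell_id = rep(c("A", "B"), each = 6),
    traj_id = paste0("t", 1:12),
    mode = rep(c("superdiffusive"), 12),
    t_mid_s = rep(c(100, 1000), 6)
  )
  out <- mode_proportions(labels, cfg)
  sup <- out[out$mode == "superdiffusive", ]
  expect_equal(sup$proportion, c(1, 1))
  expect_equal(sort(unique(out$bin_start_s)), c(0, 900))
  # within each bin the three mode proportions sum to 1
  for (b in unique(out$bin_start_s)) {
    s <- out[out$bin_start_s == b & out$mode != "unclassified", ]
    expect_equal(sum(s$proportion), 1)
  }

  mixed <- data.frame(
    cell_id = "A", traj_id = paste0("t", 1:4),
    mode = c("constrained", "subdiffusive", "subdiffusive", "unclassified"),
    t_mid_s = 10
  )
  m <- mode_proportions(mixed, cfg)
  expect_equal(m$proportion[m$mode == "constrained"], 1 / 3)
  expect_equal(m$proportion[m$mode == "subdiffusive"], 2 / 3)
  expect_equal(m$proportion[m$mode == "unclassified"], 1 / 4)
})

test_that("velocity versus run length buckets segments left-closed right-open", {
  segs <- data.frame(
    run_length_um = c(0.3, 1.2),
    mean_velocity_um_s = c(0.5, 0.9)
  )
  out <- velocity_vs_runlength(segs, c(0, 0.5, 1.5))
  expect_equal(nrow(out), 2L)
  expect_equal(out$n_segments, c(1L, 1L))
  expect_equal(out$mean_velocity_um_s, c(0.5, 0.9))

  # identical segments all land in one bucket with their common velocity
  same <- data.frame(run_length_um = rep(0.7, 5),
                     mean_velocity_um_s = rep(1.1, 5))
  o2 <- velocity_vs_runlength(same, c(0, 0.5, 1.5))
  expect_equal(o2$mean_velocity_um_s, 1.1)
  expect_equal(o2$n_segments, 5L)

  # beyond the last edge: overflow bucket
  over <- data.frame(run_length_um = 9, mean_velocity_um_s = 2)
  o3 <- velocity_vs_runlength(over, c(0, 0.5, 1.5))
  expect_true(is.infinite(o3$bin_hi_um))
  expect_error(velocity_vs_runlength(same[0, ], c(0, 1)), "no segments")
})
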