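# Reproducible validation studies: each function simulates a ground-truth
# scenario with the synthetic-data generator, runs the analysis pipeline on
# it, and reports how well the known truth is recovered. These studies
# define the package's quantitative self-checks; the acceptance script and
# test suite both call them.

#' Anomalous-exponent recovery study
#'
#' Simulates three pure-motion ensembles (free Brownian diffusion with
#' 20 nm localization noise, noise-free ballistic transport, and
#' noise-free sub-diffusion with generator exponent 0.75) and reports the
#' mean fitted local exponent of each, where a trajectory's exponent is
#' the mean of its valid per-point local alpha values.
#'
#' Note that for Brownian motion observed with localization noise the
#' measured MSD is `4 D t + 4 sigma^2`; the additive noise floor flattens
#' the log-log curve at short lags, so the recovered exponent sits well
#' below 1 even though the underlying motion is ideal diffusion. This is
#' a property of the published fitting procedure, not an estimator defect;
#' see the methods vignette.
#'
#' @param seed Integer seed.
#' @param n_traj Trajectories per ensemble.
#' @param n_frames Frames per trajectory.
#' @param cfg An [analysis_config()].
#' @return List `brownian_alpha`, `ballistic_alpha`, `sub_alpha`, `n`.
#' @export
study_exponent_recovery <- function(seed, n_traj = 200L, n_frames = 200L,
                                    cfg = analysis_config()) {
  mean_alpha <- function(params, off) {
    vals <- vapply(seq_len(n_traj), function(k) {
      tr <- simulate_trajectory(params, n_frames,
                                seed = derive_seed(seed, off + k))$trajectory
      prof <- profile_trajectory(tr, cfg)
      mean(prof$alpha[prof$valid])
    }, numeric(1))
    mean(vals)
  }
  list(
    brownian_alpha = mean_alpha(
      pure_state_params("subdiffusive", alpha_sub = 1, D_free = 0.01,
                        loc_noise_sigma = 0.02), 0L),
    ballistic_alpha = mean_alpha(
      pure_state_params("directed", v_directed = 0.8, heading_jitter = 0,
                        D_directed_overlay = 0, loc_noise_sigma = 0), 1000L),
    sub_alpha = mean_alpha(
      pure_state_params("subdiffusive", alpha_sub = 0.75,
                        loc_noise_sigma = 0), 2000L),
    n = n_traj
  )
}

#' Diffusion-constant recovery study
#'
#' Simulates free diffusion at `D = 0.01` um^2/s and reports the relative
#' error of the median fitted per-point diffusion constant, noise-free and
#' at 30 nm localization noise (the worst case of the instrument's 10--30
#' nm precision range). The free intercept of the D fit absorbs the static
#' noise offset, so both should recover the truth closely.
#'
#' @inheritParams study_exponent_recovery
#' @return List `rel_err_noise_free`, `rel_err_noisy`, `D_true`, `n`.
#' @export
study_diffusion_recovery <- function(seed, n_traj = 200L, n_frames = 200L,
                                     cfg = analysis_config()) {
  D_true <- 0.01
  median_D <- function(sigma, off) {
    d <- unlist(lapply(seq_len(n_traj), function(k) {
      tr <- simulate_trajectory(
        pure_state_params("subdiffusive", alpha_sub = 1, D_free = D_true,
                          loc_noise_sigma = sigma),
        n_frames, seed = derive_seed(seed, off + k)
      )$trajectory
      prof <- profile_trajectory(tr, cfg)
      prof$D_um2_s[prof$valid]
    }))
    stats::median(d)
  }
  list(
    rel_err_noise_free = abs(median_D(0, 3000L) / D_true - 1),
    rel_err_noisy = abs(median_D(0.03, 4000L) / D_true - 1),
    D_true = D_true,
    n = n_traj
  )
}

#' Directed-segment recovery study
#'
#' Embeds one 30-frame directed run at 0.8 um/s inside a sub-diffusive
#' background (45 frames on each side) in every trajectory, then measures
#' how the segment extractor recovers the known runs: recall (fraction of
#' true runs overlapped by a reported segment), the relative error of the
#' mean reported segment velocity, and the number of reported segments
#' violating the 5-frame / 267 nm-per-0.5-s rule (checked independently
#' of the extractor).
#'
#' @param seed Integer seed.
#' @param n_traj Number of trajectories.
#' @param cfg An [analysis_config()].
#' @return List `recall`, `velocity_rel_err`, `n_violations`,
#'   `v_true`, `n`.
#' @export
study_segment_recovery <- function(seed, n_traj = 100L,
                                   cfg = analysis_config()) {
  v_true <- 0.8
  params <- motion_params(v_directed = v_true, alpha_sub = 0.75)
  schedule <- c(rep("subdiffusive", 45), rep("directed", 30),
                rep("subdiffusive", 44))
  hits <- 0L
  viol <- 0L
  seg_vels <- numeric(0)
  for (k in seq_len(n_traj)) {
    sim <- simulate_trajectory(params, 120L, seed = derive_seed(seed, 5000L + k),
                               state_schedule = schedule)
    tr <- sim$trajectory
    prof <- profile_trajectory(tr, cfg)
    segs <- extract_directed_segments(prof, tr, cfg)$segments
    true_seg <- sim$truth$segments
    if (nrow(segs)) {
      overlap <- segs$end_frame >= true_seg$start_frame[1] &
        segs$start_frame <= true_seg$end_frame[1]
      if (any(overlap)) {
        hits <- hits + 1L
        seg_vels <- c(seg_vels, segs$mean_velocity_um_s[overlap])
      }
      # independent re-check of the reported segments
      for (s in seq_len(nrow(segs))) {
        i0 <- match(segs$start_frame[s], tr$frame)
        i1 <- match(segs$end_frame[s], tr$frame)
        if (i1 - i0 + 1L < cfg$min_directed_frames) viol <- viol + 1L
        w <- min(round(cfg$displacement_window_s / 0.1), i1 - i0)
        req <- cfg$min_displacement_um * (w * 0.1 / cfg$displacement_window_s)
        j <- i0:(i1 - w)
        disp <- sqrt((tr$x_um[j + w] - tr$x_um[j])^2 +
                     (tr$y_um[j + w] - tr$y_um[j])^2)
        if (any(disp <= req)) viol <- viol + 1L
      }
    }
  }
  list(
    recall = hits / n_traj,
    velocity_rel_err = abs(mean(seg_vels) / v_true - 1),
    n_violations = viol,
    v_true = v_true,
    n = n_traj
  )
}

#' Two-condition directed-velocity contrast study
#'
#' Simulates a control condition (true directed speed 1.0 um/s) and a
#' treated condition (0.7 um/s), several cells each, with the default
#' state-switching motion model; runs the full per-cell analysis and the
#' two-step binned velocity statistics, and reports the treated/control
#' ratio of the recovered mean directed velocities.
#'
#' @param seed Integer seed.
#' @param n_cells Cells per condition.
#' @param n_traj Trajectories per cell.
#' @param n_frames Frames per trajectory.
#' @param cfg An [analysis_config()].
#' @return List `ratio`, `v_control`, `v_treated`, `true_ratio`, `n`.
#' @export
study_condition_contrast <- function(seed, n_cells = 6L, n_traj = 15L,
                                     n_frames = 300L,
                                     cfg = analysis_config()) {
  speeds <- c(control = 1.0, treated = 0.7)
  cond_mean <- function(cond, off) {
    pts <- list()
    for (c_i in seq_len(n_cells)) {
      cell_id <- sprintf("%s_%02d", cond, c_i)
      for (k in seq_len(n_traj)) {
        sim <- simulate_trajectory(
          motion_params(v_directed = speeds[[cond]]), n_frames,
          seed = derive_seed(seed, off + 100L * c_i + k)
        )
        tr <- sim$trajectory
        prof <- profile_trajectory(tr, cfg)
        p <- extract_directed_segments(prof, tr, cfg)$points
        if (nrow(p)) {
          p$cell_id <- cell_id
          pts[[length(pts) + 1L]] <- p
        }
      }
    }
    pts <- do.call(rbind, pts)
    binned_velocity_stats(pts, cfg)$mean_velocity_um_s[1L]
  }
  v_ctrl <- cond_mean("control", 10000L)
  v_trt <- cond_mean("treated", 20000L)
  list(ratio = v_trt / v_ctrl, v_control = v_ctrl, v_treated = v_trt,
       true_ratio = 0.7, n = n_cells)
}

#' Motion-mode classification study
#'
#' Draws 300-frame trajectories purely from each generator class in a
#' 50/30/20 constrained / sub-diffusive / directed mix, classifies each
#' trajectory from its mean local exponent, and reports the per-class
#' accuracy and the recovered mix proportions.
#'
#' @param seed Integer seed.
#' @param n_traj Total number of trajectories (split 50/30/20).
#' @param cfg An [analysis_config()].
#' @return List `accuracy` (named, per class), `min_accuracy`,
#'   `proportions` (recovered), `max_proportion_err`, `n`.
#' @export
study_mode_classification <- function(seed, n_traj = 100L,
                                      cfg = analysis_config()) {
  mix <- c(constrained = 0.5, subdiffusive = 0.3, directed = 0.2)
  expected_mode <- c(constrained = "constrained",
                     subdiffusive = "subdiffusive",
                     directed = "superdiffusive")
  counts <- round(mix * n_traj)
  labels <- list()
  correct <- stats::setNames(numeric(3), names(mix))
  total <- stats::setNames(numeric(3), names(mix))
  k <- 0L
  for (cls in names(mix)) {
    for (i in seq_len(counts[[cls]])) {
      k <- k + 1L
      tr <- simulate_trajectory(pure_state_params(cls), 300L,
                                seed = derive_seed(seed, 30000L + k),
                                id = sprintf("t%03d", k))$trajectory
      prof <- profile_trajectory(tr, cfg)
      attr(prof, "traj_id") <- sprintf("t%03d", k)
      lab <- classify_mode(prof, cfg)
      lab$cell_id <- "cellA"
      labels[[k]] <- lab
      total[cls] <- total[cls] + 1
      if (lab$mode == expected_mode[[cls]]) correct[cls] <- correct[cls] + 1
    }
  }
  labels <- do.call(rbind, labels)
  props <- mode_proportions(labels, cfg)
  rec <- stats::setNames(
    props$proportion[match(expected_mode, props$mode)], names(mix)
  )
  acc <- correct / total
  list(
    accuracy = acc,
    min_accuracy = min(acc),
    proportions = rec,
    max_proportion_err = max(abs(rec - mix)),
    n = n_traj
  )
}

#' Endocytic-ratio validation study
#'
#' Checks the closed-form anchor cases (boundary puncta give R = 1, a
#' punctum at half radius of a circular cell gives R = 2) and runs a
#' drift-dominated inward-transport scene to report the fraction of
#' strictly increasing steps in the smoothed endocytic-ratio series.
#'
#' @param seed Integer seed.
#' @param cfg An [analysis_config()].
#' @return List `boundary_R`, `half_radius_R`, `monotone_fraction`, `n`.
#' @export
study_endocytic_ratio <- function(seed, cfg = analysis_config()) {
  sq <- cell_geometry(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)), c(5, 5))
  boundary_R <- endocytic_ratio_frame(
    rbind(c(10, 5), c(5, 10), c(0, 5), c(5, 0)), sq
  )$R
  circ <- cell_geometry(make_cell_boundary(10, n_vertices = 4096L), c(0, 0))
  half_R <- endocytic_ratio_frame(cbind(5, 0), circ)$R

  sc <- scene_params(n_trajectories = 50L, n_frames = 300L,
                     inward_drift_speed = 0.05, fusion_rate = 0,
                     off_rate = 0, seed = derive_seed(seed, 40000L))
  sim <- simulate_cell_scene(sc, motion_params(D_free = 0.005,
                                               v_directed = 0.4))
  rs <- endocytic_ratio_series(sim$recording, cfg)
  list(
    boundary_R = boundary_R,
    half_radius_R = half_R,
    monotone_fraction = mean(diff(rs$R_smooth) > 0),
    n = nrow(rs)
  )
}

#' Colocalization validation study
#'
#' Renders synthetic image groups at constructed red-on-green overlap
#' fractions 0.2 and 0.8 (three images each) and reports the recovered
#' group mean M1 values under a fixed mid-range threshold.
#'
#' @param seed Integer seed.
#' @param n_images Images per group.
#' @return List `m1_low`, `m1_high`, `targets`, `n`.
#' @export
study_colocalization <- function(seed, n_images = 3L) {
  groups <- list()
  k <- 0L
  for (f in c(0.2, 0.8)) {
    for (i in seq_len(n_images)) {
      k <- k + 1L
      img <- render_two_channel_image(
        overlap_fraction = f, seed = derive_seed(seed, 50000L + k)
      )
      groups[[k]] <- data.frame(condition = sprintf("f%.1f", f),
                                timepoint_min = 15)
      groups[[k]]$images <- list(list(red = img$red, green = img$green))
    }
  }
  pairs <- do.call(rbind, groups)
  out <- coloc_timecourse(pairs, threshold = 100)
  list(
    m1_low = out$mean_m1[out$condition == "f0.2"],
    m1_high = out$mean_m1[out$condition == "f0.8"],
    targets = c(0.2, 0.8),
    n = n_images
  )
}

#' End-to-end determinism study
#'
#' Runs the simulate + analyze pipeline twice with the same configuration
#' and seed into separate directories and reports whether every output
#' file is byte-identical.
#'
#' @param seed Integer seed.
#' @return List `identical` (logical), `n_files`.
#' @export
study_determinism <- function(seed) {
  cfg <- run_config(
    motion = list(control = motion_params()),
    scene = list(control = scene_params(n_trajectories = 8L,
                                        n_frames = 150L)),
    n_cells = 2L,
    seed = derive_seed(seed, 60000L)
  )
  d1 <- tempfile("det1_"); d2 <- tempfile("det2_")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  suppressMessages({
    run_simulate(cfg, file.path(d1, "sim"))
    run_analyze(cfg, file.path(d1, "sim"), file.path(d1, "out"))
    run_simulate(cfg, file.path(d2, "sim"))
    run_analyze(cfg, file.path(d2, "sim"), file.path(d2, "out"))
  })
  same <- TRUE
  n_files <- 0L
  for (sub in c("sim", "out")) {
    f1 <- sort(list.files(file.path(d1, sub)))
    f2 <- sort(list.files(file.path(d2, sub)))
    if (!identical(f1, f2)) same <- FALSE
    for (f in intersect(f1, f2)) {
      n_files <- n_files + 1L
      if (!identical(readLines(file.path(d1, sub, f), warn = FALSE),
                     readLines(file.path(d2, sub, f), warn = FALSE))) {
        same <- FALSE
      }
    }
  }
  list(identical = same, n_files = n_files)
}
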