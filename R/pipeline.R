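# Reproducible end-to-end runs: simulate scenes to disk, analyze
# recordings into per-cell tables, and summarize colocalization groups.
# Every output embeds the configuration hash and seed so a run can be
# audited and reproduced exactly.

#' Run configuration
#'
#' Bundles the analysis parameters with simulation settings, condition
#' labels and the master seed of a pipeline run.
#'
#' @param analysis An [analysis_config()].
#' @param motion Named list of [motion_params()] per condition label.
#' @param scene Named list of [scene_params()] per condition label (same
#'   names as `motion`).
#' @param n_cells Cells simulated per condition.
#' @param seed Master integer seed; per-cell seeds are derived from it.
#' @return List of class `run_config` with a stable `hash`.
#' @export
run_config <- function(analysis = analysis_config(),
                       motion = list(control = motion_params()),
                       scene = list(control = scene_params()),
                       n_cells = 3L,
                       seed = 1L) {
  if (!identical(sort(names(motion)), sort(names(scene)))) {
    stop("`motion` and `scene` must share condition names", call. = FALSE)
  }
  cfg <- list(analysis = analysis, motion = motion, scene = scene,
              n_cells = as.integer(n_cells), seed = as.integer(seed))
  cfg$hash <- rlang::hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

# derived per-cell seed, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

csv_header <- function(config) {
  sprintf("qdtrack config_hash=%s seed=%d", config$hash, config$seed)
}

write_table_with_header <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", csv_header(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Simulate condition scenes to disk
#'
#' Generates `n_cells` cell scenes per condition and writes, per cell, the
#' trajectory CSV, the puncta CSV, the geometry JSON and a ground-truth
#' JSON sidecar, plus a run manifest. Deterministic per config + seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config$hash, seed = config$seed,
                   conditions = list())
  k <- 0L
  for (cond in names(config$motion)) {
    cells <- character(0)
    for (c_i in seq_len(config$n_cells)) {
      k <- k + 1L
      sc <- config$scene[[cond]]
      sc$seed <- derive_seed(config$seed, k)
      cell_id <- sprintf("%s_cell%02d", cond, c_i)
      sim <- simulate_cell_scene(sc, config$motion[[cond]], cell_id = cell_id)
      base <- file.path(out_dir, cell_id)
      write_trajectory_csv(sim$recording, paste0(base, "_traj.csv"),
                           header_comment = csv_header(config))
      write_table_with_header(sim$recording$puncta,
                              paste0(base, "_puncta.csv"), config)
      write_geometry(sim$recording$geometry, paste0(base, "_geometry.json"))
      jsonlite::write_json(
        list(config_hash = config$hash, seed = sc$seed,
             n_puncta = sim$truth$n_puncta,
             total_base_intensity = sim$truth$total_base_intensity,
             states = sim$truth$states,
             segments = sim$truth$segments),
        paste0(base, "_truth.json"), digits = NA, auto_unbox = TRUE
      )
      cells <- c(cells, cell_id)
    }
    manifest$conditions[[cond]] <- list(
      cells = cells, n_trajectories = config$scene[[cond]]$n_trajectories
    )
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}

#' Analyze one recording
#'
#' Runs the full single-cell analysis: trajectory filtering, per-point
#' motion profiles, directed-segment extraction, trajectory mode labels,
#' and (when geometry / puncta are present) the endocytic-ratio and
#' normalized-intensity series.
#'
#' @param recording A [cell_recording()].
#' @param cfg An [analysis_config()].
#' @param min_frames Trajectory length filter applied first (default 50).
#' @return List: `profiles`, `segments`, `segment_points`, `modes` (data
#'   frames, possibly empty), `ratio_series`, `intensity_series` (or
#'   NULL), and `n_trajectories` after filtering.
#' @export
analyze_recording <- function(recording, cfg = analysis_config(),
                              min_frames = 50L) {
  rec <- filter_trajectories(recording, min_frames)
  trajs <- split_trajectories(rec)
  profiles <- list(); segments <- list(); points <- list(); modes <- list()
  for (id in names(trajs)) {
    tr <- trajs[[id]]
    attr(tr, "traj_id") <- id
    prof <- profile_trajectory(tr, cfg, rec$dt)
    seg <- extract_directed_segments(prof, tr, cfg, rec$dt)
    md <- classify_mode(prof, cfg)
    prof$cell_id <- rec$cell_id
    prof$traj_id <- id
    if (nrow(seg$segments)) seg$segments$cell_id <- rec$cell_id
    if (nrow(seg$points)) seg$points$cell_id <- rec$cell_id
    md$cell_id <- rec$cell_id
    profiles[[id]] <- prof
    segments[[id]] <- seg$segments
    points[[id]] <- seg$points
    modes[[id]] <- md
  }
  ratio <- if (!is.null(rec$geometry) && nrow(rec$trajectories)) {
    endocytic_ratio_series(rec, cfg)
  }
  intens <- if (!is.null(rec$puncta) && nrow(rec$puncta)) {
    normalized_intensity_series(rec$puncta, rec$dt)
  }
  list(
    profiles = if (length(profiles)) do.call(rbind, profiles) else NULL,
    segments = if (length(segments)) do.call(rbind, segments) else NULL,
    segment_points = if (length(points)) do.call(rbind, points) else NULL,
    modes = if (length(modes)) do.call(rbind, modes) else NULL,
    ratio_series = ratio,
    intensity_series = intens,
    n_trajectories = length(trajs)
  )
}

#' Analyze simulated or imported recordings on disk
#'
#' Reads every `*_traj.csv` under `in_dir` (with its geometry and puncta
#' sidecars when present), runs [analyze_recording()], pools the
#' per-cell outputs, computes the two-step binned velocity statistics and
#' mode proportions, and writes all tables plus a run manifest to
#' `out_dir`. Deterministic: rerunning on the same inputs reproduces the
#' outputs byte for byte.
#'
#' @param config A [run_config()].
#' @param in_dir Directory holding the per-cell files.
#' @param out_dir Output directory.
#' @return Invisibly, the pooled results list.
#' @export
run_analyze <- function(config, in_dir, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traj_files <- sort(list.files(in_dir, pattern = "_traj\\.csv$",
                                full.names = TRUE))
  if (!length(traj_files)) stop("no *_traj.csv files in ", in_dir, call. = FALSE)
  cfg <- config$analysis
  pooled <- list(profiles = list(), segments = list(), points = list(),
                 modes = list(), ratio = list(), intensity = list())
  counts <- list()
  for (tf in traj_files) {
    base <- sub("_traj\\.csv$", "", tf)
    cell_id <- basename(base)
    rec <- read_trajectory_csv(tf)
    gfile <- paste0(base, "_geometry.json")
    if (file.exists(gfile)) rec$geometry <- read_geometry(gfile)
    pfile <- paste0(base, "_puncta.csv")
    if (file.exists(pfile)) {
      rec$puncta <- utils::read.csv(pfile, comment.char = "#")
    }
    res <- analyze_recording(rec, cfg)
    counts[[cell_id]] <- res$n_trajectories
    if (res$n_trajectories == 0L) {
      message(sprintf("%s: 0 trajectories after filter", cell_id))
    }
    for (nm in c("profiles", "segments", "modes")) {
      if (!is.null(res[[nm]])) pooled[[nm]][[cell_id]] <- res[[nm]]
    }
    if (!is.null(res$segment_points)) pooled$points[[cell_id]] <- res$segment_points
    if (!is.null(res$ratio_series)) {
      rs <- res$ratio_series; rs$cell_id <- cell_id
      pooled$ratio[[cell_id]] <- rs
    }
    if (!is.null(res$intensity_series)) {
      is_ <- res$intensity_series; is_$cell_id <- cell_id
      pooled$intensity[[cell_id]] <- is_
    }
  }
  bindp <- function(l) if (length(l)) do.call(rbind, l) else NULL
  profiles <- bindp(pooled$profiles)
  segments <- bindp(pooled$segments)
  points <- bindp(pooled$points)
  modes <- bindp(pooled$modes)
  ratio <- bindp(pooled$ratio)
  intensity <- bindp(pooled$intensity)

  vel_bins <- if (!is.null(points) && nrow(points)) {
    binned_velocity_stats(points, cfg)
  }
  mode_bins <- if (!is.null(modes) && nrow(modes)) {
    mode_proportions(modes, cfg)
  }

  wt <- function(df, name) {
    if (!is.null(df) && nrow(df)) {
      write_table_with_header(df, file.path(out_dir, name), config)
    }
  }
  wt(profiles, "profiles.csv")
  wt(segments, "segments.csv")
  wt(points, "segment_points.csv")
  wt(modes, "modes.csv")
  wt(ratio, "endocytic_ratio.csv")
  wt(intensity, "intensity_series.csv")
  wt(vel_bins, "binned_velocity.csv")
  wt(mode_bins, "mode_proportions.csv")
  manifest <- list(config_hash = config$hash, seed = config$seed,
                   cells = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(profiles = profiles, segments = segments,
                 segment_points = points, modes = modes,
                 ratio_series = ratio, intensity_series = intensity,
                 binned_velocity = vel_bins, mode_proportions = mode_bins,
                 manifest = manifest))
}

#' Colocalization run over grouped TIFF pairs
#'
#' Computes the per-group Manders M1 table for red/green image pairs and
#' writes it as CSV with the config hash embedded.
#'
#' @param config A [run_config()].
#' @param pairs See [coloc_timecourse()].
#' @param out_dir Output directory.
#' @param threshold Number or `"otsu"`.
#' @return Invisibly, the group table.
#' @export
run_coloc <- function(config, pairs, out_dir, threshold = "otsu") {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- coloc_timecourse(pairs, threshold)
  write_table_with_header(res, file.path(out_dir, "colocalization.csv"), config)
  invisible(res)
}

#' Read or write a run configuration as YAML
#'
#' Serializes the scalar parameters of a [run_config()] (analysis
#' settings, per-condition motion and scene parameters, cell count and
#' seed) so a run is fully documented in one auditable text file.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (is.matrix(v)) as.vector(t(v)) else v)
  }
  yaml::write_yaml(list(
    analysis = strip(config$analysis),
    motion = lapply(config$motion, strip),
    scene = lapply(config$scene, strip),
    n_cells = config$n_cells,
    seed = config$seed
  ), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ana <- do.call(analysis_config, y$analysis)
  mk_motion <- function(m) {
    if (!is.null(m$switch_rates)) {
      m$switch_rates <- matrix(unlist(m$switch_rates), 3L, 3L, byrow = TRUE)
    }
    do.call(motion_params, m)
  }
  mk_scene <- function(s) do.call(scene_params, s)
  run_config(
    analysis = ana,
    motion = lapply(y$motion, mk_motion),
    scene = lapply(y$scene, mk_scene),
    n_cells = y$n_cells,
    seed = y$seed
  )
}
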