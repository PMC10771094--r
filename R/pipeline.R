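#' Default pipeline configuration
#'
#' One nested list holding every tunable of the simulation, rendering,
#' detection, fusion and statistics stages. Round-trips losslessly through
#' [write_config()] / [read_config()] (YAML).
#'
#' @param seed Master seed; every randomized stage derives child seeds from
#'   it.
#' @return Nested configuration list of class `batcage_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cage = list(length_m = 60.2, width_m = 10, height_m = 4.4,
                ud_end = "near"),
    schedule = list(fps = 30, period_s = 240),
    fields = list(source_level_db = 125,
                  atten_db_per_m = as.list(default_atten_db_per_m),
                  repulsion_coeff = 60),
    movement = list(speed_mean_mps = 4, relax_s = 1, max_accel_mps2 = 20,
                    landing_rate_per_min = 0, landing_duration_s = 10),
    cameras = list(n_cameras = 4, coverage_halfwidth_m = 8, standoff_m = 23,
                   height_m = 3.7, hfov_deg = 40,
                   resolution = c(640L, 480L)),
    noise = list(background_level = 30, drift_amp = 3, drift_period_s = 60,
                 gauss_sd = 2, salt_rate = 1e-4, blob_amp = 120,
                 blob_sd_px = 1.5),
    detection = list(window = 151, k_sigma = 5, min_area = 3,
                     max_area = 500, radius_px = 30),
    fusion = list(landmark_spacing_m = 2, tol_m = 0.5),
    stats = list(taus = c(.1, .25, .5, .75, .9), q_min = 100, B = 2000,
                 alpha = 0.05, comparisons = 3)
  ), class = "batcage_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config A [default_config()]-shaped list.
#' @param path File path.
#' @return `write_config()` the path, invisibly; `read_config()` the
#'   configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$cameras$resolution <- as.integer(cfg$cameras$resolution)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "batcage_config")
}

config_cage <- function(config) {
  do.call(cage_geometry, config$cage)
}
config_movement <- function(config) {
  do.call(movement_params, config$movement)
}
config_fields <- function(config, repulsion_coeff = NULL) {
  deterrent_fields(
    source_level_db = config$fields$source_level_db,
    atten_db_per_m = unlist(config$fields$atten_db_per_m),
    repulsion_coeff = repulsion_coeff %||% config$fields$repulsion_coeff
  )
}

#' Simulate a batch of trials and run the full inference
#'
#' For each manifest row: simulate the flight, reduce it to the ground-truth
#' fused distance track, apply the quality-control filter, and compute
#' per-period quantiles; then estimate quantile treatment effects per
#' species with cluster-bootstrap uncertainty. This is the
#' trajectory-level pipeline (no video rendering); see
#' [run_video_pipeline()] for the pixel-level path of a single trial.
#'
#' @param manifest Trial manifest from [simulate_trials()].
#' @param config A [default_config()].
#' @param repulsion_coeff Optional override of the emission repulsion
#'   strength (0 gives null trials).
#' @param by_species Estimate effects per species (default) or pooled.
#' @return List of class `ud_experiment`: `manifest`, `qc`, `quantiles`
#'   (kept bats only), `effects` (a `ud_qte` tibble), `dropped`.
#' @export
#' @examples
#' man <- simulate_trials(3, seed = 1)
#' cfg <- default_config()
#' cfg$schedule$period_s <- 10  # desk-scale periods
#' cfg$stats$q_min <- 10
#' cfg$stats$B <- 200
#' run_experiment(man, cfg)
run_experiment <- function(manifest, config = default_config(),
                           repulsion_coeff = NULL, by_species = TRUE) {
  cage <- config_cage(config)
  movement <- config_movement(config)
  fields <- config_fields(config, repulsion_coeff)
  taus <- config$stats$taus

  pq <- vector("list", nrow(manifest))
  qc <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    rec <- trial_record(m$bat_id, m$species_code, m$sex, m$season, m$ud_end,
                        seed = m$seed, fps = config$schedule$fps,
                        period_s = config$schedule$period_s)
    cage_i <- cage_geometry(cage$length_m, cage$width_m, cage$height_m,
                            ud_end = m$ud_end)
    traj <- simulate_flight(rec, cage_i, fields, movement)
    track <- track_from_trajectory(traj, cage_i)
    qc[[i]] <- qc_filter(track, cage_i)
    if (qc[[i]]$keep) {
      pq[[i]] <- period_quantiles(track, taus = taus,
                                  q_min = config$stats$q_min)
    }
  }
  qc <- bind_rows(qc)
  pq <- bind_rows(pq)
  effects <- quantile_effects(
    pq, metadata = if (by_species) manifest else NULL,
    taus = taus, B = config$stats$B, seed = config$seed,
    alpha = config$stats$alpha, comparisons = config$stats$comparisons
  )
  structure(
    list(manifest = manifest, qc = qc, quantiles = pq, effects = effects,
         dropped = filter(qc, !.data$keep)),
    class = "ud_experiment"
  )
}

#' @export
print.ud_experiment <- function(x, ...) {
  cat(sprintf("<ud_experiment> %d trials (%d kept, %d dropped)\n",
              nrow(x$manifest), sum(x$qc$keep), sum(!x$qc$keep)))
  print(x$effects)
  invisible(x)
}

#' Pixel-level pipeline for one trial
#'
#' Renders a trajectory through every camera, recovers detections by
#' background subtraction, applies the spatiotemporal neighbor filter,
#' converts pixels to distance with per-camera calibrations, and fuses the
#' cameras into one track. Intended for method validation at desk scale;
#' the stage counts (detections before/after filtering, dropped
#' out-of-coverage detections) are returned alongside the track.
#'
#' @param traj A [simulate_flight()] trajectory (or a contiguous slice).
#' @param cage A [cage_geometry()].
#' @param cameras A [camera_bank()].
#' @param noise A [render_noise()].
#' @param config A [default_config()] supplying detection/fusion tunables.
#' @param ud_end Deterrent end; defaults to the trajectory's.
#' @param seed Render seed.
#' @return List: `track` (fused per-frame distances), `detections`
#'   (post-filter), `counts` (per-camera stage counts).
#' @export
run_video_pipeline <- function(traj, cage = cage_geometry(),
                               cameras = camera_bank(cage),
                               noise = render_noise(),
                               config = default_config(), ud_end = NULL,
                               seed = 1L) {
  ud_end <- ud_end %||% attr(traj, "ud_end") %||% cage$ud_end
  det_cfg <- config$detection
  kid <- sub_seeds(seed, length(cameras))
  dets <- vector("list", length(cameras))
  counts <- vector("list", length(cameras))
  for (k in seq_along(cameras)) {
    stack <- render_frames(traj, cameras[[k]], noise, seed = kid[k])
    masks <- background_subtract(stack, det_cfg$window, det_cfg$k_sigma)
    raw <- extract_detections(masks, stack, det_cfg$min_area,
                              det_cfg$max_area)
    filt <- neighbor_filter(raw, det_cfg$radius_px)
    counts[[k]] <- tibble(camera = cameras[[k]]$index,
                          detections_raw = nrow(raw),
                          detections_filtered = nrow(filt))
    dets[[k]] <- filt
  }
  detections <- bind_rows(dets)
  maps <- lapply(cameras, function(cm) {
    fit_calibration(
      calibration_landmarks(cm, cage, config$fusion$landmark_spacing_m),
      coverage = cm$coverage)
  })
  dist_vals <- to_distance(detections, maps, cage, ud_end,
                           tol_m = config$fusion$tol_m)
  fused <- fuse_cameras(dist_vals, cameras, cage, ud_end)
  track <- fused_track(fused, traj$bat_id[1], attr(traj, "schedule"), cage)
  list(track = track, detections = detections, counts = bind_rows(counts))
}

#' Ingest a deposited per-frame distance table
#'
#' Maps an externally deposited table of per-bat, per-period, per-frame
#' distances onto the package's fused-track and metadata schemas via an
#' explicit column mapping, and validates it: species codes must belong to
#' the five analysis groups, period labels to the seven-period design, and
#' per-bat period frame counts are flagged when they deviate more than 10%
#' from the nominal 7,200 frames of a 4-minute period at 30 frames/s.
#'
#' @param path CSV file to ingest.
#' @param column_map Named character vector mapping package column names
#'   (`bat_id`, `period_label`, `distance_m`, optionally `frame`,
#'   `species_code`, `sex`, `season`) to columns of the file.
#' @param expected_frames Nominal frames per period.
#' @return List: `track` (fused-track tibble), `metadata` (one row per bat;
#'   only the mapped identity columns), `validation` (tibble of checks with
#'   `check`, `ok`, `detail`).
#' @export
ingest_supplementary <- function(path, column_map,
                                 expected_frames = 7200) {
  required <- c("bat_id", "period_label", "distance_m")
  if (!all(required %in% names(column_map))) {
    abort(paste("column_map must map:",
                paste(setdiff(required, names(column_map)), collapse = ", ")),
          class = "batcage_schema_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols)) {
    abort(paste("mapped column(s) not in file:",
                paste(missing_cols, collapse = ", ")),
          class = "batcage_schema_error")
  }
  dat <- raw
  names(dat)[match(unname(column_map), names(dat))] <- names(column_map)
  if (!"frame" %in% names(dat)) {
    dat <- dat |>
      group_by(.data$bat_id) |>
      mutate(frame = row_number() - 1L) |>
      ungroup()
  }
  track <- select(dat, "bat_id", "frame", "period_label", "distance_m")
  track$camera <- NA_integer_

  meta_cols <- intersect(c("species_code", "sex", "season"), names(dat))
  metadata <- distinct(dat, .data$bat_id,
                       across(dplyr::all_of(meta_cols)))

  checks <- list()
  if ("species_code" %in% meta_cols) {
    bad <- setdiff(unique(metadata$species_code), species_codes)
    if (length(bad)) {
      abort(paste("unknown species code(s):", paste(bad, collapse = ", ")),
            class = "batcage_schema_error")
    }
    checks$species <- tibble(check = "species codes", ok = TRUE, detail = "")
  }
  bad_periods <- setdiff(unique(track$period_label), trial_period_labels)
  if (length(bad_periods)) {
    abort(paste("unknown period label(s):",
                paste(bad_periods, collapse = ", ")),
          class = "batcage_schema_error")
  }
  checks$periods <- tibble(check = "period labels", ok = TRUE, detail = "")
  fc <- track |>
    count(.data$bat_id, .data$period_label) |>
    filter(abs(.data$n - expected_frames) > 0.1 * expected_frames)
  checks$frames <- tibble(
    check = "frames per period",
    ok = nrow(fc) == 0,
    detail = if (nrow(fc) == 0) "" else
      sprintf("%d bat-period(s) deviate >10%% from %d frames", nrow(fc),
              expected_frames)
  )
  list(track = track, metadata = metadata,
       validation = bind_rows(checks), flagged_periods = fc)
}

#' Read / write the package's tabular artifacts as CSV
#'
#' Plain-CSV persistence for trajectories, detections, fused tracks and
#' trial manifests.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return a tibble.
#' @name batcage_io
NULL

#' @rdname batcage_io
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname batcage_io
#' @export
read_track_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    bat_id = readr::col_character(),
                    frame = readr::col_integer(),
                    period_label = readr::col_character(),
                    distance_m = readr::col_double()))
}

#' @rdname batcage_io
#' @export
read_manifest_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    bat_id = readr::col_character(),
                    species_code = readr::col_character(),
                    sex = readr::col_character(),
                    season = readr::col_character(),
                    ud_end = readr::col_character(),
                    seed = readr::col_integer()))
}
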