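# Method-evaluation studies: self-contained experiments on synthetic trials
# that measure the calibration and accuracy of the whole pipeline. These are
# the computations behind the package's validation claims.

#' Null-calibration study
#'
#' Simulates experiments with the repulsion drift switched off (the deterrent
#' acoustically present but behaviorally inert), runs the full
#' trajectory-to-effects inference on each, and summarizes how often the
#' bootstrap test rejects at the Bonferroni-corrected threshold. Under the
#' null the rejection rate should not exceed the nominal level and effect
#' estimates should center on zero.
#'
#' @param n_experiments Number of independent experiments.
#' @param n_bats Bats (trials) per experiment.
#' @param config A [default_config()]; its `stats` block sets taus, B and the
#'   Bonferroni rule.
#' @param seed Study seed.
#' @return List: `effects` (all per-experiment effect rows), `rejection_rate`,
#'   `mean_estimate_m`, `n_tests`.
#' @export
null_calibration_study <- function(n_experiments = 20, n_bats = 10,
                                   config = default_config(), seed = 1L) {
  kid <- sub_seeds(seed, n_experiments)
  effects <- purrr::map(seq_len(n_experiments), function(e) {
    man <- simulate_trials(n_bats, seed = kid[e])
    cfg <- config
    cfg$seed <- kid[e]
    ex <- run_experiment(man, cfg, repulsion_coeff = 0, by_species = FALSE)
    mutate(tidy(ex$effects), experiment = e)
  }) |> bind_rows()
  done <- filter(effects, !is.na(.data$p))
  list(
    effects = effects,
    rejection_rate = mean(done$p <
                            bonferroni_threshold(config$stats$alpha,
                                                 config$stats$comparisons)$exact),
    mean_estimate_m = mean(effects$estimate, na.rm = TRUE),
    n_tests = nrow(done)
  )
}

#' Known-effect recovery study
#'
#' Computes the flight model's true quantile shifts from a long-run oracle
#' simulation (stationary distance quantiles under each emission field minus
#' the no-emission quantiles), then repeatedly simulates experiments of
#' `n_bats` full-length trials and checks whether the 95% cluster-bootstrap
#' confidence intervals cover the oracle truth.
#'
#' @param n_experiments Replicate experiments.
#' @param n_bats Bats per experiment.
#' @param repulsion_coeff Emission repulsion strength under test.
#' @param config A [default_config()].
#' @param oracle_steps Steps of the long-run oracle simulation.
#' @param seed Study seed.
#' @return List: `truth` (per treatment x tau), `cells` (per experiment x
#'   treatment x tau with CI and coverage flag), `coverage`.
#' @export
recovery_study <- function(n_experiments = 50, n_bats = 50,
                           repulsion_coeff = 60,
                           config = default_config(),
                           oracle_steps = 1e6, seed = 1L) {
  taus <- config$stats$taus
  cage <- config_cage(config)
  movement <- config_movement(config)
  kid <- sub_seeds(seed, n_experiments + 2L)

  period_frames <- as.integer(round(config$schedule$fps *
                                      config$schedule$period_s))
  truth <- purrr::map(treatment_levels, function(trt) {
    fld <- deterrent_field(trt,
                           source_level_db = config$fields$source_level_db,
                           atten_db_per_m = unlist(config$fields$atten_db_per_m),
                           repulsion_coeff = repulsion_coeff)
    ps <- longrun_period_shift(fld, taus, n_steps = oracle_steps,
                               cage = cage, movement = movement,
                               fps = config$schedule$fps,
                               period_frames = period_frames, seed = kid[2])
    tibble(treatment = trt, tau = taus, true_shift_m = ps$shift_m)
  }) |> bind_rows()

  cells <- purrr::map(seq_len(n_experiments), function(e) {
    man <- simulate_trials(n_bats, seed = kid[e + 2L])
    cfg <- config
    cfg$seed <- kid[e + 2L]
    ex <- run_experiment(man, cfg, repulsion_coeff = repulsion_coeff,
                         by_species = FALSE)
    mutate(tidy(ex$effects), experiment = e)
  }) |>
    bind_rows() |>
    inner_join(truth, by = c("treatment", "tau")) |>
    mutate(covered = .data$ci_lo <= .data$true_shift_m &
             .data$true_shift_m <= .data$ci_hi)
  list(truth = truth, cells = cells,
       coverage = mean(cells$covered, na.rm = TRUE))
}

#' Tracking-fidelity study
#'
#' Renders one synthetic trial through the four-camera bank at the default
#' noise settings, runs detection, neighbor filtering, calibration and
#' fusion, and scores the result against the exact projected ground truth:
#' per-frame recall, false detections per frame, centroid error, the median
#' absolute error of fused distances, and the fraction of airborne frames
#' that yield a fused value.
#'
#' @param config A [default_config()]; the camera resolution in it controls
#'   the rendering cost.
#' @param period_s Period length of the rendered trial (desk-scale default).
#' @param repulsion_coeff Emission strength for the rendered trial.
#' @param seed Study seed.
#' @return List of scalar metrics plus the per-camera stage counts.
#' @export
tracking_fidelity_study <- function(config = default_config(),
                                    period_s = 4, repulsion_coeff = 60,
                                    seed = 1L) {
  cage <- config_cage(config)
  kid <- sub_seeds(seed, 2L)
  rec <- trial_record("fidelity", "REDS", seed = kid[1],
                      fps = config$schedule$fps, period_s = period_s)
  fields <- config_fields(config, repulsion_coeff)
  traj <- simulate_flight(rec, cage, fields, config_movement(config))
  cams <- do.call(camera_bank, c(list(cage = cage), config$cameras))
  noise <- do.call(render_noise, config$noise)
  out <- run_video_pipeline(traj, cage, cams, noise, config, seed = kid[2])

  gt <- bind_rows(lapply(cams, function(cm) ground_truth(traj, cm)))
  m <- inner_join(out$detections, gt, by = c("camera", "frame"),
                  suffix = c("", ".gt"))
  m$err_px <- sqrt((m$x_px - m$x_px.gt)^2 + (m$y_px - m$y_px.gt)^2)
  hits <- distinct(filter(m, .data$err_px <= 3), .data$camera, .data$frame)
  truth <- track_from_trajectory(traj, cage)
  cmp <- inner_join(out$track, truth, by = "frame",
                    suffix = c("", ".true"))
  list(
    recall = nrow(hits) / nrow(gt),
    false_per_frame = (nrow(out$detections) - nrow(hits)) / nrow(traj),
    rms_centroid_px = sqrt(mean(m$err_px[m$err_px <= 3]^2)),
    median_abs_error_m = median(abs(cmp$distance_m - cmp$distance_m.true)),
    frac_frames_fused = nrow(out$track) / sum(traj$airborne),
    counts = out$counts
  )
}
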