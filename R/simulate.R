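#' Movement model parameters
#'
#' The flight model is an Ornstein-Uhlenbeck velocity process: velocity
#' relaxes toward zero with time constant `relax_s` while being driven by
#' white noise scaled so the stationary mean speed is `speed_mean_mps`,
#' giving a correlated random walk with reflecting cage walls. During
#' emission periods a repulsive drift (capped at `max_accel_mps2`) is added
#' along the cage axis. Optional landing episodes start as a Poisson process
#' at `landing_rate_per_min` and freeze the bat for `landing_duration_s`.
#'
#' @param speed_mean_mps Stationary mean flight speed, m/s.
#' @param relax_s Velocity relaxation time, s.
#' @param max_accel_mps2 Cap on the repulsive drift acceleration, m/s^2.
#' @param landing_rate_per_min Poisson rate of landing episodes (0 = off).
#' @param landing_duration_s Duration of each landing episode, s.
#' @return An object of class `movement_params`.
#' @export
movement_params <- function(speed_mean_mps = 4, relax_s = 1,
                            max_accel_mps2 = 20,
                            landing_rate_per_min = 0,
                            landing_duration_s = 10) {
  vals <- c(speed_mean_mps, relax_s, max_accel_mps2, landing_rate_per_min,
            landing_duration_s)
  if (!all(is.finite(vals)) || speed_mean_mps <= 0 || relax_s <= 0 ||
      max_accel_mps2 <= 0 || landing_rate_per_min < 0 ||
      landing_duration_s < 0) {
    abort("movement parameters must be finite and positive (rates >= 0)",
          class = "batcage_validation_error")
  }
  structure(
    list(speed_mean_mps = speed_mean_mps, relax_s = relax_s,
         max_accel_mps2 = max_accel_mps2,
         landing_rate_per_min = landing_rate_per_min,
         landing_duration_s = landing_duration_s,
         # mean of a 3D Maxwell speed distribution is sigma * sqrt(8/pi)
         sigma_c = speed_mean_mps / sqrt(8 / pi)),
    class = "movement_params"
  )
}

# Landing episodes as a per-frame airborne flag (Poisson starts, fixed
# duration, drawn from its own seed stream so landings never perturb the
# flight noise stream).
landing_flags <- function(n_frames, fps, movement, seed) {
  airborne <- rep(TRUE, n_frames)
  rate <- movement$landing_rate_per_min / 60 / fps  # per frame
  if (rate <= 0) return(airborne)
  dur <- max(1L, as.integer(round(movement$landing_duration_s * fps)))
  starts <- withr::with_seed(seed, which(runif(n_frames) < rate))
  for (s in starts) airborne[seq(s, min(n_frames, s + dur - 1L))] <- FALSE
  airborne
}

#' Simulate one bat's flight through a full trial
#'
#' Runs the Ornstein-Uhlenbeck flight model frame by frame through the
#' trial's seven periods. During the three emission periods the active
#' field's repulsion drift pushes the bat away from the deterrent end;
#' during acclimation and control periods there is no drift. The bat starts
#' at the cage center; walls reflect. Identical seeds and parameters give
#' bit-identical trajectories.
#'
#' @param record A [trial_record()].
#' @param cage A [cage_geometry()] (the record's `ud_end` overrides the
#'   cage's).
#' @param fields Named list from [deterrent_fields()].
#' @param movement A [movement_params()].
#' @param seed Optional override of the record's trial seed.
#' @return A tibble (class `bat_trajectory`) with columns `bat_id`, `frame`,
#'   `x_m`, `y_m`, `z_m`, `airborne`, `period_label`, `treatment`.
#' @export
#' @examples
#' rec <- trial_record("bat001", "REDS", seed = 7, period_s = 2)
#' simulate_flight(rec, fields = deterrent_fields(repulsion_coeff = 0))
simulate_flight <- function(record, cage = cage_geometry(),
                            fields = deterrent_fields(),
                            movement = movement_params(), seed = NULL) {
  stopifnot(inherits(record, "trial_record"))
  schedule <- record$schedule
  fps <- attr(schedule, "fps")
  n <- max(schedule$end_frame)
  if (!is.null(seed)) {
    kids <- sub_seeds(seed, 3L)
    flight_seed <- kids[2]; landing_seed <- kids[3]
  } else {
    flight_seed <- record$flight_seed; landing_seed <- record$landing_seed
  }

  frames <- seq.int(0L, n - 1L)
  labels <- period_of_frame(frames, schedule)
  treatment <- ifelse(labels %in% treatment_levels, labels, "off")
  trt_rows <- c(combined = 1L, high = 2L, low = 3L)
  drift_idx <- ifelse(treatment == "off", 0L, trt_rows[treatment])

  grid_dx <- 0.05
  drift_tab <- rbind(
    drift_profile(fields$combined, cage, grid_dx, movement$max_accel_mps2),
    drift_profile(fields$high, cage, grid_dx, movement$max_accel_mps2),
    drift_profile(fields$low, cage, grid_dx, movement$max_accel_mps2)
  )

  airborne <- landing_flags(n, fps, movement, landing_seed)
  start <- c(cage$length_m / 2, cage$width_m / 2, cage$height_m / 2)
  sim <- withr::with_seed(flight_seed, .sim_ou_flight(
    n, 1 / fps, c(cage$length_m, cage$width_m, cage$height_m),
    movement$relax_s, movement$sigma_c, movement$max_accel_mps2,
    as.integer(drift_idx), drift_tab, grid_dx,
    if (record$ud_end == "near") 1L else -1L,
    airborne, start
  ))

  out <- tibble(
    bat_id = record$bat_id, frame = frames,
    x_m = sim$pos[, 1], y_m = sim$pos[, 2], z_m = sim$pos[, 3],
    airborne = airborne, period_label = labels, treatment = treatment
  )
  attr(out, "schedule") <- schedule
  attr(out, "ud_end") <- record$ud_end
  class(out) <- c("bat_trajectory", class(out))
  out
}

#' Ground-truth distance track from a simulated trajectory
#'
#' Converts a trajectory straight to the per-frame distance-from-deterrent
#' series the video pipeline would estimate, bypassing rendering and
#' detection. Landed frames carry no observation and are dropped, as a
#' stationary bat produces no detections.
#'
#' @param traj A [simulate_flight()] trajectory.
#' @param cage A [cage_geometry()].
#' @return A fused-track tibble: `bat_id`, `frame`, `period_label`,
#'   `distance_m`, `camera` (`NA`: no camera involved).
#' @export
track_from_trajectory <- function(traj, cage = cage_geometry()) {
  ud_end <- attr(traj, "ud_end") %||% cage$ud_end
  out <- traj |>
    filter(.data$airborne) |>
    mutate(distance_m = if (ud_end == "near") .data$x_m else
             cage$length_m - .data$x_m,
           camera = NA_integer_) |>
    select("bat_id", "frame", "period_label", "distance_m", "camera")
  attr(out, "schedule") <- attr(traj, "schedule")
  out
}

#' Draw a batch of trial records mirroring the study population
#'
#' Species, sex and season are sampled with probabilities proportional to the
#' per-cell trial counts in [study_demographics()]; the deterrent end is
#' randomized per trial. Each trial receives its own child seed.
#'
#' @param n_trials Number of trials.
#' @param seed Batch seed.
#' @param species Optional species code(s) to restrict sampling to.
#' @param fps,period_s Passed to [make_schedule()].
#' @return A manifest tibble: `bat_id`, `species_code`, `sex`, `season`,
#'   `ud_end`, `seed`.
#' @export
#' @examples
#' simulate_trials(5, seed = 1)
simulate_trials <- function(n_trials, seed = 1L, species = NULL,
                            fps = 30, period_s = 240) {
  demo <- study_demographics()
  if (!is.null(species)) {
    demo <- filter(demo, .data$species_code %in% !!species)
    if (nrow(demo) == 0) abort("unknown species code(s)")
  }
  withr::with_seed(as.integer(seed), {
    cells <- demo[sample.int(nrow(demo), n_trials, replace = TRUE,
                             prob = demo$n), ]
    tibble(
      bat_id = sprintf("bat%04d", seq_len(n_trials)),
      species_code = cells$species_code, sex = cells$sex,
      season = cells$season,
      ud_end = sample(c("near", "far"), n_trials, replace = TRUE),
      seed = sample.int(.Machine$integer.max - 1L, n_trials)
    )
  })
}

#' Long-run quantile oracle for the flight model
#'
#' Simulates a single very long run of the Ornstein-Uhlenbeck flight model
#' under a constant emission field (or none) and returns empirical quantiles
#' of distance from the deterrent. With enough steps this approximates the
#' stationary distribution, so differences between a treatment field and
#' `treatment = "off"` give the model's true quantile shifts.
#'
#' @param field A [deterrent_field()] (use treatment `"off"` for the control
#'   distribution).
#' @param taus Quantile levels.
#' @param n_steps Number of frames to simulate.
#' @param cage,movement,fps,seed As elsewhere.
#' @param burn_in Frames discarded before computing quantiles.
#' @return Named numeric vector of distance quantiles (m).
#' @export
longrun_quantiles <- function(field, taus = c(.1, .25, .5, .75, .9),
                              n_steps = 1e6, cage = cage_geometry(),
                              movement = movement_params(), fps = 30,
                              seed = 1L, burn_in = 2000L) {
  grid_dx <- 0.05
  tab <- rbind(drift_profile(field, cage, grid_dx, movement$max_accel_mps2))
  idx <- rep(if (field$treatment == "off") 0L else 1L, n_steps)
  sim <- withr::with_seed(as.integer(seed), .sim_ou_flight(
    as.integer(n_steps), 1 / fps,
    c(cage$length_m, cage$width_m, cage$height_m),
    movement$relax_s, movement$sigma_c, movement$max_accel_mps2,
    idx, tab, grid_dx, 1L, rep(TRUE, n_steps),
    c(cage$length_m / 2, cage$width_m / 2, cage$height_m / 2)
  ))
  x <- sim$pos[-seq_len(burn_in), 1]
  quantile(x, taus, names = TRUE, type = 7)
}

#' Long-run protocol oracle for period-length quantile shifts
#'
#' The per-period quantile estimand of a 4-minute trial period differs from
#' the stationary quantile because the cage occupancy does not fully
#' equilibrate within a period. This oracle runs one very long simulation of
#' the same flight model cycling through period blocks `off`, `off`,
#' `treatment` (mirroring a control period that follows an emission-free
#' period, and an emission period that follows a control), pools distances
#' over the second (control-analogue) and third (treatment) blocks of every
#' cycle, and summarizes them with the estimator's own functional: the
#' tau-quantile is computed within each period block and averaged across
#' cycles, giving the expected per-period quantile (block-pooled quantiles
#' would differ, because per-block quantiles of a slowly mixing occupancy
#' process are a nonlinear summary). The difference of the two averages is
#' the model's true period-length quantile shift.
#'
#' @param field A [deterrent_field()] for the emission block.
#' @param taus Quantile levels.
#' @param n_steps Approximate total frames (rounded up to whole cycles).
#' @param cage,movement,fps,seed As elsewhere.
#' @param period_frames Frames per period block.
#' @return Tibble `tau`, `control_q`, `treatment_q`, `shift_m`.
#' @export
longrun_period_shift <- function(field, taus = c(.1, .25, .5, .75, .9),
                                 n_steps = 2e6, cage = cage_geometry(),
                                 movement = movement_params(), fps = 30,
                                 period_frames = 7200L, seed = 1L) {
  cycle <- 3L * period_frames
  n_cycles <- max(2L, ceiling(n_steps / cycle))
  n <- n_cycles * cycle
  block <- rep(rep(1:3, each = period_frames), n_cycles)
  idx <- ifelse(block == 3L, 1L, 0L)
  grid_dx <- 0.05
  tab <- rbind(drift_profile(field, cage, grid_dx, movement$max_accel_mps2))
  sim <- withr::with_seed(as.integer(seed), .sim_ou_flight(
    n, 1 / fps, c(cage$length_m, cage$width_m, cage$height_m),
    movement$relax_s, movement$sigma_c, movement$max_accel_mps2,
    as.integer(idx), tab, grid_dx, 1L, rep(TRUE, n),
    c(cage$length_m / 2, cage$width_m / 2, cage$height_m / 2)
  ))
  x <- sim$pos[, 1]
  cycle_id <- rep(seq_len(n_cycles), each = cycle)
  block_q <- function(b) {
    per_cycle <- vapply(split(x[block == b], cycle_id[block == b]),
                        quantile, numeric(length(taus)), probs = taus,
                        names = FALSE, type = 7)
    if (length(taus) == 1L) mean(per_cycle) else rowMeans(per_cycle)
  }
  cq <- block_q(2L)
  tq <- block_q(3L)
  tibble(tau = taus, control_q = cq, treatment_q = tq, shift_m = tq - cq)
}
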