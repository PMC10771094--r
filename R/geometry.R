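#' Flight cage geometry
#'
#' Describes the trial arena: a box `length_m` x `width_m` x `height_m` with an
#' ultrasonic deterrent (UD) mounted at one end of the long axis. Cage
#' coordinates put `x` along the long axis, `y` across the width and `z` up;
#' distance from the deterrent is `x` when `ud_end = "near"` (source at
#' `x = 0`) and `length_m - x` when `ud_end = "far"`.
#'
#' Defaults match a 60.2 m x 10 m x 4.4 m outdoor cage.
#'
#' @param length_m,width_m,height_m Cage dimensions in meters.
#' @param ud_end Which end of the long axis hosts the active deterrent.
#' @return An object of class `cage_geometry`.
#' @export
#' @examples
#' cage_geometry()
cage_geometry <- function(length_m = 60.2, width_m = 10, height_m = 4.4,
                          ud_end = c("near", "far")) {
  ud_end <- match.arg(ud_end)
  dims <- c(length_m, width_m, height_m)
  if (!all(is.finite(dims)) || any(dims <= 0)) {
    abort("all cage dimensions must be finite and > 0")
  }
  structure(
    list(length_m = length_m, width_m = width_m, height_m = height_m,
         ud_end = ud_end),
    class = "cage_geometry"
  )
}

#' @export
print.cage_geometry <- function(x, ...) {
  cat(sprintf("<cage_geometry> %.1f x %.1f x %.1f m, deterrent at %s end\n",
              x$length_m, x$width_m, x$height_m, x$ud_end))
  invisible(x)
}

#' Distance from the active deterrent
#'
#' @param x_m Cage-axis coordinate(s) in meters.
#' @param cage A [cage_geometry()].
#' @return Distance in meters from the active deterrent end, in
#'   `[0, length_m]` for in-cage points.
#' @export
distance_from_ud <- function(x_m, cage) {
  if (cage$ud_end == "near") x_m else cage$length_m - x_m
}

trial_period_labels <- c("acclimation", "control1", "control2", "control3",
                         "combined", "high", "low")
treatment_levels <- c("combined", "high", "low")

#' Randomized trial schedule
#'
#' A trial is seven contiguous equal-length periods: an acclimation period,
#' then a control period, then the three emission treatments (`combined`,
#' `high`, `low`) in an order drawn uniformly at random, each preceded by its
#' own control period. Frame intervals are half-open `[start_frame,
#' end_frame)` and 0-based.
#'
#' @param seed Integer seed; the treatment permutation is a deterministic
#'   function of it.
#' @param fps Frame rate of the recording (frames per second).
#' @param period_s Period length in seconds (default 4 minutes).
#' @return A tibble of class `trial_schedule` with columns `period`, `label`,
#'   `start_frame`, `end_frame`, and attributes `fps` and `period_frames`.
#' @export
#' @examples
#' make_schedule(seed = 1)
make_schedule <- function(seed, fps = 30, period_s = 240) {
  perm <- withr::with_seed(as.integer(seed), sample(treatment_levels))
  labels <- c("acclimation", "control1", perm[1], "control2", perm[2],
              "control3", perm[3])
  pf <- as.integer(round(fps * period_s))
  out <- tibble(
    period = 1:7,
    label = labels,
    start_frame = (0:6) * pf,
    end_frame = (1:7) * pf
  )
  attr(out, "fps") <- fps
  attr(out, "period_frames") <- pf
  class(out) <- c("trial_schedule", class(out))
  out
}

#' Map frame indices to schedule period labels
#'
#' @param frames Integer 0-based frame indices.
#' @param schedule A [make_schedule()] result.
#' @return Character vector of period labels (`NA` outside the trial).
#' @export
period_of_frame <- function(frames, schedule) {
  idx <- findInterval(frames, schedule$start_frame)
  lab <- rep(NA_character_, length(frames))
  ok <- idx >= 1 & frames < max(schedule$end_frame) & frames >= 0
  lab[ok] <- schedule$label[idx[ok]]
  lab
}

#' Species, sex and season composition of the study population
#'
#' Per-cell trial counts for the five analysis groups: red bats (`REDS`,
#' *Lasiurus borealis* / *L. blossevillii*), cave myotis (`MYVE`), Brazilian
#' free-tailed bats (`TABR`), evening bats (`NYHU`) and tricolored bats
#' (`PESU`), split by sex and season. Used as sampling weights by
#' [simulate_trials()].
#'
#' @return A tibble with columns `species_code`, `sex`, `season`, `n`.
#' @export
study_demographics <- function() {
  tribble(
    ~species_code, ~sex, ~season, ~n,
    "REDS", "M", "fall", 17, "REDS", "M", "spring", 4,
    "REDS", "F", "fall", 13, "REDS", "F", "spring", 12,
    "MYVE", "M", "fall", 21, "MYVE", "M", "spring", 11,
    "MYVE", "F", "fall", 25, "MYVE", "F", "spring", 0,
    "TABR", "M", "fall", 31, "TABR", "M", "spring", 7,
    "TABR", "F", "fall", 21, "TABR", "F", "spring", 14,
    "NYHU", "M", "fall", 21, "NYHU", "M", "spring", 1,
    "NYHU", "F", "fall", 23, "NYHU", "F", "spring", 8,
    "PESU", "M", "fall", 7,  "PESU", "M", "spring", 4,
    "PESU", "F", "fall", 5,  "PESU", "F", "spring", 1
  )
}

species_codes <- c("REDS", "MYVE", "TABR", "NYHU", "PESU")

#' Metadata record for one trial
#'
#' Bundles the identity of the bat, which cage end hosts the active
#' deterrent, the randomized schedule and the trial seed. All
#' trial-level randomness (schedule permutation, flight, landings) derives
#' deterministically from `seed` via independent child seeds.
#'
#' @param bat_id Identifier string.
#' @param species_code One of `REDS`, `MYVE`, `TABR`, `NYHU`, `PESU`.
#' @param sex `"F"` or `"M"`.
#' @param season `"fall"` or `"spring"`.
#' @param ud_end `"near"` or `"far"`.
#' @param seed Integer trial seed.
#' @param fps,period_s Passed to [make_schedule()].
#' @return An object of class `trial_record` with elements including
#'   `schedule` and the derived `flight_seed` / `landing_seed`.
#' @export
trial_record <- function(bat_id, species_code, sex = "F", season = "fall",
                         ud_end = "near", seed = 1L, fps = 30, period_s = 240) {
  species_code <- match.arg(species_code, species_codes)
  sex <- match.arg(sex, c("F", "M"))
  season <- match.arg(season, c("fall", "spring"))
  ud_end <- match.arg(ud_end, c("near", "far"))
  kids <- sub_seeds(seed, 3L)
  structure(
    list(bat_id = bat_id, species_code = species_code, sex = sex,
         season = season, ud_end = ud_end, seed = as.integer(seed),
         schedule = make_schedule(kids[1], fps = fps, period_s = period_s),
         flight_seed = kids[2], landing_seed = kids[3]),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s (%s, %s, %s), deterrent %s end, seed %d\n",
              x$bat_id, x$species_code, x$sex, x$season, x$ud_end, x$seed))
  invisible(x)
}
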