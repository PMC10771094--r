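#' Fuse per-camera distance values into one track
#'
#' Collapses simultaneous detections from overlapping cameras to exactly one
#' distance value per frame. Per frame: the lowest-index reporting camera
#' (cameras are ordered by ascending cage-axis coverage) wins; values from
#' the next camera that do not exceed the winning camera's minimum reported
#' distance in that frame are discarded as duplicates; any remaining
#' candidates are resolved by taking the detection closest to its own
#' camera's coverage center. Fusion never invents values: every output
#' distance equals one of the input distances.
#'
#' @param values Tibble `camera`, `frame`, `distance_m` (from
#'   [to_distance()]).
#' @param cameras The [camera_bank()] that produced the detections.
#' @param cage A [cage_geometry()].
#' @param ud_end Deterrent end used when `distance_m` was computed; defaults
#'   to the cage's.
#' @return Tibble `frame`, `distance_m`, `camera`, one row per reporting
#'   frame.
#' @export
fuse_cameras <- function(values, cameras, cage = cage_geometry(),
                         ud_end = NULL) {
  ud_end <- ud_end %||% cage$ud_end
  if (nrow(values) == 0) {
    return(tibble(frame = integer(), distance_m = numeric(),
                  camera = integer()))
  }
  idx <- vapply(cameras, function(cm) cm$index, integer(1))
  center_d <- vapply(cameras, function(cm) {
    mean(if (ud_end == "near") cm$coverage else cage$length_m - cm$coverage)
  }, numeric(1))
  values |>
    mutate(cam_rank = match(.data$camera, idx),
           center_off = abs(.data$distance_m - center_d[.data$cam_rank])) |>
    group_by(.data$frame) |>
    filter({
      lead_rank <- min(.data$cam_rank)
      m_k <- min(.data$distance_m[.data$cam_rank == lead_rank])
      .data$cam_rank == lead_rank |
        (.data$cam_rank == lead_rank + 1L & .data$distance_m > m_k)
    }) |>
    arrange(.data$cam_rank, .data$center_off, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    select("frame", "distance_m", "camera") |>
    arrange(.data$frame)
}

#' Assemble a fused per-trial track
#'
#' Attaches the bat identity and schedule period labels to fused per-frame
#' distances, giving the analysis-ready track.
#'
#' @param fused Output of [fuse_cameras()] (or any `frame`/`distance_m`
#'   tibble).
#' @param bat_id Identifier.
#' @param schedule The trial's [make_schedule()].
#' @param cage A [cage_geometry()] used to validate the distance range.
#' @return Tibble `bat_id`, `frame`, `period_label`, `distance_m`, `camera`.
#' @export
fused_track <- function(fused, bat_id, schedule, cage = cage_geometry()) {
  if (any(fused$distance_m < 0 | fused$distance_m > cage$length_m)) {
    abort("fused distances outside [0, cage length]")
  }
  out <- fused |>
    mutate(bat_id = bat_id,
           period_label = period_of_frame(.data$frame, schedule),
           camera = if ("camera" %in% names(fused)) .data$camera else
             NA_integer_) |>
    select("bat_id", "frame", "period_label", "distance_m", "camera")
  attr(out, "schedule") <- schedule
  out
}

#' Mean distance error induced by the center-line assumption
#'
#' The calibration assumes bats fly on the cage's long center line; a bat at
#' lateral offset `w` from that line sits at true depth `D0 + w` (with `D0`
#' the standoff plus half the cage width), so its estimated cage-axis
#' position is scaled by `D0 / (D0 + w)` about the camera axis. This
#' integrates the absolute position error over bat positions uniform in the
#' camera's coverage and offsets uniform in `[-offset_bound_m,
#' offset_bound_m]`.
#'
#' @param cage A [cage_geometry()].
#' @param cam A [camera_model()].
#' @param offset_bound_m Maximum lateral offset from the center line (m), at
#'   most half the cage width.
#' @param n_grid Nodes per dimension for the midpoint-rule integration.
#' @return Mean absolute cage-axis distance error in meters.
#' @export
#' @examples
#' centerline_uncertainty(cage_geometry(), camera_bank()[[1]], 3)
centerline_uncertainty <- function(cage, cam, offset_bound_m, n_grid = 601) {
  stopifnot(offset_bound_m >= 0, offset_bound_m <= cage$width_m / 2)
  if (offset_bound_m == 0) return(0)
  d0 <- cam$standoff_m + cage$width_m / 2
  xs <- seq(cam$coverage[1], cam$coverage[2], length.out = n_grid)
  xs <- (xs[-1] + xs[-n_grid]) / 2
  ws <- seq(-offset_bound_m, offset_bound_m, length.out = n_grid)
  ws <- (ws[-1] + ws[-n_grid]) / 2
  err <- outer(abs(xs - cam$axis_center_m), abs(ws) / (d0 + ws))
  mean(err)
}
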