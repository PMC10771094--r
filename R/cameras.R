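#' Virtual side-view thermal camera
#'
#' A pinhole camera on the north side of the cage, mounted `standoff_m` from
#' the cage wall at height `height_m`, optical axis horizontal and
#' perpendicular to the cage axis, pointed at cage-axis coordinate
#' `axis_center_m`. `coverage` is the cage-axis interval the camera is
#' responsible for during fusion; neighboring cameras' coverages overlap
#' slightly.
#'
#' Pixel coordinates are 0-based with `x_px` increasing with cage-axis
#' coordinate and `y_px` increasing downward.
#'
#' @param index Camera number (1-based, ordered along the cage axis).
#' @param axis_center_m Cage-axis coordinate the camera points at.
#' @param standoff_m Perpendicular distance from the cage side (m).
#' @param height_m Mount height (m).
#' @param hfov_deg Horizontal field of view (degrees).
#' @param resolution `c(width_px, height_px)`.
#' @param coverage Cage-axis interval `c(min_m, max_m)` assigned to this
#'   camera for fusion.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(index, axis_center_m, standoff_m = 23,
                         height_m = 3.7, hfov_deg = 40,
                         resolution = c(640L, 480L), coverage = NULL) {
  stopifnot(standoff_m > 0, hfov_deg > 0, hfov_deg < 180,
            length(resolution) == 2, all(resolution > 0))
  if (is.null(coverage)) coverage <- axis_center_m + c(-8, 8)
  focal_px <- (resolution[1] / 2) / tan(hfov_deg / 2 * pi / 180)
  structure(
    list(index = as.integer(index), axis_center_m = axis_center_m,
         standoff_m = standoff_m, height_m = height_m, hfov_deg = hfov_deg,
         resolution = as.integer(resolution), coverage = coverage,
         focal_px = focal_px),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model> #%d at axis %.1f m, %dx%d px, hfov %g deg, coverage [%.1f, %.1f] m\n",
    x$index, x$axis_center_m, x$resolution[1], x$resolution[2], x$hfov_deg,
    x$coverage[1], x$coverage[2]))
  invisible(x)
}

#' Bank of side-view cameras covering the full cage
#'
#' Places `n_cameras` evenly along the cage axis with coverage intervals of
#' half-width `coverage_halfwidth_m` clipped to the cage, so that the union
#' covers the whole axis and adjacent coverages overlap slightly.
#'
#' @param cage A [cage_geometry()].
#' @param n_cameras Number of cameras.
#' @param coverage_halfwidth_m Half-width of each coverage interval (m).
#' @inheritParams camera_model
#' @return List of [camera_model()] objects.
#' @export
#' @examples
#' camera_bank()
camera_bank <- function(cage = cage_geometry(), n_cameras = 4,
                        coverage_halfwidth_m = 8, standoff_m = 23,
                        height_m = 3.7, hfov_deg = 40,
                        resolution = c(640L, 480L)) {
  L <- cage$length_m
  centers <- (seq_len(n_cameras) - 0.5) * L / n_cameras
  cams <- lapply(seq_len(n_cameras), function(i) {
    cov <- pmin(pmax(centers[i] + c(-1, 1) * coverage_halfwidth_m, 0), L)
    camera_model(i, centers[i], standoff_m, height_m, hfov_deg, resolution,
                 coverage = cov)
  })
  # coverage invariants: union spans the cage, neighbors overlap
  for (i in seq_len(n_cameras - 1)) {
    if (cams[[i + 1]]$coverage[1] >= cams[[i]]$coverage[2]) {
      abort(sprintf("cameras %d and %d do not overlap; widen coverage", i,
                    i + 1))
    }
  }
  if (cams[[1]]$coverage[1] > 0 || cams[[n_cameras]]$coverage[2] < L) {
    abort("camera coverages do not span the cage axis")
  }
  cams
}

#' Project cage coordinates through a camera
#'
#' Pinhole projection. Depth is measured from the camera along its optical
#' axis (perpendicular to the cage axis), so a point at cage width `y` sits
#' at depth `standoff + y`.
#'
#' @param points Data frame with columns `x_m`, `y_m`, `z_m` (a trajectory
#'   works directly).
#' @param cam A [camera_model()].
#' @return A tibble with `x_px`, `y_px`, `depth_m`, `in_view`.
#' @export
project_points <- function(points, cam) {
  stopifnot(all(c("x_m", "y_m", "z_m") %in% names(points)))
  w <- cam$resolution[1]; h <- cam$resolution[2]
  depth <- points$y_m + cam$standoff_m
  u <- w / 2 + cam$focal_px * (points$x_m - cam$axis_center_m) / depth
  v <- h / 2 + cam$focal_px * (cam$height_m - points$z_m) / depth
  tibble(
    x_px = u, y_px = v, depth_m = depth,
    in_view = is.finite(u) & is.finite(v) & depth > 0 &
      u >= 0 & u < w & v >= 0 & v < h
  )
}

#' Exact projected detections for a trajectory (testing aid)
#'
#' The noise-free projected centroid of the bat in every airborne, in-view
#' frame of one camera; the reference against which detector output is
#' scored.
#'
#' @param traj A [simulate_flight()] trajectory (or any tibble with `frame`,
#'   `x_m`, `y_m`, `z_m`, `airborne`).
#' @param cam A [camera_model()].
#' @return Tibble `camera`, `frame`, `x_px`, `y_px`.
#' @export
ground_truth <- function(traj, cam) {
  pr <- project_points(traj, cam)
  keep <- traj$airborne & pr$in_view
  tibble(camera = cam$index, frame = traj$frame[keep],
         x_px = pr$x_px[keep], y_px = pr$y_px[keep])
}
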