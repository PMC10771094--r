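#' Fit a per-camera pixel-to-distance calibration
#'
#' Monotone piecewise-linear interpolation of landmark pairs relating
#' `x_px` (horizontal pixel coordinate) to cage-axis distance in meters,
#' with linear extrapolation from the end segments clamped to the camera's
#' coverage interval. Landmarks must be strictly increasing in both pixel
#' and distance (the imaging convention puts larger cage-axis coordinates at
#' larger `x_px`).
#'
#' @param landmarks Data frame with columns `x_px` and `distance_m` (and
#'   optionally `camera`).
#' @param camera Camera index the map belongs to (taken from `landmarks` if
#'   present).
#' @param coverage Interval `c(min_m, max_m)` the output is clamped to;
#'   defaults to the landmark distance range.
#' @return An object of class `calibration_map`.
#' @export
#' @examples
#' m <- fit_calibration(data.frame(x_px = c(100, 300), distance_m = c(10, 20)))
#' predict(m, 200)  # 15
fit_calibration <- function(landmarks, camera = NULL, coverage = NULL) {
  stopifnot(all(c("x_px", "distance_m") %in% names(landmarks)))
  if (nrow(landmarks) < 2) abort("need at least 2 landmarks")
  lm_ord <- landmarks[order(landmarks$x_px), ]
  bad <- which(diff(lm_ord$distance_m) <= 0 | diff(lm_ord$x_px) <= 0)
  if (length(bad)) {
    i <- bad[1]
    abort(sprintf(
      paste0("landmarks are not strictly increasing: (%g px, %g m) vs ",
             "(%g px, %g m)"),
      lm_ord$x_px[i], lm_ord$distance_m[i],
      lm_ord$x_px[i + 1], lm_ord$distance_m[i + 1]),
      class = "batcage_calibration_error")
  }
  if (is.null(camera)) camera <- lm_ord$camera[1] %||% NA_integer_
  if (is.null(coverage)) coverage <- range(lm_ord$distance_m)
  structure(
    list(camera = as.integer(camera), x_px = lm_ord$x_px,
         distance_m = lm_ord$distance_m, coverage = coverage),
    class = "calibration_map"
  )
}

# piecewise-linear evaluation with end-segment extrapolation, before clamping
pwl_eval <- function(x, xs, ys) {
  out <- approx(xs, ys, xout = x, rule = 1, ties = "ordered")$y
  k <- length(xs)
  lo <- x < xs[1]; hi <- x > xs[k]
  s1 <- (ys[2] - ys[1]) / (xs[2] - xs[1])
  sk <- (ys[k] - ys[k - 1]) / (xs[k] - xs[k - 1])
  out[lo] <- ys[1] + s1 * (x[lo] - xs[1])
  out[hi] <- ys[k] + sk * (x[hi] - xs[k])
  out
}

#' Evaluate a calibration map
#'
#' @param object A [fit_calibration()] map.
#' @param x_px Pixel coordinates.
#' @param clamp Clamp output to the coverage interval (default `TRUE`).
#' @param ... Unused.
#' @return Cage-axis distances in meters.
#' @export
predict.calibration_map <- function(object, x_px, clamp = TRUE, ...) {
  d <- pwl_eval(x_px, object$x_px, object$distance_m)
  if (clamp) d <- pmin(pmax(d, object$coverage[1]), object$coverage[2])
  d
}

#' Invert a calibration map
#'
#' @param map A [fit_calibration()] map.
#' @param distance_m Cage-axis distances in meters.
#' @return Pixel coordinates.
#' @export
calibration_inverse <- function(map, distance_m) {
  pwl_eval(distance_m, map$distance_m, map$x_px)
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf("<calibration_map> camera %s: %d landmarks, coverage [%.1f, %.1f] m\n",
              x$camera, length(x$x_px), x$coverage[1], x$coverage[2]))
  invisible(x)
}

#' Generate calibration landmarks from known cage positions
#'
#' Projects points at known cage-axis distances on the cage center line
#' through a camera, producing the (pixel, distance) pairs a field crew
#' would measure against cage landmarks.
#'
#' @param cam A [camera_model()].
#' @param cage A [cage_geometry()].
#' @param spacing_m Landmark spacing along the cage axis (m).
#' @return Tibble `camera`, `x_px`, `distance_m` restricted to the camera's
#'   coverage interval.
#' @export
calibration_landmarks <- function(cam, cage = cage_geometry(),
                                  spacing_m = 2) {
  d <- seq(cam$coverage[1], cam$coverage[2], by = spacing_m)
  if (tail(d, 1) < cam$coverage[2]) d <- c(d, cam$coverage[2])
  pts <- tibble(x_m = d, y_m = cage$width_m / 2, z_m = cam$height_m)
  pr <- project_points(pts, cam)
  tibble(camera = cam$index, x_px = pr$x_px, distance_m = d)
}

#' Convert pixel detections to distance from the deterrent
#'
#' Applies each camera's calibration to the `x_px` coordinate (the vertical
#' coordinate is ignored under the center-line assumption), yielding
#' cage-axis position, then measures distance from the active deterrent end.
#' Detections whose uncalibrated estimate falls outside the camera's
#' coverage interval by more than `tol_m` are dropped and counted in a
#' message.
#'
#' @param detections Detections tibble with `camera`, `frame`, `x_px`.
#' @param maps A single [fit_calibration()] map or a list of maps whose
#'   `camera` fields cover all cameras present.
#' @param cage A [cage_geometry()].
#' @param ud_end Which end hosts the active deterrent; defaults to the
#'   cage's.
#' @param tol_m Out-of-coverage tolerance before a detection is dropped.
#' @return Tibble `camera`, `frame`, `x_px`, `distance_m`.
#' @export
to_distance <- function(detections, maps, cage = cage_geometry(),
                        ud_end = NULL, tol_m = 0.5) {
  ud_end <- ud_end %||% cage$ud_end
  if (inherits(maps, "calibration_map")) maps <- list(maps)
  map_cam <- vapply(maps, function(m) m$camera, integer(1))
  missing_cams <- setdiff(unique(detections$camera), map_cam)
  if (length(missing_cams)) {
    abort(paste("no calibration for camera(s)",
                paste(missing_cams, collapse = ", ")))
  }
  parts <- lapply(split(detections, detections$camera), function(det) {
    m <- maps[[match(det$camera[1], map_cam)]]
    raw <- pwl_eval(det$x_px, m$x_px, m$distance_m)
    keep <- raw >= m$coverage[1] - tol_m & raw <= m$coverage[2] + tol_m
    det$axis_m <- pmin(pmax(raw, m$coverage[1]), m$coverage[2])
    det$dropped <- !keep
    det
  })
  all <- bind_rows(parts)
  n_drop <- sum(all$dropped)
  if (n_drop > 0) {
    message(sprintf("to_distance: dropped %d detection(s) outside coverage",
                    n_drop))
  }
  all |>
    filter(!.data$dropped) |>
    mutate(distance_m = if (ud_end == "near") .data$axis_m else
             cage$length_m - .data$axis_m) |>
    select("camera", "frame", "x_px", "distance_m") |>
    arrange(.data$frame, .data$camera)
}
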