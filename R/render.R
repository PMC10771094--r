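#' Thermal rendering noise parameters
#'
#' Controls the synthetic 8-bit thermal image model: a flat background with a
#' slow per-row sinusoidal drift (exercising the background model), additive
#' Gaussian pixel noise, isolated salt pixels (hot spurious pixels), and the
#' bat itself as a Gaussian blob at the projected position.
#'
#' @param background_level Mean background intensity (0-255).
#' @param drift_amp Amplitude of the slow background drift.
#' @param drift_period_s Period of the drift sinusoid, seconds.
#' @param gauss_sd Gaussian pixel noise standard deviation.
#' @param salt_rate Per-pixel per-frame probability of a saturated salt pixel.
#' @param blob_amp Peak intensity of the bat blob above background.
#' @param blob_sd_px Gaussian radius of the blob, pixels.
#' @return An object of class `render_noise`.
#' @export
render_noise <- function(background_level = 30, drift_amp = 3,
                         drift_period_s = 60, gauss_sd = 2,
                         salt_rate = 1e-4, blob_amp = 120, blob_sd_px = 1.5) {
  structure(
    list(background_level = background_level, drift_amp = drift_amp,
         drift_period_s = drift_period_s, gauss_sd = gauss_sd,
         salt_rate = salt_rate, blob_amp = blob_amp, blob_sd_px = blob_sd_px),
    class = "render_noise"
  )
}

#' Render a trajectory into a noisy thermal frame stack
#'
#' Each airborne in-view frame contains one Gaussian blob at the bat's
#' projected pixel position, added onto the noisy drifting background, then
#' quantized to 8 bits. The salt-noise stream has its own child seed, so
#' changing only `salt_seed` perturbs no blob or background pixel.
#'
#' @param traj Trajectory rows to render (frames must be contiguous).
#' @param cam A [camera_model()].
#' @param noise A [render_noise()].
#' @param seed Render seed.
#' @param salt_seed Optional explicit seed for the salt-noise stream.
#' @return An object of class `frame_stack`: list with `camera`, integer
#'   array `frames` (height x width x n), `fps`, `start_frame`.
#' @export
render_frames <- function(traj, cam, noise = render_noise(), seed = 1L,
                          salt_seed = NULL) {
  fr <- traj$frame
  if (length(fr) > 1 && any(diff(fr) != 1L)) {
    abort("trajectory frames must be contiguous to render a stack")
  }
  fps <- attr(attr(traj, "schedule"), "fps") %||% 30
  w <- cam$resolution[1]; h <- cam$resolution[2]
  n <- nrow(traj)
  pr <- project_points(traj, cam)
  kids <- sub_seeds(seed, 2L)
  if (is.null(salt_seed)) salt_seed <- kids[2]

  half <- ceiling(4 * noise$blob_sd_px)
  stack <- array(0L, dim = c(h, w, n))
  withr::with_seed(kids[1], {
    row_phase <- runif(h, 0, 2 * pi)
    for (t in seq_len(n)) {
      bg <- noise$background_level +
        noise$drift_amp * sin(2 * pi * (fr[t] / fps) / noise$drift_period_s +
                                row_phase)
      fr_img <- matrix(bg, h, w) +
        matrix(rnorm(h * w, 0, noise$gauss_sd), h, w)
      if (traj$airborne[t] && pr$in_view[t]) {
        u <- pr$x_px[t]; v <- pr$y_px[t]
        cols <- max(0L, floor(u) - half):min(w - 1L, floor(u) + half)
        rows <- max(0L, floor(v) - half):min(h - 1L, floor(v) + half)
        if (length(cols) && length(rows)) {
          blob <- noise$blob_amp *
            exp(-(outer((rows - v)^2, (cols - u)^2, "+")) /
                  (2 * noise$blob_sd_px^2))
          fr_img[rows + 1L, cols + 1L] <- fr_img[rows + 1L, cols + 1L] + blob
        }
      }
      stack[, , t] <- as.integer(pmin(pmax(round(fr_img), 0), 255))
    }
  })
  withr::with_seed(salt_seed, {
    for (t in seq_len(n)) {
      ns <- rbinom(1, h * w, noise$salt_rate)
      if (ns > 0) {
        idx <- sample.int(h * w, ns)
        sl <- stack[, , t]; sl[idx] <- 255L; stack[, , t] <- sl
      }
    }
  })
  structure(
    list(camera = cam, frames = stack, fps = fps,
         start_frame = as.integer(fr[1])),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> camera %d: %d frames of %dx%d px @ %g fps, start frame %d\n",
              x$camera$index, d[3], d[2], d[1], x$fps, x$start_frame))
  invisible(x)
}

#' Write / read a frame stack as multi-page TIFF plus JSON sidecar
#'
#' The TIFF holds 8-bit grayscale pages; the sidecar records the camera
#' model, fps and start frame so the stack round-trips losslessly.
#'
#' @param stack A [render_frames()] result.
#' @param path Path to the `.tif` file; the sidecar is `path` + `.json`.
#' @return `write_frame_stack()` returns `path` invisibly;
#'   `read_frame_stack()` returns a `frame_stack`.
#' @export
write_frame_stack <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack$frames)[3]),
                  function(t) stack$frames[, , t] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  cam <- stack$camera
  side <- list(camera = cam[c("index", "axis_center_m", "standoff_m",
                              "height_m", "hfov_deg", "resolution",
                              "coverage")],
               fps = stack$fps, start_frame = stack$start_frame)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cm <- side$camera
  cam <- camera_model(cm$index, cm$axis_center_m, cm$standoff_m, cm$height_m,
                      cm$hfov_deg, cm$resolution, coverage = cm$coverage)
  stack <- array(0L, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                             length(pages)))
  for (t in seq_along(pages)) {
    stack[, , t] <- as.integer(round(pages[[t]] * 255))
  }
  structure(list(camera = cam, frames = stack, fps = side$fps,
                 start_frame = as.integer(side$start_frame)),
            class = "frame_stack")
}
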