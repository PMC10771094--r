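cage <- cage_geometry()
cam <- camera_model(2, 22.575, resolution = c(160L, 120L),
                    coverage = c(14.55, 30.6))

mini_traj <- function(n = 180, seed = 5) {
  rec <- trial_record("b1", "REDS", seed = seed, period_s = 2)
  simulate_flight(rec, cage, deterrent_fields(repulsion_coeff = 0))[1:n, ]
}

test_that("constant and slowly drifting stacks yield no foreground", {
  traj <- mini_traj(30)
  grounded <- dplyr::mutate(traj, airborne = FALSE)
  flat <- render_frames(grounded, cam,
                        render_noise(drift_amp = 0, gauss_sd = 0,
                                     salt_rate = 0), seed = 1)
  expect_warning(m <- background_subtract(flat, window = 151),
                 "window shrunk")
  expect_equal(sum(m$masks), 0)
  # slow drift stays within the robust threshold: no foreground
  grounded2 <- dplyr::mutate(mini_traj(180), airborne = FALSE)
  drifty <- render_frames(grounded2, cam,
                          render_noise(drift_amp = 3, gauss_sd = 2,
                                       drift_period_s = 60, salt_rate = 0),
                          seed = 1)
  md <- background_subtract(drifty, window = 151)
  expect_lt(mean(md$masks), 1e-4)
})

test_that("a rendered blob is recovered at sub-pixel accuracy", {
  # grounded background with a few isolated airborne frames, so the
  # background median is clean and each blob can be checked directly
  traj <- dplyr::mutate(mini_traj(180), airborne = FALSE)
  up <- c(30, 70, 110, 150)
  traj$airborne[up] <- TRUE
  traj$x_m[up] <- c(18, 22, 26, 29)
  traj$y_m[up] <- c(3, 5, 7, 5)
  traj$z_m[up] <- c(1, 2, 3, 3.5)
  quiet <- render_noise(drift_amp = 0, gauss_sd = 0, salt_rate = 0)
  st <- render_frames(traj, cam, quiet, seed = 1)
  masks <- background_subtract(st, window = 151)
  det <- extract_detections(masks, st)
  gt <- ground_truth(traj, cam)
  expect_equal(nrow(det), nrow(gt))
  m <- dplyr::inner_join(det, gt, by = c("camera", "frame"))
  err <- sqrt((m$x_px.x - m$x_px.y)^2 + (m$y_px.x - m$y_px.y)^2)
  expect_lt(max(err), 0.5)
  expect_true(all(det$area_px >= 3 & det$area_px <= 500))
  # the mask support is exactly the rendered pixels above the threshold
  t1 <- up[2]
  expect_identical(masks$masks[, , t1],
                   st$frames[, , t1] > quiet$background_level)
})

test_that("detection extraction respects area bounds and empty input", {
  empty <- structure(list(masks = array(FALSE, c(10, 10, 3)),
                          camera = cam, fps = 30, start_frame = 0L),
                     class = "fg_masks")
  fake_stack <- structure(list(camera = cam,
                               frames = array(0L, c(10, 10, 3)),
                               fps = 30, start_frame = 0L),
                          class = "frame_stack")
  expect_equal(nrow(extract_detections(empty, fake_stack)), 0)
  # isolated single salt pixels fall below min_area = 2
  msk <- array(FALSE, c(10, 10, 1))
  msk[3, 3, 1] <- TRUE; msk[8, 8, 1] <- TRUE
  salty <- structure(list(masks = msk, camera = cam, fps = 30,
                          start_frame = 0L), class = "fg_masks")
  stk <- structure(list(camera = cam, frames = array(255L, c(10, 10, 1)),
                        fps = 30, start_frame = 0L), class = "frame_stack")
  expect_equal(nrow(extract_detections(salty, stk, min_area = 2)), 0)
  # the two singletons are found when min_area allows them
  expect_equal(nrow(extract_detections(salty, stk, min_area = 1)), 2)
})

test_that("neighbor filter matches the brute-force pairwise oracle", {
  # far-corner singleton at frame 9, isolated one at 10, continuous chain
  chain <- tibble::tibble(
    camera = 1L, frame = 20:40,
    x_px = 50 + (0:20) * 3, y_px = 60 + (0:20) * 2,
    area_px = 5L, peak_intensity = 100)
  det <- dplyr::bind_rows(
    tibble::tibble(camera = 1L, frame = 9L, x_px = 155, y_px = 115,
                   area_px = 4L, peak_intensity = 90),
    tibble::tibble(camera = 1L, frame = 10L, x_px = 5, y_px = 5,
                   area_px = 4L, peak_intensity = 90),
    chain)
  out <- neighbor_filter(det, radius_px = 30)
  expect_equal(out, brute_force_neighbor(det, 30), ignore_attr = TRUE)
  expect_setequal(out$frame, 20:40)  # chain kept, singletons removed

  # randomized equivalence with the oracle
  for (s in 1:5) {
    rnd <- withr::with_seed(s, tibble::tibble(
      camera = sample(1:2, 60, TRUE), frame = sample(1:12, 60, TRUE),
      x_px = runif(60, 0, 160), y_px = runif(60, 0, 120),
      area_px = 5L, peak_intensity = 100))
    expect_equal(neighbor_filter(rnd, 25), brute_force_neighbor(rnd, 25),
                 ignore_attr = TRUE)
  }
})

test_that("neighbor filter is a single pass over the original set", {
  # two identical coordinates in adjacent frames keep each other
  dup <- tibble::tibble(camera = 1L, frame = c(5L, 6L), x_px = 10,
                        y_px = 10, area_px = 4L, peak_intensity = 80)
  expect_equal(nrow(neighbor_filter(dup, 30)), 2)
  expect_equal(nrow(neighbor_filter(dup[0, ], 30)), 0)
  # output is always a subset of the input
  rnd <- withr::with_seed(7, tibble::tibble(
    camera = 1L, frame = sample(1:20, 80, TRUE),
    x_px = runif(80, 0, 160), y_px = runif(80, 0, 120),
    area_px = 5L, peak_intensity = 100))
  out1 <- neighbor_filter(rnd, 20)
  expect_true(nrow(dplyr::anti_join(
    out1, rnd, by = c("camera", "frame", "x_px", "y_px"))) == 0)
  # a second pass may remove more: the pipeline applies exactly one
  out2 <- neighbor_filter(out1, 20)
  expect_lte(nrow(out2), nrow(out1))
})
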