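cage <- cage_geometry()

test_that("pinhole projection maps axis points to the principal point", {
  cam <- camera_model(1, axis_center_m = 7.5, resolution = c(160L, 120L))
  # a point on the optical axis projects to the image center
  on_axis <- tibble::tibble(x_m = 7.5, y_m = 5, z_m = cam$height_m)
  pr <- project_points(on_axis, cam)
  expect_equal(pr$x_px, 80)
  expect_equal(pr$y_px, 60)
  expect_true(pr$in_view)
  # 1 m along the cage axis on the center line = focal_px / (standoff + W/2)
  off <- tibble::tibble(x_m = 8.5, y_m = 5, z_m = cam$height_m)
  expect_equal(project_points(off, cam)$x_px - 80,
               cam$focal_px / (cam$standoff_m + 5))
  # behind the camera plane is never in view
  behind <- tibble::tibble(x_m = 7.5, y_m = -30, z_m = 2)
  expect_false(project_points(behind, cam)$in_view)
})

test_that("camera bank covers the full cage axis with pairwise overlaps", {
  cams <- camera_bank(cage)
  covs <- t(vapply(cams, function(cm) cm$coverage, numeric(2)))
  expect_lte(covs[1, 1], 0)
  expect_gte(covs[4, 2], cage$length_m)
  for (i in 1:3) expect_gt(covs[i, 2], covs[i + 1, 1])  # overlap
  # every axis point covered; overlap zones by exactly two cameras
  x <- seq(0, cage$length_m, by = 0.1)
  n_cover <- rowSums(outer(x, covs[, 1], ">=") & outer(x, covs[, 2], "<="))
  expect_true(all(n_cover >= 1))
  expect_true(all(n_cover <= 2))
})

short_traj <- function(n = 40, seed = 5, period_s = 2) {
  rec <- trial_record("b1", "REDS", seed = seed, period_s = period_s)
  traj <- simulate_flight(rec, cage, deterrent_fields(repulsion_coeff = 0))
  traj[seq_len(n), ]
}

test_that("rendered stacks contain one blob per airborne in-view frame", {
  cam <- camera_model(2, 22.575, resolution = c(160L, 120L),
                      coverage = c(14.55, 30.6))
  traj <- short_traj(40)
  gt <- ground_truth(traj, cam)
  # noiseless render: the brightest pixel is the rounded projection
  quiet <- render_noise(drift_amp = 0, gauss_sd = 0, salt_rate = 0)
  st <- render_frames(traj, cam, quiet, seed = 1)
  for (t in which(traj$frame %in% gt$frame)[1:5]) {
    sl <- st$frames[, , t]
    ij <- arrayInd(which.max(sl), dim(sl))
    g <- gt[gt$frame == traj$frame[t], ]
    expect_equal(ij[1, 2] - 1, round(g$x_px))
    expect_equal(ij[1, 1] - 1, round(g$y_px))
  }
  # frame count identity: frames with a blob == airborne in-view frames
  has_blob <- vapply(seq_len(dim(st$frames)[3]), function(t) {
    max(st$frames[, , t]) > quiet$background_level + 5
  }, logical(1))
  expect_equal(sum(has_blob), nrow(gt))
  # zero blob amplitude leaves pure background statistics
  none <- render_frames(traj, cam,
                        render_noise(blob_amp = 0, salt_rate = 0), seed = 1)
  grounded <- dplyr::mutate(traj, airborne = FALSE)
  base <- render_frames(grounded, cam,
                        render_noise(salt_rate = 0), seed = 2)
  set.seed(99)  # dequantize the 8-bit values for a continuous KS test
  a <- sample(as.numeric(none$frames), 2e4) + runif(2e4, -0.5, 0.5)
  b <- sample(as.numeric(base$frames), 2e4) + runif(2e4, -0.5, 0.5)
  expect_gt(stats::ks.test(a, b)$p.value, 0.01)
})

test_that("the salt-noise stream is independent of blob rendering", {
  cam <- camera_model(2, 22.575, resolution = c(160L, 120L))
  traj <- short_traj(30)
  s1 <- render_frames(traj, cam, seed = 9, salt_seed = 1)
  s2 <- render_frames(traj, cam, seed = 9, salt_seed = 2)
  # identical except at the (few) salt pixels
  d <- s1$frames != s2$frames
  expect_lt(mean(d), 1e-3)
  expect_true(all(pmax(s1$frames[d], s2$frames[d]) == 255L))
  # determinism under a full fixed seed
  expect_identical(render_frames(traj, cam, seed = 9),
                   render_frames(traj, cam, seed = 9))
})

test_that("frame stacks round-trip through multi-page TIFF", {
  cam <- camera_model(3, 37.625, resolution = c(80L, 60L))
  traj <- short_traj(12)
  st <- render_frames(traj, cam, seed = 2)
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame_stack(st, path)
  rt <- read_frame_stack(path)
  expect_identical(rt$frames, st$frames)
  expect_equal(rt$start_frame, st$start_frame)
  expect_equal(rt$camera$axis_center_m, cam$axis_center_m)
  expect_equal(rt$camera$coverage, cam$coverage)
})

test_that("ground truth has at most one detection per camera-frame", {
  cam <- camera_model(1, 7.525, resolution = c(160L, 120L))
  traj <- short_traj(100)
  gt <- ground_truth(traj, cam)
  expect_false(any(duplicated(gt$frame)))
  expect_true(all(gt$x_px >= 0 & gt$x_px < 160))
})
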