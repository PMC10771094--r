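test_that("schedules satisfy the seven-period randomized design", {
  for (seed in c(0, 1, 99)) {
    s <- make_schedule(seed)
    expect_equal(nrow(s), 7)
    expect_equal(s$label[c(1, 2, 4, 6)],
                 c("acclimation", "control1", "control2", "control3"))
    expect_setequal(s$label[c(3, 5, 7)], c("combined", "high", "low"))
    expect_true(all(s$end_frame - s$start_frame == 7200))
    expect_equal(s$start_frame[-1], s$end_frame[-7])  # contiguous
    expect_identical(make_schedule(seed)$label, s$label)  # deterministic
  }
  expect_equal(max(make_schedule(5)$end_frame), 7 * 7200)
})

test_that("treatment permutations are uniform over seeds", {
  perms <- vapply(1:6000, function(s) {
    paste(make_schedule(s)$label[c(3, 5, 7)], collapse = "-")
  }, "")
  counts <- table(perms)
  expect_equal(length(counts), 6)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("received level follows spreading plus absorption from 125 dB at 1 m", {
  f <- deterrent_field("combined")
  expect_equal(deterrent_intensity(1, f, 26), 125)
  # strictly decreasing in distance for every treatment
  for (trt in c("combined", "high", "low")) {
    fld <- deterrent_field(trt)
    for (fr in fld$subarray_freqs_khz) {
      lv <- deterrent_intensity(c(1, 2, 5, 10, 30), fld, fr)
      expect_true(all(diff(lv) < 0))
    }
  }
  # zero absorption leaves pure spherical spreading
  f0 <- deterrent_field("low", atten_db_per_m = c(`20` = 0, `26` = 0, `32` = 0))
  expect_equal(deterrent_intensity(10, f0, 20), 105)
  expect_error(deterrent_intensity(5, deterrent_field("low"), 44),
               class = "batcage_invalid_freq")
  expect_error(deterrent_intensity(0.5, f, 20))
})

test_that("flights are deterministic, in-cage, and respect landings", {
  cage <- cage_geometry()
  rec <- trial_record("b1", "REDS", seed = 11, period_s = 8)
  fields <- deterrent_fields(repulsion_coeff = 60)
  mv <- movement_params(landing_rate_per_min = 3, landing_duration_s = 2)
  t1 <- simulate_flight(rec, cage, fields, mv)
  t2 <- simulate_flight(rec, cage, fields, mv)
  expect_identical(t1, t2)
  air <- dplyr::filter(t1, airborne)
  expect_true(all(air$x_m >= 0 & air$x_m <= cage$length_m))
  expect_true(all(air$y_m >= 0 & air$y_m <= cage$width_m))
  expect_true(all(air$z_m >= 0 & air$z_m <= cage$height_m))
  expect_gt(sum(!t1$airborne), 0)
  # landed frames do not advance position
  frozen <- which(!t1$airborne[-1] & !t1$airborne[-nrow(t1)])
  expect_equal(t1$x_m[frozen + 1], t1$x_m[frozen])
  expect_error(
    simulate_flight(rec, cage, fields, movement_params(speed_mean_mps = NaN)),
    class = "batcage_validation_error")
})

test_that("zero repulsion produces no treatment-control displacement", {
  fields0 <- deterrent_fields(repulsion_coeff = 0)
  diffs <- vapply(1:50, function(i) {
    rec <- trial_record(paste0("b", i), "REDS", seed = 1000 + i,
                        period_s = 30)
    tr <- track_from_trajectory(simulate_flight(rec, fields = fields0))
    med <- tapply(tr$distance_m, tr$period_label %in%
                    c("combined", "high", "low"), median)
    med[["TRUE"]] - med[["FALSE"]]
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2)  # Monte-Carlo error around a true 0
})

test_that("strong repulsion empties the deterrent half of the cage", {
  cage <- cage_geometry()
  strong <- deterrent_field("combined", repulsion_coeff = 2000)
  # long-run oracle occupancy under the same dynamics
  lr <- longrun_quantiles(strong, taus = 0.05, n_steps = 2e5, seed = 3)
  expect_gt(lr, cage$length_m / 2)
  rec <- trial_record("b1", "REDS", seed = 21)
  traj <- simulate_flight(rec, cage,
                          fields = deterrent_fields(repulsion_coeff = 2000))
  trt <- dplyr::filter(traj, treatment == "combined")
  expect_lt(mean(trt$x_m < cage$length_m / 2), 0.05)
})

test_that("trial manifests mirror the study demographics", {
  man <- simulate_trials(200, seed = 4)
  expect_equal(nrow(man), 200)
  expect_true(all(man$species_code %in%
                    c("REDS", "MYVE", "TABR", "NYHU", "PESU")))
  expect_false(any(duplicated(man$bat_id)))
  expect_identical(simulate_trials(200, seed = 4), man)
  # restricted draw honors the requested species
  reds <- simulate_trials(46, seed = 5, species = "REDS")
  expect_true(all(reds$species_code == "REDS"))
  # cave myotis have no spring females to sample
  myve <- simulate_trials(300, seed = 6, species = "MYVE")
  expect_equal(sum(myve$sex == "F" & myve$season == "spring"), 0)
})
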