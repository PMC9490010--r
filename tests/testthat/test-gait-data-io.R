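# Trial containers, bundle round-trips and gait-cycle resampling.

test_that("gait_trial validates its invariants", {
  tr <- toy_trial()
  expect_s3_class(tr, "gait_trial")
  expect_length(tr$time, 121)
  expect_identical(cycle_frames(tr), 21L + 0:100)
  expect_equal(percent_cycle(tr)[21], 0)
  expect_equal(percent_cycle(tr)[121], 100)
  expect_equal(percent_cycle(tr)[1], -20)

  bad_time <- tr$time
  bad_time[5] <- bad_time[7]
  expect_error(gait_trial("x", "s", "l", bad_time, tr$excitations,
                          tr$joint_angles, tr$joint_velocities,
                          tr$id_moments, 1.2),
               "strictly increasing")
  expect_error(gait_trial("x", "s", "l", tr$time[-1], tr$excitations,
                          tr$joint_angles, tr$joint_velocities,
                          tr$id_moments, 1.2),
               "frames")
  exc2 <- tr$excitations
  colnames(exc2) <- rep("dup", ncol(exc2))
  expect_error(gait_trial("x", "s", "l", tr$time, exc2, tr$joint_angles,
                          tr$joint_velocities, tr$id_moments, 1.2),
               "unique")
})

test_that("gait_dataset enforces shared ordering and known unmeasured", {
  trs <- list(toy_trial("a"), toy_trial("b"))
  ds <- gait_dataset(trs, unmeasured_muscles = "mus1")
  expect_setequal(ds$measured_muscles, c("mus2", "mus3"))
  expect_error(gait_dataset(trs, unmeasured_muscles = "nope"), "unknown")
  expect_error(gait_dataset(list(toy_trial("a"), toy_trial("a"))),
               "unique")
})

test_that("trial bundles round-trip through CSV and STO identically", {
  tr <- toy_trial()
  for (dialect in c("csv", "sto_mot")) {
    dir <- withr::local_tempdir()
    write_trial_bundle(tr, dir, dialect)
    back <- read_trial_bundle(dir)
    expect_equal(back$time, tr$time, tolerance = 1e-10)
    expect_equal(back$excitations, tr$excitations, tolerance = 1e-10)
    expect_equal(back$id_moments, tr$id_moments, tolerance = 1e-10)
    expect_identical(back$speed_label, tr$speed_label)
    expect_identical(back$cycle_duration, tr$cycle_duration)
  }
  # cross-dialect agreement
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_trial_bundle(tr, d1, "csv")
  write_trial_bundle(tr, d2, "sto_mot")
  a <- read_trial_bundle(d1); b <- read_trial_bundle(d2)
  expect_equal(a$excitations, b$excitations, tolerance = 1e-10)
  expect_equal(a$joint_angles, b$joint_angles, tolerance = 1e-10)
})

test_that("bundle reader reports missing tables and bad time", {
  tr <- toy_trial()
  dir <- withr::local_tempdir()
  write_trial_bundle(tr, dir, "csv")
  file.remove(file.path(dir, "id_moments.csv"))
  expect_error(read_trial_bundle(dir), "id moments")
  # non-monotone time
  dir2 <- withr::local_tempdir()
  write_trial_bundle(tr, dir2, "csv")
  tab <- utils::read.csv(file.path(dir2, "excitations.csv"))
  tab$time[3] <- tab$time[10]
  utils::write.csv(tab, file.path(dir2, "excitations.csv"),
                   row.names = FALSE)
  expect_error(read_trial_bundle(dir2), "non-monotone")
})

test_that("an empty muscle list cannot be written", {
  tr <- toy_trial()
  tr$excitations <- tr$excitations[, 0, drop = FALSE]
  expect_error(write_trial_bundle(tr, withr::local_tempdir(), "csv"),
               "empty muscle list")
})

test_that("STO fixture parses to its analytic contents", {
  path <- system.file("extdata", "example_trial.sto", package = "synx")
  dat <- read_sto(path)
  expect_identical(dim(dat), c(121L, 7L))
  expect_identical(names(dat)[1], "time")
  t <- seq(0, 1.2, length.out = 121)
  for (j in 1:6)
    expect_equal(dat[[paste0("chan", j)]],
                 round(sin(2 * pi * t / 1.2 + j / 3) * j / 10, 8),
                 tolerance = 1e-7)
})

test_that("dataset directories round-trip", {
  syn <- cached_synthetic(seed = 11, n_trials_per_speed = 1L)
  ds <- holdout_muscles(syn)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir, "csv")
  back <- read_dataset(dir)
  expect_identical(names(back$trials), names(ds$trials))
  expect_identical(back$unmeasured_muscles, ds$unmeasured_muscles)
  expect_equal(back$trials[[1]]$excitations, ds$trials[[1]]$excitations,
               tolerance = 1e-10)
})

test_that("resampling lands on the 121-frame grid with exact endpoints", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  const <- matrix(2.5, length(t), 1)
  out <- resample_to_cycle(t, const, c(1.0, 2.2))
  expect_identical(nrow(out), 121L)
  expect_true(all(abs(out - 2.5) < 1e-12))

  ramp <- matrix(3 * t - 1, ncol = 1)
  out <- resample_to_cycle(t, ramp, c(1.0, 2.2))
  expect_equal(out[21, 1], 3 * 1.0 - 1, tolerance = 1e-12)
  expect_equal(out[121, 1], 3 * 2.2 - 1, tolerance = 1e-12)

  sine <- matrix(sin(2 * pi * 3 * t), ncol = 1)
  out <- resample_to_cycle(t, sine, c(1.0, 2.2))
  grid <- attr(out, "time")
  expect_lt(max(abs(out[, 1] - sin(2 * pi * 3 * grid))), 1e-3)
})

test_that("resampling is idempotent on the target grid and guards the pre-window", {
  t <- seq(-0.5, 1.5, by = 0.001)
  x <- matrix(cos(3 * t), ncol = 1)
  once <- resample_to_cycle(t, x, c(0, 1))
  twice <- resample_to_cycle(attr(once, "time"), once, c(0, 1))
  expect_equal(unclass(once), unclass(twice), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(resample_to_cycle(seq(0, 2, 0.001),
                                 matrix(1, 2001, 1), c(0.05, 1.0)),
               "insufficient pre-window")
})
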