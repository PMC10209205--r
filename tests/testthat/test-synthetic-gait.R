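test_that("vertical GRF has the contracted stance impulse and onset", {
  sim <- noisy_sim()
  cfg <- sim$truth$config
  ins <- sim$insole
  fs <- cfg$sample_rate_insole
  bw <- cfg$body_mass * cfg$gravity
  stance <- 0.6 * cfg$stride_time
  rhs <- sim$truth$rhs_times
  for (k in c(5, 20, 40)) {
    sel <- ins$time >= rhs[k] & ins$time < rhs[k + 1]
    impulse <- sum(ins$vgrf_right[sel]) / fs
    expect_lt(abs(impulse / (bw * stance) - 1), 0.02)
  }
  # force crosses 30 N within one insole sample of the true heel strike
  crossings <- detect_heel_strikes_force(sim$insole)
  t_cross <- ins$time[crossings]
  walking <- t_cross >= sim$truth$rhs_times[1] - 0.05
  for (tk in rhs[2:10]) {
    expect_lte(min(abs(t_cross[walking] - tk)), 1 / fs + 1e-9)
  }
})

test_that("zero gains and zero noise give perfectly regular stepping", {
  cfg <- sim_config(n_strides = 30, stepping_gains = matrix(0, 2, 9),
                    fp_noise_sd = 0, compensation_noise_sd = 0, seed = 11)
  sim <- simulate_walker(cfg)
  expect_true(all(sim$truth$strides$fp_dev_ap == 0))
  expect_true(all(sim$truth$strides$fp_dev_ml == 0))
  feats <- gait_features(sim$kin, clock_offset = 0)
  expect_lt(diff(range(feats$step_width)), 1e-9)
  expect_lt(diff(range(feats$stride_length)), 1e-9)
})

test_that("noiseless generator is exactly recovered by the stepping fit", {
  feats <- noiseless_features()
  truth <- noiseless_sim()$truth
  for (dir in c("ap", "ml")) {
    fit <- fit_stepping(feats, dir)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_equal(unname(fit$gains),
                 unname(truth$stepping_gains[dir, ]), tolerance = 1e-6)
  }
})

test_that("ground-truth table has one row per stride and matches the pipeline", {
  sim <- noisy_sim()
  expect_identical(nrow(sim$truth$strides), sim$truth$config$n_strides)
  feats <- noisy_features()
  expect_identical(nrow(feats), sim$truth$config$n_strides)
  tr <- sim$truth$strides
  for (nm in state_names()) {
    expect_equal(feats[[nm]] - mean(feats[[nm]]),
                 tr[[nm]] - mean(tr[[nm]]), tolerance = 1e-9)
  }
  expect_equal(feats$fp_ml - mean(feats$fp_ml),
               tr$fp_dev_ml - mean(tr$fp_dev_ml), tolerance = 1e-9)
})

test_that("configured forward-MoS offset shifts the measured mean exactly", {
  base <- sim_config(n_strides = 40, seed = 55)
  shifted <- sim_config(n_strides = 40, seed = 55, fw_mos_offset = 0.05)
  f0 <- gait_features(simulate_walker(base)$kin, clock_offset = 0)
  f1 <- gait_features(simulate_walker(shifted)$kin, clock_offset = 0)
  expect_equal(mean(f1$fw_mos) - mean(f0$fw_mos), 0.05, tolerance = 1e-3)
})

test_that("measured leg length recovers the configured value within 3%", {
  feats <- noisy_features()
  L <- sim_config()$leg_length
  expect_lt(abs(mean(feats$leg_length) - L) / L, 0.03)
})

test_that("fixture suite writes the four named fixture pairs", {
  dir <- withr::local_tempdir()
  paths <- make_fixture_suite(dir, n_strides = 35, seed = 3)
  expect_gte(length(paths), 4)
  for (nm in c("noiseless", "noisy", "zerogain", "offset_clock")) {
    expect_true(all(file.exists(paths[[nm]])))
  }
  # the noiseless fixture propagates to a perfect stepping fit after a
  # round trip through the CSV files
  rec <- read_gait_recordings(dir, "noiseless")
  feats <- gait_features(rec$kin, rec$insole, clock_offset = 0)
  expect_equal(fit_stepping(feats, "ap")$r_squared, 1, tolerance = 1e-9)
  # the offset-clock fixture stores its offset and synchronization
  # recovers it within one insole sample
  rec2 <- read_gait_recordings(dir, "offset_clock")
  expect_equal(rec2$truth$clock_offset, 0.37)
  est <- synchronize_jumps(rec2$kin, rec2$insole)
  expect_lt(abs(est - 0.37), 0.01)
})

test_that("fixture writing fails on an unwritable path", {
  expect_error(write_gait_sim(simulate_walker(sim_config(n_strides = 2)),
                              "/proc/definitely/not/writable", "x"))
})
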