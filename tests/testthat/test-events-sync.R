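test_that("force heel strikes follow the 30 N upward-crossing rule", {
  expect_identical(
    detect_heel_strikes_force(c(0, 0, 10, 40, 300, 500), sample_rate = 100),
    4L)
  expect_identical(detect_heel_strikes_force(rep(0, 200), sample_rate = 100),
                   integer())
  # square wave: one event per period, at each rising edge, matching a
  # brute-force scan of all upward crossings
  f <- rep(c(rep(0, 50), rep(500, 50)), 5)
  ev <- detect_heel_strikes_force(f, sample_rate = 100)
  expect_identical(ev, as.integer(brute_crossings(f, 30)))
  expect_identical(length(ev), 5L)
  expect_error(detect_heel_strikes_force(c(0, 10, 40), threshold = -5,
                                         sample_rate = 100), "positive")
  expect_error(detect_heel_strikes_force(c(0, -10, 40), sample_rate = 100),
               "non-negative")
})

test_that("threshold chatter within the refractory window is rejected", {
  # bounces around 30 N within 0.2 s produce a single contact event
  f <- c(rep(0, 100), 35, 20, 40, 25, rep(500, 60), rep(0, 100))
  ev <- detect_heel_strikes_force(f, sample_rate = 100)
  expect_identical(ev, 101L)
})

test_that("kinematic events match the generator's times exactly", {
  sim <- noisy_sim()
  ev <- detect_events_kinematic(sim$kin)
  fs <- 120
  expect_identical(ev$rhs, as.integer(round(sim$truth$rhs_times * fs)) + 1L)
  expect_identical(ev$lhs, as.integer(round(sim$truth$lhs_times * fs)) + 1L)
  # toe-offs within one sample of truth (the last ground-plateau sample)
  n <- length(sim$truth$rto_times)
  walking_rto <- tail(ev$rto, n)
  expect_lte(max(abs(walking_rto -
                       (round(sim$truth$rto_times * fs) + 1))), 1)
  # event counts per foot differ by at most one
  expect_lte(abs(length(ev$rhs) - length(ev$lhs)), 1)
})

test_that("degenerate kinematics raise explanatory errors", {
  expect_error(detect_events_kinematic(standing_recording()),
               "constant|no gait|displacement")
})

test_that("invalid event trains fail the ordering invariants", {
  sim <- noisy_sim()
  ev <- detect_events_kinematic(sim$kin)
  # non-increasing heel strikes
  bad1 <- ev
  bad1$rhs[2] <- bad1$rhs[4]
  expect_error(segment_strides(sim$kin, bad1), "increasing")
  # a second right toe-off inside one stride
  bad2 <- ev
  bad2$rto <- sort(c(bad2$rto, bad2$rhs[3] - 5L))
  expect_error(segment_strides(sim$kin, bad2), "toe-off")
})

test_that("force- and kinematics-derived heel strikes agree after sync", {
  sim <- cached("offset_sim", simulate_walker(
    sim_config(n_strides = 20, seed = 104, clock_offset = 0.2)))
  off <- synchronize_jumps(sim$kin, sim$insole)
  ev <- detect_events_kinematic(sim$kin)
  t_kin_hs <- sim$kin$time[ev$rhs]
  fev <- detect_heel_strikes_force(sim$insole)
  t_force_hs <- sim$insole$time[fev] - off
  for (tk in t_kin_hs) {
    expect_lte(min(abs(t_force_hs - tk)), 0.01 + 1e-9)
  }
})

test_that("jump synchronization recovers configured clock offsets", {
  for (true_off in c(0, 0.37)) {
    sim <- simulate_walker(sim_config(n_strides = 6, seed = 7,
                                      clock_offset = true_off))
    expect_lt(abs(synchronize_jumps(sim$kin, sim$insole) - true_off), 0.01)
  }
  # insole stream without any flight phase -> explanatory error
  sim <- simulate_walker(sim_config(n_strides = 6, seed = 7))
  ins <- tibble::as_tibble(sim$insole)
  flat <- ins
  flat$vgrf_right <- pmax(flat$vgrf_right, 100)
  flat <- insole_recording(flat, 100)
  expect_error(synchronize_jumps(sim$kin, flat), "no jump")
})

test_that("downsampling preserves low-frequency content and duration", {
  fs <- 240
  t <- (0:(fs * 10)) / fs
  df <- tibble::tibble(time = t)
  for (ch in gaitstab:::kin_channel_names()) df[[ch]] <- 0
  df$com_x <- sin(2 * pi * 2 * t)
  k240 <- kin_recording(df, fs)
  k120 <- downsample_kinematics(k240, 120)
  expect_equal(attr(k120, "sample_rate"), 120)
  expect_lte(abs(max(k120$time) - max(t)), 1 / 120)
  mid <- 100:1100 # away from filter edge effects
  err <- k120$com_x[mid] - sin(2 * pi * 2 * k120$time[mid])
  expect_lt(sqrt(mean(err^2)) / sqrt(0.5), 0.01)
  # identity and argument errors
  expect_identical(downsample_kinematics(k240, 240), k240)
  expect_error(downsample_kinematics(k240, 0), "positive")
  expect_error(downsample_kinematics(k240, 480), "exceeds")
})
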