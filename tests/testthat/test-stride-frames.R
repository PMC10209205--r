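rotate_world <- function(kin, theta) {
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2,
              byrow = TRUE)
  df <- tibble::as_tibble(kin)
  for (lm in gaitstab:::kin_landmarks) {
    x <- df[[paste0(lm, "_x")]]
    y <- df[[paste0(lm, "_y")]]
    df[[paste0(lm, "_x")]] <- R[1, 1] * x + R[1, 2] * y
    df[[paste0(lm, "_y")]] <- R[2, 1] * x + R[2, 2] * y
  }
  kin_recording(df, attr(kin, "sample_rate"),
                walk_start = attr(kin, "walk_start"))
}

test_that("segmentation is a fencepost over right heel strikes", {
  sim <- noisy_sim()
  ev <- detect_events_kinematic(sim$kin)
  sl <- segment_strides(sim$kin, ev, sim$insole, clock_offset = 0)
  expect_identical(length(sl), length(ev$rhs) - 1L)
  expect_identical(length(sl), sim$truth$config$n_strides)
  # out-of-order events are rejected
  bad <- ev
  bad$rhs <- rev(bad$rhs)
  expect_error(segment_strides(sim$kin, bad), "increasing")
})

test_that("stride frames are equivariant under world rotation", {
  sim <- noisy_sim()
  kin2 <- rotate_world(sim$kin, 73 * pi / 180)
  sl1 <- segment_strides(sim$kin, detect_events_kinematic(sim$kin))
  sl2 <- segment_strides(kin2, detect_events_kinematic(kin2))
  a <- transform_stride(sl1[[4]])$kin
  b <- transform_stride(sl2[[4]])$kin
  for (ch in c("com_x", "com_y", "rheel_x", "rheel_y", "lheel_y")) {
    expect_equal(a[[ch]], b[[ch]], tolerance = 1e-9)
  }
  # walking along -X flips the AP axis so progression stays positive
  kin3 <- rotate_world(sim$kin, pi)
  sl3 <- segment_strides(kin3, detect_events_kinematic(kin3))
  c3 <- transform_stride(sl3[[4]])$kin
  expect_equal(c3$com_x, a$com_x, tolerance = 1e-9)
  expect_gt(mean(diff(c3$sacrum_x)), 0)
})

test_that("frame transform round-trips to global coordinates", {
  sim <- noisy_sim()
  sl <- segment_strides(sim$kin, detect_events_kinematic(sim$kin))
  s <- transform_stride(sl[[2]])
  fr <- s$frame
  back <- t(fr$rotation) %*% rbind(s$kin$com_x, s$kin$com_y, s$kin$com_z)
  expect_equal(back[1, ] + fr$origin[1], sl[[2]]$kin$com_x,
               tolerance = 1e-12)
  expect_equal(back[2, ] + fr$origin[2], sl[[2]]$kin$com_y,
               tolerance = 1e-12)
})

test_that("standing slices cannot define a stride frame", {
  kin <- standing_recording()
  slice <- list(kin = tibble::as_tibble(kin), start_index = 1L,
                end_index = nrow(kin), events = list(), stride = 1L)
  class(slice) <- "stride_slice"
  expect_error(build_stride_frame(slice), "displacement")
})

test_that("percent-gait resampling is faithful and idempotent", {
  sim <- noisy_sim()
  sl <- segment_strides(sim$kin, detect_events_kinematic(sim$kin),
                        sim$insole, clock_offset = 0)
  s <- transform_stride(sl[[3]])
  st <- normalize_percent_gait(s, n_points = 101L)
  expect_identical(nrow(st), 101L)
  # boundary samples preserved exactly
  expect_identical(st$com_x[1], s$kin$com_x[1])
  expect_identical(st$com_x[101], s$kin$com_x[nrow(s$kin)])
  # a linear ramp resamples onto its percent coordinate
  s2 <- s
  s2$kin$com_x <- seq(0, 1, length.out = nrow(s$kin))
  r <- normalize_percent_gait(s2, 101L)
  expect_equal(r$com_x, seq(0, 1, length.out = 101), tolerance = 1e-12)
  # a sine channel is reproduced within 1e-3 of its amplitude
  tt <- s$kin$time
  s3 <- s
  s3$kin$com_y <- sin(2 * pi * 3 * (tt - tt[1]))
  r3 <- normalize_percent_gait(s3, 101L)
  tq <- seq(tt[1], tt[length(tt)], length.out = 101)
  expect_lt(max(abs(r3$com_y - sin(2 * pi * 3 * (tq - tt[1])))), 1e-3)
  # events become percent phases inside (0, 100)
  ph <- attr(st, "events_pct")
  expect_true(ph$rto > 0 && ph$rto < 100)
  expect_error(normalize_percent_gait(s, 1L), "n_points")
})

test_that("resampling commutes with the frame transform", {
  sim <- noisy_sim()
  sl <- segment_strides(sim$kin, detect_events_kinematic(sim$kin))
  a <- normalize_percent_gait(transform_stride(sl[[5]]), 101L)
  raw <- normalize_percent_gait(sl[[5]], 101L)
  fr <- build_stride_frame(sl[[5]])
  b <- gaitstab:::transform_landmarks(raw, fr)
  for (ch in c("com_x", "com_y", "rheel_x", "lheel_y")) {
    expect_equal(a[[ch]], b[[ch]], tolerance = 1e-9)
  }
})

test_that("leg length follows the stance-phase foot-to-CoM distance", {
  # CoM held 0.9 m directly above a stationary foot marker
  fs <- 120
  t <- seq(0, 1, by = 1 / fs)
  df <- tibble::tibble(time = t)
  for (ch in gaitstab:::kin_channel_names()) df[[ch]] <- 0
  df$com_z <- 0.9
  slice <- list(kin = df, start_index = 1L, end_index = nrow(df),
                events = list(rto = nrow(df)), stride = 1L)
  class(slice) <- "stride_slice"
  expect_equal(compute_leg_length(slice), 0.9, tolerance = 1e-12)
  # degenerate stride
  slice$kin <- df[1, ]
  expect_error(compute_leg_length(slice), "degenerate")
})
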