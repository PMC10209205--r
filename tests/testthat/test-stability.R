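test_that("XCoM follows the inverted-pendulum extrapolation", {
  expect_identical(compute_xcom(1.2, 0, L = 0.9), 1.2)
  # direct evaluation of the definition at the study's scale constants
  expect_equal(compute_xcom(1.0, 0.5, L = 0.91, g = 9.806),
               1.0 + 0.5 * sqrt(0.91 / 9.806), tolerance = 1e-12)
  expect_equal(compute_xcom(1.0, 0.5, L = 0.91, g = 9.806), 1.152316,
               tolerance = 1e-6)
  # linearity: doubling position and velocity doubles the XCoM
  expect_equal(compute_xcom(2.0, 1.0, L = 0.91, g = 9.806),
               2 * compute_xcom(1.0, 0.5, L = 0.91, g = 9.806),
               tolerance = 1e-12)
  expect_error(compute_xcom(1, 1, L = -1), "positive")
  expect_error(compute_xcom(1, 1, L = 1, g = 0), "positive")
  # whole-trajectory identity with zeroed velocities
  x <- rnorm(500)
  expect_identical(compute_xcom(x, numeric(500), L = 0.91), x)
})

fake_ap_slice <- function(ant_heel, post_met5, com, com_vel, L = 0.91,
                          g = 9.806) {
  fs <- 120
  t <- seq(0, 1, by = 1 / fs)
  df <- tibble::tibble(time = t)
  for (ch in gaitstab:::kin_channel_names()) df[[ch]] <- 0
  df$rheel_x <- ant_heel
  df$lheel_x <- post_met5 - 0.16
  df$lmet5_x <- post_met5
  df$com_x <- com + com_vel * (t - t[length(t)])
  df$com_z <- sqrt(max(L^2 - 0.01, 0.5))
  slice <- list(kin = df, start_index = 1L, end_index = nrow(df),
                events = list(rto = nrow(df)), stride = 1L)
  class(slice) <- "stride_slice"
  slice
}

test_that("AP margins reproduce direct arithmetic and their identity", {
  # anterior heel 1.2 m, posterior fifth metatarsal 0.55 m, XCoM 1.33 m
  L <- 0.91
  g <- 9.806
  vel <- 0.4
  com <- 1.33 - vel * sqrt(L / g)
  slice <- fake_ap_slice(1.2, 0.55, com, vel, L)
  mos <- compute_ap_mos(slice, L = L, g = g)
  expect_equal(mos$fw_mos, 1.2 - 1.33, tolerance = 1e-6)
  expect_equal(mos$bw_mos, 1.33 - 0.55, tolerance = 1e-6)
  expect_equal(mos$fw_mos + mos$bw_mos, mos$bos_extent, tolerance = 1e-12)
  # XCoM exactly at the anterior heel -> zero forward margin
  com0 <- 1.2 - vel * sqrt(L / g)
  mos0 <- compute_ap_mos(fake_ap_slice(1.2, 0.55, com0, vel, L),
                         L = L, g = g)
  expect_equal(mos0$fw_mos, 0, tolerance = 1e-6)
})

test_that("fw + bw equals the AP base-of-support extent on every stride", {
  feats <- noisy_features()
  expect_lt(max(abs(feats$fw_mos + feats$bw_mos - feats$bos_extent)),
            1e-12)
})

test_that("ML margin uses signed distance with medial positive", {
  sim <- noisy_sim()
  ev <- detect_events_kinematic(sim$kin)
  sl <- segment_strides(sim$kin, ev)
  s <- transform_stride(sl[[4]])
  # constant-offset construction: XCoM trace 3 cm medial to the marker
  s2 <- s
  s2$kin$com_y <- s2$kin$rmet5_y + 0.03
  ml <- compute_ml_mos(s2, L = 0.91,
                       com_vel_ml = numeric(nrow(s2$kin)))
  expect_equal(ml, 0.03, tolerance = 1e-12)
  # a lateral crossing at one sample makes the minimum negative
  s3 <- s2
  mid <- round(nrow(s3$kin) * 0.3)
  s3$kin$com_y[mid] <- s3$kin$rmet5_y[mid] - 0.01
  expect_lt(compute_ml_mos(s3, L = 0.91,
                           com_vel_ml = numeric(nrow(s3$kin))), 0)
  # no single-stance window -> NA with warning
  s4 <- s
  s4$events$lto <- integer()
  expect_warning(out <- compute_ml_mos(s4), "single-stance")
  expect_true(is.na(out))
})

test_that("ML margin of the sinusoidal walker matches its closed form", {
  # quiet walker (no state perturbations): com_y = -a_y sin(2 pi phi);
  # the minimum signed distance over right single stance follows from the
  # analytic XCoM of that sinusoid
  cfg <- sim_config(n_strides = 12, fp_noise_sd = 0,
                    compensation_noise_sd = 0,
                    com_state_cov = matrix(0, 9, 9), seed = 9)
  sim <- simulate_walker(cfg)
  feats <- gait_features(sim$kin, clock_offset = 0)
  a_y <- 0.020
  Tt <- cfg$stride_time
  L <- feats$leg_length[10]
  tau <- sqrt(L / cfg$gravity)
  ev_lto <- 0.1
  ev_lhs <- 0.5
  phi <- seq(ev_lto, ev_lhs, by = 1 / (120 * Tt))
  y <- -a_y * sin(2 * pi * phi)
  vy <- -a_y * 2 * pi / Tt * cos(2 * pi * phi)
  xcom <- y + tau * vy
  marker <- -cfg$step_width / 2 - 0.03
  closed_form <- min(xcom - marker)
  expect_equal(feats$ml_mos[10], closed_form, tolerance = 1e-3)
})

test_that("nondimensional margins equal raw margins divided by L", {
  feats <- noisy_features()
  scales <- nondim_scales(mean(feats$leg_length))
  nf <- nondimensionalize_features(feats, scales)
  expect_equal(nf$fw_mos, feats$fw_mos / scales$L, tolerance = 1e-12)
  expect_equal(nf$ml_mos, feats$ml_mos / scales$L, tolerance = 1e-12)
})
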