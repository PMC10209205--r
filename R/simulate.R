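#' Simulate an instrumented outdoor walking trial
#'
#' Generates a kinematic recording, an insole recording and a ground-truth
#' table for a walker whose foot placement is governed by a known linear
#' controller on the midstance CoM state. The trial starts with
#' synchronization jumps (simultaneous flight phases in the force and
#' vertical-acceleration signals), followed by `n_strides` complete strides
#' delineated by right heel strikes.
#'
#' The continuous CoM trajectory is a constant-speed AP ramp with sinusoidal
#' ML sway at step frequency and a double-bump vertical oscillation;
#' per-stride CoM-state perturbations are injected as smooth compactly
#' supported bumps centred on the midstance instant. Foot placements follow
#' a recursion `fp_k = B * (midstance state deviation) + noise`, with the
#' midstance state measured exactly as the analysis pipeline measures it
#' (central differences on the sampled 120 Hz signals, stride-frame origin
#' at the previous right heel strike), so that the downstream regressions
#' have exactly recoverable gains in the noiseless cases. Vertical GRFs are
#' two-peaked stance profiles whose stance-average equals body weight, and
#' the insole clock can carry a configurable offset for synchronization
#' testing.
#'
#' @param config A [sim_config()].
#' @return A list of class `gait_sim` with elements `kin`
#'   ([kin_recording()]), `insole` ([insole_recording()]) and `truth`
#'   (a `gait_truth` list: per-stride tibble plus the gain matrices, event
#'   times and clock offset actually used).
#' @export
#' @examples
#' sim <- simulate_walker(sim_config(n_strides = 8, seed = 7))
#' sim$truth$strides
simulate_walker <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("config must be a sim_config object")
  }
  withr::with_seed(config$seed, simulate_walker_impl(config))
}

# Geometry constants of the emulated body (m). The foot is rigid: the
# metatarsal markers translate with the heel.
.geom <- list(
  met5 = c(0.16, -0.03, 0),   # lateral forefoot edge (right foot sign)
  met1 = c(0.18, +0.02, 0),   # medial forefoot edge (right foot sign)
  stance_frac = 0.6,          # per-foot stance fraction of the stride
  swing_height = 0.06,        # swing foot clearance
  backslide = 0.003,          # small heel retreat during stance
  a_x = 0.012,                # AP CoM oscillation amplitude (2 / stride)
  a_y = 0.020,                # ML CoM sway amplitude (1 / stride)
  a_z = 0.012,                # VT CoM oscillation amplitude (2 / stride)
  a_w = 8,                    # trunk angular velocity amplitude, deg/s
  trunk_omega_base = 0,       # baseline about which trunk offsets act
  cop_base_frac = 0.5,        # CoP sits under the foot centreline
  fw_mos_base = -0.12,        # default mean FW MoS before fw_mos_offset
  midstance_frac = 0.8,       # midstance instant as a stride phase
  bump_halfwidth = 0.17,      # CoM-state bump half-support, stride units
  bump_plateau = 0.3,         # fraction of the support at full amplitude
  jump_flight = 0.30,         # jump flight time, s
  jump_spike_dur = 0.12,      # landing force transient duration, s
  jump_spike_amp = 1.3        # landing transient amplitude, body weights
)

# C1 window: 1 on |u| <= p, cosine-squared taper to 0 at |u| = 1.
bump_window <- function(u, p = .geom$bump_plateau) {
  au <- abs(u)
  w <- numeric(length(u))
  w[au <= p] <- 1
  tap <- au > p & au < 1
  w[tap] <- cos(pi * (au[tap] - p) / (2 * (1 - p)))^2
  w
}

smoothstep <- function(u) u^2 * (3 - 2 * u)

# Trial timing: jump phase, blend-in, and walking stride grid.
sim_schedule <- function(cfg) {
  t_walk <- if (cfg$n_jumps > 0L) 6.0 else 1.0
  jumps <- if (cfg$n_jumps > 0L) 1.2 + 1.4 * (seq_len(cfg$n_jumps) - 1) else numeric()
  list(
    t0 = t_walk,
    jump_starts = jumps,
    blend = 0.8,
    t_end = t_walk + cfg$n_strides * cfg$stride_time + 0.5,
    rhs_times = t_walk + (0:cfg$n_strides) * cfg$stride_time,
    lhs_times = t_walk + ((0:(cfg$n_strides - 1)) + 0.5) * cfg$stride_time
  )
}

# 1-based indices of uniform samples (i-1)/fs falling in [a, b).
idx_range <- function(a, b, fs, n) {
  lo <- max(1L, as.integer(ceiling(a * fs - 1e-9)) + 1L)
  hi <- min(n, as.integer(ceiling(b * fs - 1e-9)))
  if (hi < lo) integer() else lo:hi
}

# Vertical displacement added to the whole body during jump flights.
jump_dz <- function(t, sched, g) {
  dz <- numeric(length(t))
  tf <- .geom$jump_flight
  v0 <- g * tf / 2
  for (ts in sched$jump_starts) {
    inside <- t >= ts & t < ts + tf
    tau <- t[inside] - ts
    dz[inside] <- v0 * tau - g * tau^2 / 2
  }
  dz
}

# Baseline CoM position at walking phase phi (no bumps, full envelope),
# relative to a right footfall at x = 0 at phi = 0.
baseline_com <- function(phi, cfg, z_c0, x_off) {
  v <- cfg$stride_length / cfg$stride_time
  list(
    x = x_off + v * cfg$stride_time * phi + .geom$a_x * sin(4 * pi * phi),
    y = -.geom$a_y * sin(2 * pi * phi),
    z = z_c0 - .geom$a_z * cos(4 * pi * phi)
  )
}

# Calibrate the CoM height so the measured foot-to-CoM distance over right
# stance equals the configured leg length, and the AP offset so the mean
# forward margin of stability at heel strike equals fw_mos_base +
# fw_mos_offset. Both use the same sampled-signal operations as the
# analysis (central differences at the kinematic rate).
calibrate_baseline <- function(cfg) {
  fs <- cfg$sample_rate_kin
  Tt <- cfg$stride_time
  pad <- 10L
  idx <- (-pad):(round(Tt * fs) + pad)
  tt <- idx / fs
  phi <- tt / Tt
  stance_idx <- which(tt >= 0 & tt <= .geom$stance_frac * Tt)

  leg_meas <- function(z_c0, x_off) {
    com <- baseline_com(phi, cfg, z_c0, x_off)
    bs <- -.geom$backslide * (tt[stance_idx] / (.geom$stance_frac * Tt))
    dx <- com$x[stance_idx] - (0 + .geom$met5[1] + bs)
    dy <- com$y[stance_idx] - (-cfg$step_width / 2 - .geom$met5[2] * 0 - 0.03)
    dz <- com$z[stance_idx]
    mean(sqrt(dx^2 + dy^2 + dz^2))
  }
  fw_meas <- function(z_c0, x_off) {
    com <- baseline_com(phi, cfg, z_c0, x_off)
    vx <- central_diff(com$x, 1 / fs)
    L <- leg_meas(z_c0, x_off)
    i1 <- which(idx == round(Tt * fs))
    xcom <- com$x[i1] + sqrt(L / cfg$gravity) * vx[i1]
    cfg$stride_length - xcom
  }

  x_off <- -0.25
  z_c0 <- sqrt(max(cfg$leg_length^2 - (cfg$stride_length / 4)^2, 0.1))
  target_fw <- .geom$fw_mos_base + cfg$fw_mos_offset
  for (it in 1:4) {
    z_c0 <- uniroot(function(z) leg_meas(z, x_off) - cfg$leg_length,
                    interval = c(0.2, 2 * cfg$leg_length),
                    tol = 1e-10)$root
    x_off <- x_off + (fw_meas(z_c0, x_off) - target_fw)
  }
  list(z_c0 = z_c0, x_off = x_off)
}

# Foot marker trajectory: hold at each footfall (with a slight backslide),
# smooth swing to the next footfall with a sinusoidal vertical lift.
build_foot <- function(t, footfall_t, footfall_x, footfall_y,
                       pre_x, pre_y, cfg, sched) {
  sw <- (1 - .geom$stance_frac) * cfg$stride_time
  fs <- 1 / (t[2] - t[1])
  n <- length(t)
  x <- rep(pre_x, n)
  y <- rep(pre_y, n)
  z <- numeric(n)
  ff_t <- c(-Inf, footfall_t)
  ff_x <- c(pre_x, footfall_x)
  ff_y <- c(pre_y, footfall_y)
  for (i in seq_along(ff_t)) {
    st_start <- max(ff_t[i], 0)
    st_end <- if (i < length(ff_t)) ff_t[i + 1] - sw else t[n] + 1
    hold <- idx_range(st_start, st_end, fs, n)
    if (length(hold) > 0) {
      dur <- st_end - st_start
      bs <- if (is.finite(ff_t[i]) && dur <= cfg$stride_time) {
        -.geom$backslide * (t[hold] - st_start) / dur
      } else 0
      x[hold] <- ff_x[i] + bs
      y[hold] <- ff_y[i]
      z[hold] <- 0
    }
    if (i < length(ff_t)) {
      swing <- idx_range(st_end, ff_t[i + 1], fs, n)
      if (length(swing) > 0) {
        u <- (t[swing] - st_end) / sw
        x0 <- ff_x[i] - if (is.finite(ff_t[i])) .geom$backslide else 0
        x[swing] <- x0 + (ff_x[i + 1] - x0) * smoothstep(u)
        y[swing] <- ff_y[i] + (ff_y[i + 1] - ff_y[i]) * smoothstep(u)
        z[swing] <- .geom$swing_height * sin(pi * u)
      }
    }
  }
  z <- z + jump_dz(t, sched, cfg$gravity)
  list(x = x, y = y, z = z)
}

# Midstance CoM states (n x 9) extracted from sampled series exactly as the
# analysis does: central differences at the kinematic rate, linear
# interpolation at the midstance instant.
midstance_state_matrix <- function(cx, cy, cz, fs, mid_time) {
  dt <- 1 / fs
  idx <- mid_time * fs + 1
  vx <- central_diff(cx, dt); vy <- central_diff(cy, dt)
  vz <- central_diff(cz, dt)
  ax <- central_diff2(cx, dt); ay <- central_diff2(cy, dt)
  az <- central_diff2(cz, dt)
  m <- cbind(
    pos_x = interp_at(cx, idx), pos_y = interp_at(cy, idx),
    pos_z = interp_at(cz, idx),
    vel_x = interp_at(vx, idx), vel_y = interp_at(vy, idx),
    vel_z = interp_at(vz, idx),
    acc_x = interp_at(ax, idx), acc_y = interp_at(ay, idx),
    acc_z = interp_at(az, idx)
  )
  m
}

simulate_walker_impl <- function(cfg) {
  n <- cfg$n_strides
  fs <- cfg$sample_rate_kin
  Tt <- cfg$stride_time
  sched <- sim_schedule(cfg)
  cal <- calibrate_baseline(cfg)
  v <- cfg$stride_length / Tt

  nk <- round(sched$t_end * fs)
  t_kin <- (0:nk) / fs
  phi <- (t_kin - sched$t0) / Tt

  # --- random draws (order is part of the determinism contract) ---------
  Z <- matrix(rnorm(n * 9), n, 9)
  eig <- eigen(cfg$com_state_cov, symmetric = TRUE)
  A <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), 9)
  delta <- Z %*% t(A)
  colnames(delta) <- state_names()
  eps_ap <- rnorm(n, 0, cfg$fp_noise_sd)
  eps_ml <- rnorm(n, 0, cfg$fp_noise_sd)
  omega0 <- rnorm(n)
  eta0 <- rnorm(n)
  cop0 <- rnorm(n)

  # --- CoM trajectory ---------------------------------------------------
  blend_u <- pmin(pmax((t_kin - sched$t0 + sched$blend) / sched$blend, 0), 1)
  env <- (1 - cos(pi * blend_u)) / 2
  ramp <- ifelse(
    t_kin >= sched$t0, v * (t_kin - sched$t0),
    ifelse(t_kin <= sched$t0 - sched$blend, -sched$blend * v / 2,
           v * sched$blend * (blend_u / 2 - sin(pi * blend_u) / (2 * pi)) -
             sched$blend * v / 2))
  com_x <- cal$x_off + ramp + env * .geom$a_x * sin(4 * pi * phi)
  com_y <- env * (-.geom$a_y * sin(2 * pi * phi))
  com_z <- cal$z_c0 + jump_dz(t_kin, sched, cfg$gravity) +
    env * (-.geom$a_z * cos(4 * pi * phi))

  # per-stride CoM-state bumps centred on the midstance instant
  mid_time <- sched$t0 + (seq_len(n) - (1 - .geom$midstance_frac)) * Tt
  hw <- .geom$bump_halfwidth * Tt
  for (k in seq_len(n)) {
    rng <- idx_range(mid_time[k] - hw, mid_time[k] + hw, fs, length(t_kin))
    dtm <- t_kin[rng] - mid_time[k]
    w <- bump_window(dtm / hw)
    for (ax_i in 1:3) {
      poly <- delta[k, ax_i] + delta[k, 3 + ax_i] * dtm +
        delta[k, 6 + ax_i] * dtm^2 / 2
      add <- poly * w
      if (ax_i == 1) com_x[rng] <- com_x[rng] + add
      if (ax_i == 2) com_y[rng] <- com_y[rng] + add
      if (ax_i == 3) com_z[rng] <- com_z[rng] + add
    }
  }

  # --- realized midstance states and the placement recursion ------------
  Xg <- midstance_state_matrix(com_x, com_y, com_z, fs, mid_time)
  # the analysis measures AP position relative to the stride origin (the
  # previous right footfall); remove the nominal footfall grid so the
  # centred states match that frame up to the origin-deviation term
  Xg[, "pos_x"] <- Xg[, "pos_x"] - (seq_len(n) - 1L) * cfg$stride_length
  cmat <- scale(Xg, center = TRUE, scale = FALSE)
  B <- cfg$stepping_gains
  o <- matrix(0, n + 1, 2) # origin deviation of right footfalls 0..n (ap, ml)
  fp_dev <- matrix(0, n, 2, dimnames = list(NULL, c("ap", "ml")))
  state_dev <- matrix(0, n, 9, dimnames = list(NULL, state_names()))
  for (k in seq_len(n)) {
    s <- cmat[k, ]
    s["pos_x"] <- s["pos_x"] - o[k, 1]
    s["pos_y"] <- s["pos_y"] - o[k, 2]
    state_dev[k, ] <- s
    u <- drop(B %*% s) + c(eps_ap[k], eps_ml[k])
    fp_dev[k, ] <- u
    o[k + 1, ] <- o[k, ] + u
  }

  # --- compensation channels (ML): Error = b_a*dCoP + b_t*dOmega + eta --
  # The stepping residual r is what the downstream OLS will leave
  # unexplained; the CoP and trunk deviations are constructed to decompose
  # -r into the two strategy channels plus a residual of SD
  # compensation_noise_sd.
  fpc <- fp_dev[, "ml"] - mean(fp_dev[, "ml"])
  Xc <- scale(state_dev, center = TRUE, scale = FALSE)
  if (n >= 12L) {
    fit <- lm.fit(Xc, fpc)
    r <- as.numeric(fit$residuals)
  } else {
    r <- eps_ml - mean(eps_ml)
  }
  eta <- if (cfg$compensation_noise_sd > 0 && stats::sd(eta0) > 0) {
    eta0 / stats::sd(eta0) * cfg$compensation_noise_sd
  } else {
    numeric(n)
  }
  if (cfg$ankle_gain != 0 && cfg$trunk_gain != 0) {
    omega_dev <- omega0 * 3
    cop_dev <- (-r - cfg$trunk_gain * omega_dev - eta) / cfg$ankle_gain
  } else if (cfg$ankle_gain == 0 && cfg$trunk_gain != 0) {
    cop_dev <- cop0 * 0.01
    omega_dev <- (-r - eta) / cfg$trunk_gain
  } else if (cfg$ankle_gain != 0) {
    omega_dev <- omega0 * 3
    cop_dev <- (-r - eta) / cfg$ankle_gain
  } else {
    cop_dev <- cop0 * 0.01
    omega_dev <- omega0 * 3
    eta <- -r
  }

  # --- footfall schedule and foot trajectories --------------------------
  x_R <- c(0, cumsum(cfg$stride_length + fp_dev[, "ap"]))
  y_R <- c(-cfg$step_width / 2,
           -cfg$step_width / 2 + cumsum(fp_dev[, "ml"]))
  x_L <- (x_R[1:n] + x_R[2:(n + 1)]) / 2
  y_L <- cfg$step_width + (y_R[1:n] + y_R[2:(n + 1)]) / 2
  rfoot <- build_foot(t_kin, sched$rhs_times, x_R, y_R,
                      pre_x = -cfg$stride_length,
                      pre_y = -cfg$step_width / 2, cfg, sched)
  lfoot <- build_foot(t_kin, sched$lhs_times, x_L, y_L,
                      pre_x = -cfg$stride_length / 2,
                      pre_y = cfg$step_width / 2, cfg, sched)

  foot_marker <- function(foot, off, side) {
    sgn <- if (side == "right") 1 else -1
    list(x = foot$x + off[1], y = foot$y + sgn * off[2], z = foot$z)
  }
  rmet5 <- foot_marker(rfoot, .geom$met5, "right")
  lmet5 <- foot_marker(lfoot, .geom$met5, "left")
  rmet1 <- foot_marker(rfoot, .geom$met1, "right")
  lmet1 <- foot_marker(lfoot, .geom$met1, "left")

  # --- trunk angular velocity ------------------------------------------
  trunk <- env * .geom$a_w * sin(2 * pi * phi)
  stride_of_t <- floor(phi + 1e-9) + 1
  in_walk <- stride_of_t >= 1 & stride_of_t <= n
  trunk[in_walk] <- trunk[in_walk] + omega_dev[stride_of_t[in_walk]]

  kin <- tibble::tibble(
    time = t_kin,
    com_x = com_x, com_y = com_y, com_z = com_z,
    sacrum_x = com_x - 0.03, sacrum_y = com_y, sacrum_z = com_z - 0.10,
    c7_x = com_x - 0.02, c7_y = com_y, c7_z = com_z + 0.35,
    rhip_x = com_x - 0.03, rhip_y = com_y - 0.09, rhip_z = com_z - 0.12,
    lhip_x = com_x - 0.03, lhip_y = com_y + 0.09, lhip_z = com_z - 0.12,
    rheel_x = rfoot$x, rheel_y = rfoot$y, rheel_z = rfoot$z,
    rmet5_x = rmet5$x, rmet5_y = rmet5$y, rmet5_z = rmet5$z,
    rmet1_x = rmet1$x, rmet1_y = rmet1$y, rmet1_z = rmet1$z,
    lheel_x = lfoot$x, lheel_y = lfoot$y, lheel_z = lfoot$z,
    lmet5_x = lmet5$x, lmet5_y = lmet5$y, lmet5_z = lmet5$z,
    lmet1_x = lmet1$x, lmet1_y = lmet1$y, lmet1_z = lmet1$z,
    trunk_omega_ml = trunk
  )
  kin <- kin_recording(kin, fs, walk_start = sched$t0 - sched$blend)

  insole <- build_insole(cfg, sched, x_R, y_R, x_L, y_L, cop_dev)

  truth_strides <- tibble::tibble(
    stride = seq_len(n),
    condition = cfg$condition,
    tibble::as_tibble(state_dev),
    fp_dev_ap = fp_dev[, "ap"],
    fp_dev_ml = fp_dev[, "ml"],
    cop_dev = cop_dev,
    trunk_omega_dev = omega_dev,
    comp_resid = eta,
    eps_ap = eps_ap,
    eps_ml = eps_ml
  )
  truth <- structure(
    list(strides = truth_strides,
         stepping_gains = B,
         ankle_gain = cfg$ankle_gain,
         trunk_gain = cfg$trunk_gain,
         rhs_times = sched$rhs_times,
         lhs_times = sched$lhs_times,
         rto_times = sched$rhs_times[1:n] + .geom$stance_frac * Tt,
         lto_times = sched$lhs_times + .geom$stance_frac * Tt,
         mid_times = mid_time,
         clock_offset = cfg$clock_offset,
         walk_start = sched$t0 - sched$blend,
         leg_length = cfg$leg_length,
         com_height = cal$z_c0,
         config = cfg),
    class = "gait_truth")

  structure(list(kin = kin, insole = insole, truth = truth),
            class = "gait_sim")
}

# Two-peaked stance vGRF shape on s in [0, 1]; stance-average 1.
grf_shape <- function(s) {
  (0.8 * sin(pi * s) + 0.2 * sin(3 * pi * s)) / 0.5517409
}

build_insole <- function(cfg, sched, x_R, y_R, x_L, y_L, cop_dev) {
  fs <- cfg$sample_rate_insole
  Tt <- cfg$stride_time
  n <- cfg$n_strides
  bw <- cfg$body_mass * cfg$gravity
  st <- .geom$stance_frac * Tt
  ni <- round(sched$t_end * fs)
  t_ins <- (0:ni) / fs

  eps <- 1e-9
  stance_force <- function(footfall_t) {
    f <- numeric(length(t_ins))
    for (tf in footfall_t) {
      inside <- idx_range(tf - eps, tf + st - eps, fs, length(t_ins))
      s <- pmax((t_ins[inside] - tf) / st, 0)
      f[inside] <- bw * grf_shape(s)
    }
    f
  }

  # standing phase: half body weight per foot, zero during jump flights,
  # with a continuous load ramp plus a landing transient after each flight
  standing <- function(first_swing_start) {
    f <- ifelse(t_ins < first_swing_start, bw / 2, 0)
    tf <- .geom$jump_flight
    for (ts in sched$jump_starts) {
      f[t_ins >= ts & t_ins < ts + tf] <- 0
      reload <- t_ins >= ts + tf & t_ins < ts + tf + 0.05
      f[reload] <- bw / 2 * (t_ins[reload] - ts - tf) / 0.05
      land <- t_ins >= ts + tf & t_ins < ts + tf + .geom$jump_spike_dur
      f[land] <- f[land] +
        .geom$jump_spike_amp * bw *
        sin(pi * (t_ins[land] - ts - tf) / .geom$jump_spike_dur)
    }
    f
  }

  sw <- (1 - .geom$stance_frac) * Tt
  vgrf_right <- stance_force(sched$rhs_times) +
    standing(sched$rhs_times[1] - sw)
  vgrf_left <- stance_force(sched$lhs_times) +
    standing(sched$lhs_times[1] - sw)

  # ML CoP relative to the sole centreline (as insole hardware reports):
  # piecewise constant per stance; the left stance preceding right footfall
  # k carries the compensation shift of stride k.
  cop_right <- rep(0, length(t_ins))
  cop_left <- rep(0, length(t_ins))
  nlt <- length(sched$lhs_times)
  for (j in seq_len(nlt)) {
    upto <- if (j < nlt) sched$lhs_times[j + 1] - eps else t_ins[length(t_ins)] + 1
    cop_left[idx_range(sched$lhs_times[j] - eps, upto, fs, length(t_ins))] <-
      cop_dev[j]
  }

  insole_recording(
    tibble::tibble(
      time = t_ins + cfg$clock_offset,
      vgrf_right = vgrf_right, cop_ml_right = cop_right,
      vgrf_left = vgrf_left, cop_ml_left = cop_left
    ),
    fs, walk_start = sched$t0 - sched$blend + cfg$clock_offset)
}

#' @export
print.gait_truth <- function(x, ...) {
  cat(sprintf("<gait ground truth: %d strides, clock offset %.3f s>\n",
              nrow(x$strides), x$clock_offset))
  invisible(x)
}
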