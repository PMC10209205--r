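#' Configuration for the synthetic gait generator
#'
#' Builds and validates the parameter set for [simulate_walker()]. Defaults
#' describe a healthy adult walking at a comfortable outdoor pace, with a
#' linear foot-placement controller acting on the midstance CoM state.
#'
#' The stepping controller is a 2 x 9 gain matrix `stepping_gains` (rows:
#' AP, ML) mapping the deviation of the midstance CoM state (position,
#' velocity, acceleration in the AP/ML/VT axes) from its mean onto the
#' deviation of the next foot placement. `fp_noise_sd` is the total SD of
#' the foot-placement deviation that is not explained by the CoM state. In
#' the ML direction that unexplained part is decomposed into an ankle
#' (centre-of-pressure) term with gain `ankle_gain`, a trunk
#' (angular-velocity) term with gain `trunk_gain`, and a residual of SD
#' `compensation_noise_sd`, so that the downstream compensation regression
#' has a known recoverable target.
#'
#' @param n_strides Number of complete strides to generate (>= 1).
#' @param stride_time Stride duration in s.
#' @param stride_length Nominal stride length in m.
#' @param step_width Nominal step width in m.
#' @param leg_length Inverted-pendulum leg length L in m (the generator
#'   calibrates the CoM height so that the measured foot-to-CoM distance
#'   recovers this value).
#' @param gravity Gravitational acceleration g in m/s^2.
#' @param body_mass Body mass in kg (sets the vertical GRF scale).
#' @param sample_rate_kin Kinematic sampling rate in Hz.
#' @param sample_rate_insole Insole sampling rate in Hz.
#' @param stepping_gains 2 x 9 numeric matrix; rows `ap` and `ml`, columns
#'   position x/y/z, velocity x/y/z, acceleration x/y/z.
#' @param fp_noise_sd SD (m) of foot-placement deviations not driven by the
#'   CoM state.
#' @param ankle_gain Dimensionless gain relating foot-placement error to the
#'   mean ML CoP shift (m per m).
#' @param trunk_gain Gain relating foot-placement error to the mean ML trunk
#'   angular velocity, in m per deg/s.
#' @param compensation_noise_sd SD (m) of the part of the ML foot-placement
#'   error unexplained by the ankle and trunk terms. Must not exceed
#'   `fp_noise_sd`.
#' @param com_state_cov 9 x 9 symmetric positive semi-definite covariance of
#'   the midstance CoM-state deviations (units: m, m/s, m/s^2).
#' @param fw_mos_offset Shift (m) applied to the mean anterior-heel-to-XCoM
#'   distance at heel strike (forward margin of stability).
#' @param clock_offset Offset (s) added to the insole clock relative to the
#'   kinematic clock, recoverable by [synchronize_jumps()].
#' @param n_jumps Number of synchronization jumps prepended to the trial.
#' @param condition Condition tag attached to every stride (e.g. "S", "W1",
#'   "W2").
#' @param seed Integer seed; fully determines the generated recordings.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_strides = 10, seed = 42)
#' cfg$stride_time
sim_config <- function(n_strides = 50L,
                       stride_time = 1.1,
                       stride_length = 1.40,
                       step_width = 0.10,
                       leg_length = 0.91,
                       gravity = 9.806,
                       body_mass = 74,
                       sample_rate_kin = 120,
                       sample_rate_insole = 100,
                       stepping_gains = default_stepping_gains(),
                       fp_noise_sd = 0.008,
                       ankle_gain = 0.8,
                       trunk_gain = 0.002,
                       compensation_noise_sd = 0.004,
                       com_state_cov = default_com_state_cov(),
                       fw_mos_offset = 0,
                       clock_offset = 0,
                       n_jumps = 3L,
                       condition = "S",
                       seed = 1L) {
  n_strides <- as.integer(n_strides)
  if (is.na(n_strides) || n_strides < 1L) abort("n_strides must be >= 1")
  for (nm in c("stride_time", "stride_length", "step_width", "leg_length",
               "gravity", "body_mass", "sample_rate_kin",
               "sample_rate_insole")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(paste0(nm, " must be a single positive number"))
    }
  }
  if (!is.matrix(stepping_gains) || !all(dim(stepping_gains) == c(2L, 9L))) {
    abort("stepping_gains must be a 2 x 9 matrix (rows ap, ml)")
  }
  if (!is.matrix(com_state_cov) || !all(dim(com_state_cov) == c(9L, 9L))) {
    abort("com_state_cov must be a 9 x 9 matrix")
  }
  if (max(abs(com_state_cov - t(com_state_cov))) > 1e-8) {
    abort("com_state_cov must be symmetric")
  }
  ev <- eigen(com_state_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    abort(paste0("com_state_cov is not positive semi-definite ",
                 "(smallest eigenvalue ", format(min(ev)), ")"))
  }
  if (fp_noise_sd < 0 || compensation_noise_sd < 0) {
    abort("noise standard deviations must be non-negative")
  }
  if (compensation_noise_sd > fp_noise_sd + 1e-12) {
    abort(paste0("compensation_noise_sd must not exceed fp_noise_sd: the ",
                 "compensation residual is one component of the ",
                 "foot-placement noise budget"))
  }
  n_jumps <- as.integer(n_jumps)
  if (is.na(n_jumps) || n_jumps < 0L) abort("n_jumps must be >= 0")
  seed <- as.integer(seed)
  if (is.na(seed)) abort("seed must be an integer")
  rownames(stepping_gains) <- c("ap", "ml")
  colnames(stepping_gains) <- state_names()
  dimnames(com_state_cov) <- list(state_names(), state_names())
  structure(
    list(n_strides = n_strides, stride_time = stride_time,
         stride_length = stride_length, step_width = step_width,
         leg_length = leg_length, gravity = gravity, body_mass = body_mass,
         sample_rate_kin = sample_rate_kin,
         sample_rate_insole = sample_rate_insole,
         stepping_gains = stepping_gains, fp_noise_sd = fp_noise_sd,
         ankle_gain = ankle_gain, trunk_gain = trunk_gain,
         compensation_noise_sd = compensation_noise_sd,
         com_state_cov = com_state_cov, fw_mos_offset = fw_mos_offset,
         clock_offset = clock_offset, n_jumps = n_jumps,
         condition = condition, seed = seed),
    class = "sim_config")
}

#' Names of the nine midstance CoM-state components
#'
#' Position, velocity and acceleration in the AP (`x`), ML (`y`) and
#' VT (`z`) stride-frame axes, in the order used by the stepping gains.
#' @return Character vector of length 9.
#' @export
state_names <- function() {
  c("pos_x", "pos_y", "pos_z", "vel_x", "vel_y", "vel_z",
    "acc_x", "acc_y", "acc_z")
}

#' @rdname sim_config
#' @export
default_stepping_gains <- function() {
  m <- rbind(
    ap = c(0.50, 0.25, 0.40, 0.30, 0.20, 0.25, 0.12, 0.15, 0.10),
    ml = c(0.15, 0.45, 0.10, 0.12, 0.35, 0.10, 0.10, 0.12, 0.10)
  )
  colnames(m) <- state_names()
  m
}

#' @rdname sim_config
#' @export
default_com_state_cov <- function() {
  sds <- c(0.015, 0.012, 0.010, 0.040, 0.030, 0.020, 0.150, 0.120, 0.100)
  m <- diag(sds^2)
  dimnames(m) <- list(state_names(), state_names())
  m
}

#' Analytic coefficient of determination of the stepping controller
#'
#' The generator's foot-placement deviation is `B s + e`, where `s` is the
#' midstance-state deviation as the analysis measures it: the injected
#' CoM-state perturbation (covariance `com_state_cov`) minus, in the
#' horizontal position components, the deviation of the stride origin (the
#' previous right footfall). The origin deviation follows the stationary
#' AR recursion `o_k = (I - G) o_(k-1) + u_k` with `G` the 2 x 2 block of
#' position gains and `u` the placement innovation, so the state
#' covariance carries an extra horizontal-position term given by the
#' discrete Lyapunov equation. The population R^2 is
#' `var(B s) / (var(B s) + fp_noise_sd^2)` under that state covariance.
#'
#' @param config A [sim_config()].
#' @param direction `"ap"` or `"ml"`.
#' @return The population R^2 in `[0, 1]`.
#' @export
analytic_stepping_r2 <- function(config, direction = c("ap", "ml")) {
  direction <- match.arg(direction)
  b <- config$stepping_gains[direction, ]
  sig <- drop(b %*% state_cov_measured(config) %*% b)
  sig / (sig + config$fp_noise_sd^2)
}

# Covariance of the midstance state as measured in the stride frame:
# injected-state covariance plus the stationary origin-deviation variance
# in the horizontal position components.
state_cov_measured <- function(config) {
  B <- config$stepping_gains
  Sig <- config$com_state_cov
  G <- B[, c("pos_x", "pos_y")]
  A <- diag(2) - G
  Q <- B %*% Sig %*% t(B) + diag(config$fp_noise_sd^2, 2)
  V <- Q
  for (i in 1:200) V <- A %*% V %*% t(A) + Q
  out <- Sig
  pos <- c("pos_x", "pos_y")
  out[pos, pos] <- out[pos, pos] + V
  out
}

#' Foot-placement noise level giving a target stepping R^2
#'
#' Inverts [analytic_stepping_r2()]: returns the `fp_noise_sd` for which the
#' population stepping R^2 equals `r2` under the configured gains and state
#' covariance.
#'
#' @param config A [sim_config()].
#' @param r2 Target R^2 in (0, 1).
#' @param direction `"ap"` or `"ml"`.
#' @return Noise SD in metres.
#' @export
fp_noise_for_r2 <- function(config, r2, direction = c("ap", "ml")) {
  direction <- match.arg(direction)
  if (r2 <= 0 || r2 >= 1) abort("r2 must be in (0, 1)")
  f <- function(sd) {
    cfg <- config
    cfg$fp_noise_sd <- sd
    cfg$compensation_noise_sd <- min(cfg$compensation_noise_sd, sd)
    analytic_stepping_r2(cfg, direction) - r2
  }
  uniroot(f, lower = 1e-6, upper = 1, tol = 1e-10)$root
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config: %d strides, %.2f s / %.2f m stride, ",
                     "L = %.2f m, seed = %d>\n"),
              x$n_strides, x$stride_time, x$stride_length, x$leg_length,
              x$seed))
  invisible(x)
}
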