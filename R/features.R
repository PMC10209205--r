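#' Per-stride gait features
#'
#' Runs the stride-level analysis over a synchronized pair of recordings:
#' stride segmentation at right heel strikes, per-stride anatomical frames,
#' margins of stability at heel strike and over single stance, the
#' midstance CoM state (position, velocity, acceleration in the stride
#' frame), foot-placement coordinates, the five spatiotemporal measures,
#' and the stance-mean ML centre of pressure and stride-mean ML trunk
#' angular velocity used by the compensation regression.
#'
#' CoM derivatives are central differences on the full recording at the
#' kinematic rate, computed before any stride-level resampling; the
#' midstance instant is the midpoint of the single-support phase of the
#' stance foot preceding the analysed foot placement, operationalized as a
#' fixed stride phase (`midstance_frac`, default 80%, the midpoint of the
#' nominal 60-100% contralateral single support).
#'
#' @param kin A [kin_recording()].
#' @param insole Optional [insole_recording()]; enables the CoP channel.
#' @param events Optional `gait_events`; detected kinematically when
#'   missing.
#' @param clock_offset Insole clock offset (s); estimated with
#'   [synchronize_jumps()] when an insole recording is present and the
#'   offset is missing.
#' @param condition Condition tag recycled over strides (default "S").
#' @param g Gravitational acceleration (m/s^2).
#' @param midstance_frac Midstance instant as a fraction of the stride.
#' @param force_threshold Contact threshold (N) for the CoP stance mask.
#' @return A tibble with one row per stride: identifiers, spatiotemporal
#'   measures, margins of stability, midstance state columns
#'   (`pos_x` ... `acc_z`), foot placement (`fp_ap`, `fp_ml`), `cop_bar`
#'   and `trunk_bar`. Strides with unresolvable windows carry `NA` in the
#'   affected columns and a warning is raised.
#' @export
#' @examples
#' sim <- simulate_walker(sim_config(n_strides = 8, seed = 2))
#' feats <- gait_features(sim$kin, sim$insole)
#' feats[, c("stride", "stride_time", "fw_mos", "ml_mos")]
gait_features <- function(kin, insole = NULL, events = NULL,
                          clock_offset = NULL, condition = "S",
                          g = 9.806, midstance_frac = 0.8,
                          force_threshold = 30) {
  events <- events %||% detect_events_kinematic(kin)
  if (!is.null(insole) && is.null(clock_offset)) {
    clock_offset <- synchronize_jumps(kin, insole, gravity = g)
  }
  clock_offset <- clock_offset %||% 0
  fs <- rate_of(kin)
  dt <- 1 / fs
  tt <- kin$time
  vx <- central_diff(kin$com_x, dt)
  vy <- central_diff(kin$com_y, dt)
  vz <- central_diff(kin$com_z, dt)
  ax <- central_diff2(kin$com_x, dt)
  ay <- central_diff2(kin$com_y, dt)
  az <- central_diff2(kin$com_z, dt)
  ins_time <- if (!is.null(insole)) insole$time - clock_offset
  left_on <- if (!is.null(insole)) insole$vgrf_left >= force_threshold

  rhs <- events$rhs
  n <- length(rhs) - 1L
  feat_names <- c("stride", "t_start", "stride_time", "stance_time",
                  "speed", "stride_length", "step_width", "leg_length",
                  "fw_mos", "bw_mos", "bos_extent", "ml_mos",
                  state_names(), "fp_ap", "fp_ml", "cop_bar", "trunk_bar")
  M <- matrix(NA_real_, n, length(feat_names),
              dimnames = list(NULL, feat_names))
  for (k in seq_len(n)) {
    i0 <- rhs[k]; i1 <- rhs[k + 1L]
    t0 <- tt[i0]; t1 <- tt[i1]
    rto <- events$rto[events$rto > i0 & events$rto < i1]
    lhs <- events$lhs[events$lhs > i0 & events$lhs < i1]
    lto <- events$lto[events$lto > i0 & events$lto < i1]

    # stride frame: origin at the initial right heel contact, x along the
    # horizontal sacrum displacement
    dxy <- c(kin$sacrum_x[i1] - kin$sacrum_x[i0],
             kin$sacrum_y[i1] - kin$sacrum_y[i0])
    nd <- sqrt(sum(dxy^2))
    if (nd < 1e-6) {
      warn(sprintf("stride %d skipped: no horizontal progression", k))
      next
    }
    xh <- dxy / nd
    R2 <- rbind(c(xh[1], xh[2]), c(-xh[2], xh[1])) # rows: ap, ml
    o <- c(kin$rheel_x[i0], kin$rheel_y[i0])
    tr_ap <- function(px, py) R2[1, 1] * (px - o[1]) + R2[1, 2] * (py - o[2])
    tr_ml <- function(px, py) R2[2, 1] * (px - o[1]) + R2[2, 2] * (py - o[2])
    rot_ap <- function(ux, uy) R2[1, 1] * ux + R2[1, 2] * uy
    rot_ml <- function(ux, uy) R2[2, 1] * ux + R2[2, 2] * uy

    # leg length over right stance
    st_end <- if (length(rto) >= 1L) rto[1] else i1
    sel <- i0:st_end
    leg <- mean(sqrt((kin$com_x[sel] - kin$rmet5_x[sel])^2 +
                       (kin$com_y[sel] - kin$rmet5_y[sel])^2 +
                       (kin$com_z[sel] - kin$rmet5_z[sel])^2))
    tau <- sqrt(leg / g)

    # midstance CoM state in the stride frame
    mi <- (t0 + midstance_frac * (t1 - t0)) * fs + 1
    p <- c(interp_at(kin$com_x, mi), interp_at(kin$com_y, mi),
           interp_at(kin$com_z, mi))
    v <- c(interp_at(vx, mi), interp_at(vy, mi), interp_at(vz, mi))
    a <- c(interp_at(ax, mi), interp_at(ay, mi), interp_at(az, mi))
    state <- c(
      pos_x = tr_ap(p[1], p[2]), pos_y = tr_ml(p[1], p[2]), pos_z = p[3],
      vel_x = rot_ap(v[1], v[2]), vel_y = rot_ml(v[1], v[2]), vel_z = v[3],
      acc_x = rot_ap(a[1], a[2]), acc_y = rot_ml(a[1], a[2]), acc_z = a[3])

    # foot placement: right heel at the terminating heel strike
    fp_ap <- tr_ap(kin$rheel_x[i1], kin$rheel_y[i1])
    fp_ml <- tr_ml(kin$rheel_x[i1], kin$rheel_y[i1])

    # AP margins of stability at the terminating heel strike
    xcom_ap <- tr_ap(kin$com_x[i1], kin$com_y[i1]) +
      tau * rot_ap(vx[i1], vy[i1])
    rheel_ap <- fp_ap
    lheel_ap <- tr_ap(kin$lheel_x[i1], kin$lheel_y[i1])
    right_ant <- rheel_ap >= lheel_ap
    ant_heel <- if (right_ant) rheel_ap else lheel_ap
    post_met5 <- if (right_ant) {
      tr_ap(kin$lmet5_x[i1], kin$lmet5_y[i1])
    } else {
      tr_ap(kin$rmet5_x[i1], kin$rmet5_y[i1])
    }
    fw_mos <- ant_heel - xcom_ap
    bw_mos <- xcom_ap - post_met5

    # ML margin of stability over right single stance
    ml_mos <- NA_real_
    if (length(lto) >= 1L && length(lhs) >= 1L && lhs[1] > lto[1]) {
      ss <- lto[1]:lhs[1]
      xcom_ml <- tr_ml(kin$com_x[ss], kin$com_y[ss]) +
        tau * rot_ml(vx[ss], vy[ss])
      ml_mos <- min(xcom_ml - tr_ml(kin$rmet5_x[ss], kin$rmet5_y[ss]))
    } else {
      warn(sprintf("stride %d: no single-stance window; ML MoS is NA", k))
    }

    # spatiotemporal measures
    stance_time <- if (length(rto) >= 1L) tt[rto[1]] - t0 else NA_real_
    if (length(rto) < 1L) {
      warn(sprintf("stride %d: missing right toe-off; stance time is NA", k))
    }
    span <- i0:(i1 - 1L)
    speed <- rot_ap(mean(vx[span]), mean(vy[span]))
    step_width <- if (length(lhs) >= 1L) {
      abs(tr_ml(kin$lheel_x[lhs[1]], kin$lheel_y[lhs[1]]))
    } else {
      NA_real_
    }

    # compensation channels
    cop_bar <- NA_real_
    if (!is.null(insole) && length(lhs) >= 1L) {
      rng <- (findInterval(tt[lhs[1]] - 1e-9, ins_time) + 1L):
        findInterval(t1 - 1e-9, ins_time)
      rng <- rng[rng >= 1L & rng <= length(ins_time)]
      rng <- rng[left_on[rng]]
      if (length(rng) > 0L) cop_bar <- mean(insole$cop_ml_left[rng])
    }
    trunk_bar <- mean(kin$trunk_omega_ml[span])

    M[k, ] <- c(k, t0, t1 - t0, stance_time, speed, fp_ap, step_width,
                leg, fw_mos, bw_mos, ant_heel - post_met5, ml_mos,
                state, fp_ap, fp_ml, cop_bar, trunk_bar)
  }
  out <- tibble::as_tibble(as.data.frame(M))
  out <- out[!is.na(out$stride), ]
  out$stride <- as.integer(out$stride)
  out$condition <- rep_len(condition, nrow(out))
  dplyr::relocate(out, "condition", .after = "stride")
}
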