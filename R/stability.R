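#' Extrapolated centre of mass
#'
#' The XCoM adds to the CoM position its velocity scaled by the
#' inverted-pendulum time constant: `XCoM = CoM + sqrt(L/g) * dCoM/dt`,
#' applied per horizontal component.
#'
#' @param com CoM position (m); numeric vector or matrix.
#' @param com_vel CoM velocity (m/s), same shape as `com`.
#' @param L Leg length (m), positive.
#' @param g Gravitational acceleration (m/s^2), positive.
#' @return XCoM position, same shape as `com`.
#' @export
#' @examples
#' compute_xcom(1.0, 0.5, L = 0.91, g = 9.806)
compute_xcom <- function(com, com_vel, L, g = 9.806) {
  if (!is.numeric(L) || any(L <= 0)) abort("leg length L must be positive")
  if (!is.numeric(g) || any(g <= 0)) abort("gravity g must be positive")
  com + sqrt(L / g) * com_vel
}

#' Anterior-posterior margins of stability of one stride
#'
#' At the heel strike terminating the stride, the forward margin (FW MoS)
#' is the AP distance from the anterior foot's heel marker to the XCoM, and
#' the backward margin (BW MoS) is the AP distance from the XCoM to the
#' posterior foot's fifth-metatarsal marker. Their sum is the AP extent of
#' the base of support, an identity that holds per stride. The anterior
#' foot is resolved by comparing heel AP positions rather than assuming the
#' striking foot is anterior.
#'
#' @param slice A `stride_slice` in its stride frame (see
#'   [transform_stride()]).
#' @param L Leg length (m); defaults to [compute_leg_length()] of the slice.
#' @param g Gravitational acceleration (m/s^2).
#' @param com_vel_ap Optional AP CoM velocity for the slice samples
#'   (stride frame); computed by central differences within the slice when
#'   missing. Supplying velocities differentiated on the full recording
#'   avoids one-sided differences at the stride boundary.
#' @return A tibble with `fw_mos`, `bw_mos` and `bos_extent` (m).
#' @export
compute_ap_mos <- function(slice, L = NULL, g = 9.806, com_vel_ap = NULL) {
  kin <- slice$kin
  n <- nrow(kin)
  L <- L %||% compute_leg_length(slice)
  if (is.null(com_vel_ap)) {
    com_vel_ap <- central_diff(kin$com_x, kin$time[2] - kin$time[1])
  }
  xcom <- compute_xcom(kin$com_x[n], com_vel_ap[n], L, g)
  right_anterior <- kin$rheel_x[n] >= kin$lheel_x[n]
  ant_heel <- if (right_anterior) kin$rheel_x[n] else kin$lheel_x[n]
  post_met5 <- if (right_anterior) kin$lmet5_x[n] else kin$rmet5_x[n]
  tibble::tibble(
    fw_mos = ant_heel - xcom,
    bw_mos = xcom - post_met5,
    bos_extent = ant_heel - post_met5
  )
}

#' Mediolateral margin of stability of one stride
#'
#' The minimum, over the single-stance samples (contralateral toe-off to
#' contralateral heel strike), of the signed ML distance from the XCoM to
#' the stance foot's fifth-metatarsal marker; the sign is positive when the
#' XCoM is medial to the marker.
#'
#' @inheritParams compute_ap_mos
#' @param com_vel_ml Optional ML CoM velocity for the slice samples.
#' @param stance `"right"` or `"left"`: the stance foot of the single-stance
#'   window. Strides are right-heel-strike delineated, so the first single
#'   stance is on the right foot.
#' @return The ML margin of stability (m), or `NA` with a warning when no
#'   single-stance window can be identified.
#' @export
compute_ml_mos <- function(slice, L = NULL, g = 9.806, com_vel_ml = NULL,
                           stance = "right") {
  kin <- slice$kin
  lto <- slice$events$lto
  lhs <- slice$events$lhs
  if (length(lto) < 1L || length(lhs) < 1L || lhs[1] <= lto[1]) {
    warn(sprintf(
      "stride %s skipped: no single-stance window (missing contralateral events)",
      slice$stride %||% "?"))
    return(NA_real_)
  }
  sel <- (lto[1]:lhs[1]) - slice$start_index + 1L
  L <- L %||% compute_leg_length(slice)
  if (is.null(com_vel_ml)) {
    com_vel_ml <- central_diff(kin$com_y, kin$time[2] - kin$time[1])
  }
  xcom <- compute_xcom(kin$com_y[sel], com_vel_ml[sel], L, g)
  marker <- if (stance == "right") kin$rmet5_y[sel] else kin$lmet5_y[sel]
  sgn <- if (stance == "right") 1 else -1
  min(sgn * (xcom - marker))
}
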