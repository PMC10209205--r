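#' Detect heel strikes from insole vertical force
#'
#' A heel strike is the first sample at which the vertical ground reaction
#' force rises above `threshold` after having been below it for at least
#' `refractory` seconds. The refractory interval rejects chatter around the
#' threshold and is far shorter than any plausible swing phase.
#'
#' @param insole An [insole_recording()], or a numeric vGRF vector.
#' @param threshold Force threshold in N (default 30).
#' @param side `"right"` or `"left"` (ignored for a numeric vector).
#' @param refractory Minimum below-threshold time (s) before a crossing
#'   counts as a new contact.
#' @param sample_rate Sampling rate in Hz; taken from the recording when one
#'   is supplied.
#' @return Integer vector of 1-based sample indices (possibly empty).
#' @export
#' @examples
#' detect_heel_strikes_force(c(0, 0, 10, 40, 300, 500), sample_rate = 100)
detect_heel_strikes_force <- function(insole, threshold = 30,
                                      side = c("right", "left"),
                                      refractory = 0.2,
                                      sample_rate = NULL) {
  side <- match.arg(side)
  if (inherits(insole, "insole_recording")) {
    f <- insole[[paste0("vgrf_", side)]]
    sample_rate <- rate_of(insole)
  } else {
    f <- as.numeric(insole)
    if (is.null(sample_rate)) abort("sample_rate is required for a vector")
  }
  if (threshold <= 0) abort("threshold must be positive")
  if (any(f < -1e-9, na.rm = TRUE)) abort("vGRF must be non-negative")
  above <- f >= threshold
  above[is.na(above)] <- FALSE
  rising <- which(above & !c(TRUE, above[-length(above)]))
  if (length(rising) == 0L) return(integer())
  need <- max(1L, round(refractory * sample_rate))
  ok <- vapply(rising, function(i) {
    lo <- max(1L, i - need)
    all(!above[lo:(i - 1L)]) && (i - lo + 1L) > need
  }, logical(1))
  # the first crossing of the record cannot show a full refractory window;
  # accept it if the signal was below threshold from the start
  first_ok <- vapply(rising, function(i) all(!above[seq_len(i - 1L)]),
                     logical(1))
  as.integer(rising[ok | first_ok])
}

#' Detect gait events from foot kinematics
#'
#' Heel strikes are found where the heel's vertical position reaches its
#' stance plateau (within `z_tol` of the local minimum) coincident with a
#' forward-velocity sign change of the heel inside a +/- 50 ms window;
#' toe-offs are the last sample of the forefoot's ground plateau before
#' sustained upward vertical velocity. Events are validated to be strictly
#' increasing and alternating per foot.
#'
#' @param kin A [kin_recording()].
#' @param z_tol Height tolerance (m) used to identify the ground plateau.
#' @param from Time (s) from which to search; defaults to the recording's
#'   `walk_start` attribute so that synchronization jumps are skipped.
#' @return A `gait_events` list with integer sample-index vectors
#'   `rhs`, `rto`, `lhs`, `lto` and the search window used.
#' @export
detect_events_kinematic <- function(kin, z_tol = 0.002, from = NULL) {
  if (!inherits(kin, "kin_recording")) abort("kin must be a kin_recording")
  from <- from %||% walk_start_of(kin)
  fs <- rate_of(kin)
  i0 <- max(1L, floor(from * fs) + 1L)
  win <- max(1L, round(0.05 * fs))

  # progression heading from the net sacrum displacement of the walking
  # segment; heel velocities are projected onto it so detection does not
  # depend on the world frame
  n_all <- nrow(kin)
  hd <- c(kin$sacrum_x[n_all] - kin$sacrum_x[i0],
          kin$sacrum_y[n_all] - kin$sacrum_y[i0])
  nh <- sqrt(sum(hd^2))
  if (nh < 1e-6) {
    abort("no gait detected: the sacrum shows no net displacement")
  }
  hd <- hd / nh

  contact_events <- function(heel_z, heel_x, heel_y, toe_z) {
    rng <- max(heel_z) - min(heel_z)
    if (rng < 0.01) {
      abort("no gait detected: heel height is effectively constant")
    }
    ground <- heel_z <= min(heel_z) + z_tol
    # first sample of each ground plateau = candidate heel strike
    starts <- which(ground & !c(FALSE, ground[-length(ground)]))
    starts <- starts[starts > i0]
    # the heel must arrive with forward swing speed and stop (or retreat)
    # on contact: a forward-velocity sign change within +/- 50 ms
    vx <- hd[1] * central_diff(heel_x, 1 / fs) +
      hd[2] * central_diff(heel_y, 1 / fs)
    hs <- starts[vapply(starts, function(i) {
      lo <- max(1L, i - win); hi <- min(length(vx), i + win)
      any(vx[lo:i] > 0.2) && any(vx[i:hi] <= 0)
    }, logical(1))]
    # toe-off: last sample of each forefoot ground plateau followed by
    # sustained upward velocity
    tg <- toe_z <= min(toe_z) + z_tol
    ends <- which(tg & !c(tg[-1], FALSE))
    ends <- ends[ends > i0 & ends < length(toe_z) - win]
    vzt <- central_diff(toe_z, 1 / fs)
    to <- ends[vapply(ends, function(i) {
      all(vzt[(i + 1L):min(length(vzt), i + win)] >= -1e-9) &&
        toe_z[min(length(toe_z), i + 2L * win)] > z_tol
    }, logical(1))]
    list(hs = as.integer(hs), to = as.integer(to))
  }

  r <- contact_events(kin$rheel_z, kin$rheel_x, kin$rheel_y, kin$rmet1_z)
  l <- contact_events(kin$lheel_z, kin$lheel_x, kin$lheel_y, kin$lmet1_z)
  if (length(r$hs) < 2L) {
    abort("fewer than 2 right heel strikes detected; cannot form strides")
  }
  ev <- structure(list(rhs = r$hs, rto = r$to, lhs = l$hs, lto = l$to,
                       sample_rate = fs, from = from),
                  class = "gait_events")
  validate_events(ev)
  ev
}

validate_events <- function(ev) {
  for (nm in c("rhs", "rto", "lhs", "lto")) {
    x <- ev[[nm]]
    if (length(x) > 1L && any(diff(x) <= 0)) {
      abort(paste0("gait events `", nm, "` are not strictly increasing"))
    }
  }
  # each right toe-off must lie between consecutive right heel strikes
  if (length(ev$rhs) >= 2L) {
    for (k in seq_len(length(ev$rhs) - 1L)) {
      inside <- ev$rto[ev$rto > ev$rhs[k] & ev$rto < ev$rhs[k + 1L]]
      if (length(inside) > 1L) {
        abort("multiple right toe-offs within one stride: events invalid")
      }
    }
  }
  invisible(ev)
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf(
    "<gait events: %d RHS, %d RTO, %d LHS, %d LTO @ %g Hz>\n",
    length(x$rhs), length(x$rto), length(x$lhs), length(x$lto),
    x$sample_rate))
  invisible(x)
}

#' Estimate the insole clock offset from the synchronization jumps
#'
#' Both streams record the jumps performed at the beginning of a trial: the
#' insoles as flight phases (force below threshold) ending in landing
#' transients, the kinematics as free-fall vertical CoM acceleration
#' (approximately -g) ending in a landing spike. The offset is the median
#' difference of the paired landing-onset times; insole onsets are located
#' to sub-sample precision by linear interpolation of the force's
#' threshold crossing, so the aligned landing onsets agree to within one
#' insole sample.
#'
#' @param kin A [kin_recording()].
#' @param insole An [insole_recording()].
#' @param window Length (s) of the initial segment searched for jumps.
#' @param gravity Gravitational acceleration used to identify free fall.
#' @param threshold Flight/contact force threshold in N.
#' @return The estimated clock offset in seconds (insole time minus
#'   kinematic time for the same physical instant).
#' @export
synchronize_jumps <- function(kin, insole, window = 30, gravity = 9.806,
                              threshold = 30) {
  fs_k <- rate_of(kin)
  fs_i <- rate_of(insole)
  nk <- min(nrow(kin), round(window * fs_k))
  az <- central_diff2(kin$com_z[1:nk], 1 / fs_k)
  t_k <- kin$time[1:nk]

  kin_landings <- landing_onsets(az > -0.7 * gravity, t_k,
                                 min_flight = 0.1, fs = fs_k)
  f_tot <- insole$vgrf_right + insole$vgrf_left
  ni <- min(length(f_tot), round((window + abs(insole$time[1]) + 5) * fs_i))
  contact <- f_tot[1:ni] >= threshold
  ins_landings <- landing_onsets(contact, insole$time[1:ni],
                                 min_flight = 0.1, fs = fs_i,
                                 values = f_tot[1:ni], level = threshold)
  if (length(kin_landings) == 0L) {
    abort("no jump found in the kinematic stream")
  }
  if (length(ins_landings) == 0L) {
    abort("no jump found in the insole stream")
  }
  m <- min(length(kin_landings), length(ins_landings))
  stats::median(ins_landings[1:m] - kin_landings[1:m])
}

# Onset times of renewed contact after a sustained non-contact interval.
# When the underlying signal and a crossing level are supplied, onsets are
# refined to sub-sample precision by linear interpolation.
landing_onsets <- function(contact, time, min_flight, fs,
                           values = NULL, level = NULL) {
  contact[is.na(contact)] <- TRUE
  onsets <- which(contact & !c(TRUE, contact[-length(contact)]))
  need <- max(1L, round(min_flight * fs))
  keep <- vapply(onsets, function(i) {
    lo <- max(1L, i - need)
    (i - lo) >= need - 1L && all(!contact[lo:(i - 1L)])
  }, logical(1))
  onsets <- onsets[keep]
  if (is.null(values) || length(onsets) == 0L) return(time[onsets])
  vapply(onsets, function(i) {
    if (i == 1L || values[i] <= values[i - 1L]) return(time[i])
    frac <- (level - values[i - 1L]) / (values[i] - values[i - 1L])
    time[i - 1L] + frac * (time[i] - time[i - 1L])
  }, numeric(1))
}

#' Downsample a kinematic recording
#'
#' Integer decimation uses a zero-phase FIR anti-alias filter (applied
#' forwards and backwards) so event times are not biased; non-integer
#' ratios are filtered and then linearly resampled onto the target grid.
#'
#' @param kin A [kin_recording()].
#' @param target Target rate in Hz (default 120).
#' @return A [kin_recording()] at the target rate.
#' @export
downsample_kinematics <- function(kin, target = 120) {
  fs <- rate_of(kin)
  if (!is.numeric(target) || length(target) != 1L || target <= 0) {
    abort("target rate must be a positive number")
  }
  if (target > fs) abort("target rate exceeds the source rate")
  if (abs(target - fs) < 1e-9) return(kin)
  chans <- setdiff(names(kin), "time")
  q <- fs / target
  filt_cols <- function(cutoff) {
    b <- signal::fir1(64, cutoff)
    lapply(kin[chans], function(x) {
      pad <- 80L
      xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(length(x) - pad):(length(x) - 1)]))
      y <- signal::filtfilt(signal::Ma(b), xp)
      y[(pad + 1):(pad + length(x))]
    })
  }
  if (abs(q - round(q)) < 1e-9) {
    q <- as.integer(round(q))
    cols <- filt_cols(0.9 / q)
    idx <- seq(1L, nrow(kin), by = q)
    out <- tibble::as_tibble(c(list(time = kin$time[idx]),
                               lapply(cols, function(x) x[idx])))
  } else {
    cols <- filt_cols(0.9 * target / fs)
    new_t <- seq(kin$time[1], kin$time[nrow(kin)], by = 1 / target)
    out <- tibble::as_tibble(c(
      list(time = new_t),
      lapply(cols, function(x) approx(kin$time, x, xout = new_t)$y)))
  }
  kin_recording(out, target, walk_start = walk_start_of(kin))
}
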