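#' Cut recordings into right-heel-strike-delineated strides
#'
#' Each stride runs from one right heel strike to the next (both endpoints
#' included, so 0% and 100% of gait are successive right heel strikes).
#' Insole samples are attached on the synchronized clock.
#'
#' @param kin A [kin_recording()].
#' @param events A `gait_events` object from [detect_events_kinematic()]
#'   (or constructed from force events).
#' @param insole Optional [insole_recording()].
#' @param clock_offset Insole clock offset (s) from [synchronize_jumps()];
#'   subtracted from insole timestamps before slicing.
#' @return A list of `stride_slice` objects, one per consecutive pair of
#'   right heel strikes.
#' @export
segment_strides <- function(kin, events, insole = NULL, clock_offset = 0) {
  if (!inherits(events, "gait_events")) abort("events must be gait_events")
  validate_events(events)
  rhs <- events$rhs
  if (length(rhs) < 2L) abort("need at least 2 right heel strikes")
  fs <- rate_of(kin)
  ins_time <- if (!is.null(insole)) insole$time - clock_offset else NULL
  lapply(seq_len(length(rhs) - 1L), function(k) {
    i0 <- rhs[k]; i1 <- rhs[k + 1L]
    t0 <- kin$time[i0]; t1 <- kin$time[i1]
    sub_ev <- list(
      rto = events$rto[events$rto > i0 & events$rto < i1],
      lhs = events$lhs[events$lhs > i0 & events$lhs < i1],
      lto = events$lto[events$lto > i0 & events$lto < i1]
    )
    ins <- NULL
    if (!is.null(insole)) {
      sel <- which(ins_time >= t0 & ins_time < t1)
      ins <- tibble::as_tibble(insole[sel, , drop = FALSE])
      ins$time <- ins_time[sel]
    }
    structure(list(kin = tibble::as_tibble(kin[i0:i1, , drop = FALSE]),
                   insole = ins,
                   start_index = i0, end_index = i1,
                   events = sub_ev, sample_rate = fs,
                   insole_rate = if (!is.null(insole)) rate_of(insole),
                   stride = k),
              class = "stride_slice")
  })
}

#' Build the anatomical coordinate frame of one stride
#'
#' The stride frame has its origin at the right heel position at the
#' initial heel strike, z pointing up (against gravity), x the horizontal
#' unit vector along the sacrum displacement over the stride
#' (anterior-posterior), and y = z x x (mediolateral, positive to the
#' walker's left).
#'
#' @param slice A `stride_slice` from [segment_strides()].
#' @return A list with a 3 x 3 `rotation` (rows are the AP/ML/VT axes) and
#'   a length-3 `origin`.
#' @export
build_stride_frame <- function(slice) {
  kin <- slice$kin
  d <- c(kin$sacrum_x[nrow(kin)] - kin$sacrum_x[1],
         kin$sacrum_y[nrow(kin)] - kin$sacrum_y[1])
  nd <- sqrt(sum(d^2))
  if (nd < 1e-6) {
    abort("no horizontal sacrum displacement over the stride (standing?)")
  }
  xhat <- c(d / nd, 0)
  yhat <- c(-xhat[2], xhat[1], 0)
  zhat <- c(0, 0, 1)
  list(rotation = rbind(ap = xhat, ml = yhat, vt = zhat),
       origin = c(kin$rheel_x[1], kin$rheel_y[1], 0))
}

#' Transform a stride slice into its stride frame
#'
#' Applies the rotation and origin shift of [build_stride_frame()] to every
#' landmark triplet of the slice (and to the CoM). Scalar channels are
#' unchanged.
#'
#' @param slice A `stride_slice`.
#' @param frame Optional frame; computed from the slice when missing.
#' @return The slice with transformed kinematic coordinates and the frame
#'   stored as `$frame`.
#' @export
transform_stride <- function(slice, frame = NULL) {
  frame <- frame %||% build_stride_frame(slice)
  slice$kin <- transform_landmarks(slice$kin, frame)
  slice$frame <- frame
  slice
}

transform_landmarks <- function(df, frame) {
  R <- frame$rotation
  o <- frame$origin
  for (lm in kin_landmarks) {
    cols <- paste(lm, c("x", "y", "z"), sep = "_")
    if (!all(cols %in% names(df))) next
    p <- t(cbind(df[[cols[1]]] - o[1], df[[cols[2]]] - o[2],
                 df[[cols[3]]] - o[3]))
    q <- R %*% p
    df[[cols[1]]] <- q[1, ]
    df[[cols[2]]] <- q[2, ]
    df[[cols[3]]] <- q[3, ]
  }
  df
}

#' Resample one stride to percent gait
#'
#' Kinematic channels are resampled by cubic-spline interpolation onto
#' `n_points` uniform points spanning heel strike to heel strike (0-100%);
#' insole channels are linearly interpolated (their contact transients are
#' not smooth). The first and last samples equal the original boundary
#' samples, and event times become percent-gait phases.
#'
#' @param slice A `stride_slice` (ideally already in its stride frame).
#' @param n_points Number of percent-gait samples (default 101, i.e. 0-100%
#'   in 1% steps).
#' @return A `gait_stride` tibble with a `percent` column, one column per
#'   channel, and stride metadata in attributes (`duration`, `events_pct`,
#'   `frame`).
#' @export
normalize_percent_gait <- function(slice, n_points = 101L) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L) abort("n_points must be >= 2")
  kin <- slice$kin
  t0 <- kin$time[1]
  t1 <- kin$time[nrow(kin)]
  if (t1 <= t0) abort("stride duration must be positive")
  tq <- seq(t0, t1, length.out = n_points)
  out <- tibble::tibble(percent = seq(0, 100, length.out = n_points))
  for (ch in setdiff(names(kin), "time")) {
    out[[ch]] <- spline(kin$time, kin[[ch]], xout = tq, method = "fmm")$y
    out[[ch]][c(1L, n_points)] <- kin[[ch]][c(1L, nrow(kin))]
  }
  if (!is.null(slice$insole)) {
    for (ch in setdiff(names(slice$insole), "time")) {
      out[[ch]] <- approx(slice$insole$time, slice$insole[[ch]], xout = tq,
                          rule = 2)$y
    }
  }
  ev_pct <- lapply(slice$events, function(i) {
    if (length(i) == 0L) return(numeric())
    (i - slice$start_index) / (slice$end_index - slice$start_index) * 100
  })
  structure(out,
            duration = t1 - t0,
            events_pct = ev_pct,
            frame = slice$frame,
            stride = slice$stride,
            class = c("gait_stride", class(out)))
}

#' Per-stride leg length
#'
#' The inverted-pendulum leg length of a stride: the mean Euclidean
#' distance from the stance-foot fifth-metatarsal marker to the CoM over
#' the stance phase of that foot (right heel strike to right toe-off).
#'
#' @param slice A `stride_slice` with a right toe-off event.
#' @return Leg length in metres.
#' @export
compute_leg_length <- function(slice) {
  kin <- slice$kin
  need <- c("rmet5_x", "rmet5_y", "rmet5_z", "com_x", "com_y", "com_z")
  if (!all(need %in% names(kin))) {
    abort("missing fifth-metatarsal or CoM landmark for leg length")
  }
  if (nrow(kin) < 2L) abort("degenerate stride: too few samples")
  rto <- slice$events$rto
  end <- if (length(rto) >= 1L) rto[1] - slice$start_index + 1L else nrow(kin)
  end <- min(max(end, 2L), nrow(kin))
  sel <- 1:end
  mean(sqrt((kin$com_x[sel] - kin$rmet5_x[sel])^2 +
              (kin$com_y[sel] - kin$rmet5_y[sel])^2 +
              (kin$com_z[sel] - kin$rmet5_z[sel])^2))
}
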