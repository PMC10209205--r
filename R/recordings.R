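#' Kinematic and insole recording containers
#'
#' Recordings are tibbles of synchronized time series with a sampling rate
#' attribute. A kinematic recording holds 3-D landmark positions (metres) of
#' the whole-body centre of mass (CoM), heels, fifth and first metatarsals,
#' sacrum, hip joint centres and C7, plus the mediolateral trunk angular
#' velocity in deg/s. An insole recording holds per-foot vertical ground
#' reaction force (N) and mediolateral centre of pressure (m).
#'
#' @param data A data frame with a `time` column (seconds) and the channel
#'   columns. Kinematic landmark columns follow the `<landmark>_<axis>`
#'   naming scheme, e.g. `com_x`, `rheel_z`; insole columns are
#'   `vgrf_right`, `cop_ml_right`, `vgrf_left`, `cop_ml_left`.
#' @param sample_rate Sampling rate in Hz.
#' @param walk_start Time (s) at which steady walking begins; earlier samples
#'   hold the synchronization jumps. Default 0.
#' @return A tibble of class `kin_recording` or `insole_recording`.
#' @name recordings
NULL

kin_landmarks <- c(
  "com", "sacrum", "c7", "rhip", "lhip",
  "rheel", "rmet5", "rmet1", "lheel", "lmet5", "lmet1"
)

kin_channel_names <- function() {
  c(paste(rep(kin_landmarks, each = 3L), c("x", "y", "z"), sep = "_"),
    "trunk_omega_ml")
}

#' @rdname recordings
#' @export
kin_recording <- function(data, sample_rate, walk_start = 0) {
  data <- tibble::as_tibble(data)
  need <- c("time", kin_channel_names())
  missing <- setdiff(need, names(data))
  if (length(missing) > 0L) {
    abort(paste0("kinematic recording is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    abort("sample_rate must be a positive number")
  }
  structure(data,
            sample_rate = sample_rate,
            walk_start = walk_start,
            class = c("kin_recording", class(tibble::tibble())))
}

#' @rdname recordings
#' @export
insole_recording <- function(data, sample_rate, walk_start = 0) {
  data <- tibble::as_tibble(data)
  need <- c("time", "vgrf_right", "cop_ml_right", "vgrf_left", "cop_ml_left")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0L) {
    abort(paste0("insole recording is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(stats::na.omit(c(data$vgrf_right, data$vgrf_left)) < -1e-9)) {
    abort("vertical ground reaction forces must be non-negative")
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    abort("sample_rate must be a positive number")
  }
  structure(data,
            sample_rate = sample_rate,
            walk_start = walk_start,
            class = c("insole_recording", class(tibble::tibble())))
}

#' @export
print.kin_recording <- function(x, ...) {
  cat(sprintf("<kinematic recording: %d samples @ %g Hz, %.1f s>\n",
              nrow(x), attr(x, "sample_rate"),
              nrow(x) / attr(x, "sample_rate")))
  NextMethod()
}

#' @export
print.insole_recording <- function(x, ...) {
  cat(sprintf("<insole recording: %d samples @ %g Hz, %.1f s>\n",
              nrow(x), attr(x, "sample_rate"),
              nrow(x) / attr(x, "sample_rate")))
  NextMethod()
}

rate_of <- function(rec) attr(rec, "sample_rate")
walk_start_of <- function(rec) attr(rec, "walk_start") %||% 0
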