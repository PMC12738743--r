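# S3 containers shared by the modules. Plain lists with validators, in the
# style of small rOpenSci packages: constructors check invariants once, the
# pipeline then trusts the classes.

#' Construct an IMU recording
#'
#' A fixed-rate triaxial inertial recording as produced by an ankle- or
#' wrist-worn sensor: acceleration in g, angular velocity in degrees/s, and
#' the sensor-to-global orientation as scalar-first unit quaternions.
#'
#' @param t time stamps in seconds (uniform grid)
#' @param accel n x 3 acceleration in g (sensor frame)
#' @param gyro n x 3 angular velocity in degrees/s (sensor frame)
#' @param quat n x 4 unit quaternions (w, x, y, z), sensor -> global
#' @param fs sampling rate in Hz
#' @param task `"FS"` (foot stomping) or `"HPS"` (hand pronation-supination)
#' @param placement `"ankle"` or `"wrist"`
#' @param side `"left"` or `"right"`
#' @return object of class `imu_recording`
#' @export
imu_recording <- function(t, accel, gyro, quat, fs,
                          task = c("FS", "HPS"),
                          placement = c("ankle", "wrist"),
                          side = c("left", "right")) {
  task <- match.arg(task)
  placement <- match.arg(placement)
  side <- match.arg(side)
  accel <- as.matrix(accel); gyro <- as.matrix(gyro); quat <- as.matrix(quat)
  n <- length(t)
  if (nrow(accel) != n || nrow(gyro) != n || nrow(quat) != n) {
    stop("t, accel, gyro and quat must have the same number of samples")
  }
  if (fs <= 0) stop("fs must be positive")
  qn <- sqrt(rowSums(quat^2))
  if (any(abs(qn - 1) > 1e-3)) {
    stop("quaternion norms deviate from 1 by more than 1e-3")
  }
  structure(list(t = as.numeric(t), accel = accel, gyro = gyro, quat = quat,
                 fs = fs, task = task, placement = placement, side = side),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> task=%s placement=%s side=%s\n",
              x$task, x$placement, x$side))
  cat(sprintf("  %d samples @ %g Hz (%.2f s)\n",
              length(x$t), x$fs, diff(range(x$t))))
  invisible(x)
}

#' Construct a movement signal
#'
#' A processed time series on its way from raw IMU data to kinematic
#' metrics. `value` is either a vector (one axis) or an n x 3 matrix.
#'
#' @param t time stamps in seconds
#' @param value numeric vector or n x 3 matrix
#' @param fs sampling rate in Hz
#' @param frame `"sensor"` or `"global"`
#' @param units unit string, e.g. `"g"`, `"m/s^2"`, `"deg/s"`
#' @param task task label carried through the pipeline
#' @return object of class `movement_signal`
#' @export
movement_signal <- function(t, value, fs, frame = c("sensor", "global"),
                            units = "m/s^2", task = "FS") {
  frame <- match.arg(frame)
  if (is.matrix(value)) {
    if (nrow(value) != length(t)) stop("value and t length mismatch")
  } else if (length(value) != length(t)) {
    stop("value and t length mismatch")
  }
  if (anyNA(value)) stop("movement signals must not contain NA")
  structure(list(t = as.numeric(t), value = value, fs = fs, frame = frame,
                 units = units, task = task),
            class = "movement_signal")
}

#' @export
print.movement_signal <- function(x, ...) {
  dims <- if (is.matrix(x$value)) paste0(ncol(x$value), " axes") else "1 axis"
  cat(sprintf("<movement_signal> %s, %s frame, %s, %d samples @ %g Hz\n",
              dims, x$frame, x$units, length(x$t), x$fs))
  invisible(x)
}

#' Construct an LFP session
#'
#' A subthalamic local field potential session: a 2 Hz band-power stream
#' (power in a 5 Hz band centered on the individual beta-peak), an optional
#' raw time-domain channel, and the labelled protocol segments.
#'
#' @param beta_peak_hz individual beta-peak frequency in Hz
#' @param band_power data.frame with columns `t_s`, `power`
#' @param segments data.frame with columns `block`, `label`, `t_start_s`,
#'   `t_end_s` (half-open windows)
#' @param raw optional list with `fs` and `values` (time-domain LFP)
#' @param normalized logical; whether `band_power` is baseline-normalized
#' @return object of class `lfp_session`
#' @export
lfp_session <- function(beta_peak_hz, band_power, segments, raw = NULL,
                        normalized = FALSE) {
  band <- feedback_band(beta_peak_hz)
  stopifnot(is.data.frame(band_power),
            all(c("t_s", "power") %in% names(band_power)))
  segments <- validate_segments(segments)
  if (!is.null(raw)) stopifnot(is.list(raw), !is.null(raw$fs),
                               !is.null(raw$values))
  structure(list(beta_peak_hz = beta_peak_hz,
                 band_low_hz = band[1], band_high_hz = band[2],
                 band_power = band_power, segments = segments, raw = raw,
                 normalized = normalized),
            class = "lfp_session")
}

#' @export
print.lfp_session <- function(x, ...) {
  cat(sprintf("<lfp_session> beta peak %.2f Hz (band %.2f-%.2f Hz)\n",
              x$beta_peak_hz, x$band_low_hz, x$band_high_hz))
  cat(sprintf("  %d band-power samples, %d segments, raw channel: %s\n",
              nrow(x$band_power), nrow(x$segments),
              if (is.null(x$raw)) "absent" else sprintf("%g Hz", x$raw$fs)))
  if (x$normalized) cat("  baseline-normalized\n")
  invisible(x)
}

# Shared validator for protocol/segment tables: non-overlap within block.
validate_segments <- function(segments) {
  req <- c("block", "label", "t_start_s", "t_end_s")
  if (!all(req %in% names(segments))) {
    stop("segments must have columns ", paste(req, collapse = ", "))
  }
  if (any(segments$t_end_s <= segments$t_start_s)) {
    stop("segment end must exceed segment start")
  }
  for (blk in unique(segments$block)) {
    s <- segments[segments$block == blk, ]
    s <- s[order(s$t_start_s), ]
    if (nrow(s) > 1 && any(s$t_start_s[-1] < s$t_end_s[-nrow(s)] - 1e-9)) {
      stop("overlapping segments in block '", blk, "'")
    }
  }
  segments
}
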