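# Preprocessing chain for raw IMU streams, in the fixed order the metrics
# assume: (i) quaternion transformation from the sensor to the global frame,
# (ii) conversion from g to m/s^2 with (iii) gravity compensation (9.81
# subtracted from the global z-axis), (iv) zero-phase high-pass filtering at
# 0.5 Hz. Task windows are cut before downsampling to 50 Hz. The
# accelerometer path (foot stomping) uses all four steps; the gyroscope
# path (pronation-supination) uses only the frame transformation and the
# high-pass filter.

GRAVITY <- 9.81  # m/s^2, fixed

#' Rotate an IMU recording into the global frame
#'
#' Applies the per-sample orientation quaternion to the acceleration (and
#' gyroscope) samples, yielding global-frame series. Acceleration stays in
#' g; the gyroscope stays in degrees/s.
#'
#' @param rec an [imu_recording]
#' @param sensor `"accel"` or `"gyro"`: which stream to return as the
#'   movement signal
#' @return a [movement_signal] in the global frame
#' @examples
#' sim <- gen_fs_recording(seed = 1)
#' sig <- to_global_frame(sim$recording)
#' @export
to_global_frame <- function(rec, sensor = c("accel", "gyro")) {
  sensor <- match.arg(sensor)
  stopifnot(inherits(rec, "imu_recording"))
  qn <- sqrt(rowSums(rec$quat^2))
  bad <- which(abs(qn - 1) > 1e-2)
  if (length(bad)) {
    stop("quaternion norm deviates from 1 by more than 1e-2 at sample ",
         bad[1])
  }
  quat <- rec$quat / qn
  value <- quat_rotate(quat, rec[[sensor]])
  movement_signal(rec$t, value, rec$fs, frame = "global",
                  units = if (sensor == "accel") "g" else "deg/s",
                  task = rec$task)
}

#' Convert to m/s^2 and compensate gravity
#'
#' Multiplies a global-frame acceleration signal in g by 9.81 and subtracts
#' 9.81 m/s^2 from the global z-axis. After this step a resting sensor
#' reads (0, 0, 0).
#'
#' @param sig a global-frame [movement_signal] in g
#' @return a [movement_signal] in m/s^2
#' @export
gravity_compensate <- function(sig) {
  stopifnot(inherits(sig, "movement_signal"))
  if (sig$frame != "global") {
    stop("gravity compensation requires a global-frame signal")
  }
  if (sig$units != "g") stop("expected acceleration in g, got ", sig$units)
  value <- sig$value * GRAVITY
  if (is.matrix(value)) value[, 3] <- value[, 3] - GRAVITY
  else value <- value - GRAVITY
  movement_signal(sig$t, value, sig$fs, frame = "global",
                  units = "m/s^2", task = sig$task)
}

#' Zero-phase high-pass filter
#'
#' 4th-order Butterworth applied forward-backward (zero phase, so peak
#' timing is preserved). Removes low-frequency drift below the cutoff while
#' preserving the passband within 1 percent above twice the cutoff.
#'
#' @param sig a [movement_signal]
#' @param cutoff cutoff frequency in Hz
#' @param order filter order (of one pass)
#' @return filtered [movement_signal]
#' @export
highpass <- function(sig, cutoff = 0.5, order = 4) {
  stopifnot(inherits(sig, "movement_signal"))
  if (cutoff >= sig$fs / 2) stop("cutoff must be below Nyquist")
  hp <- butter_design(order, cutoff, sig$fs, "high")
  value <- if (is.matrix(sig$value)) {
    apply(sig$value, 2, function(col) filtfilt(hp$b, hp$a, col))
  } else {
    filtfilt(hp$b, hp$a, sig$value)
  }
  movement_signal(sig$t, value, sig$fs, frame = sig$frame,
                  units = sig$units, task = sig$task)
}

#' Downsample a movement signal
#'
#' Fourier-domain resampling to the target rate: the spectrum is truncated
#' at the new Nyquist frequency (ideal anti-alias filter), so tones below
#' the new Nyquist are preserved within 1 percent regardless of whether the
#' decimation ratio is an integer.
#'
#' @param sig a [movement_signal]
#' @param target_fs target sampling rate in Hz (<= current rate)
#' @return resampled [movement_signal] at `target_fs`
#' @export
downsample <- function(sig, target_fs = 50) {
  stopifnot(inherits(sig, "movement_signal"))
  if (target_fs > sig$fs) stop("target_fs exceeds the current rate")
  if (target_fs == sig$fs) return(sig)
  n_out <- max(2L, round(length(sig$t) * target_fs / sig$fs))
  t_out <- sig$t[1] + (seq_len(n_out) - 1) / target_fs
  value <- if (is.matrix(sig$value)) {
    apply(sig$value, 2, fft_resample, n_out = n_out)
  } else {
    fft_resample(sig$value, n_out)
  }
  movement_signal(t_out, value, target_fs, frame = sig$frame,
                  units = sig$units, task = sig$task)
}

#' Locate the active-movement window of a task recording
#'
#' With `protocol_hint` given (manual segmentation), the hint is returned
#' verbatim. Otherwise the window is found automatically as the smallest
#' interval containing all samples whose moving-RMS envelope (250 ms
#' window) exceeds 5 times the median envelope of the first 0.5 s of the
#' recording, a deterministic stand-in for visual segmentation.
#'
#' @param sig a [movement_signal] (vector or matrix; matrices use the
#'   per-sample Euclidean norm)
#' @param protocol_hint optional numeric `c(t_start, t_end)` in seconds
#' @param envelope_s moving-RMS window in seconds
#' @param threshold_factor multiple of the quiet-period envelope median
#' @param pad_s margin added on both sides of the detected window so that
#'   the onset/offset ramps of the first and last movement stay inside
#' @return numeric vector `c(t_start, t_end)` in seconds
#' @export
segment_task <- function(sig, protocol_hint = NULL, envelope_s = 0.25,
                         threshold_factor = 5, pad_s = 0.25) {
  stopifnot(inherits(sig, "movement_signal"))
  if (!is.null(protocol_hint)) {
    stopifnot(length(protocol_hint) == 2, protocol_hint[1] < protocol_hint[2])
    return(as.numeric(protocol_hint))
  }
  if (diff(range(sig$t)) < 1) stop("signal shorter than 1 s")
  x <- if (is.matrix(sig$value)) sqrt(rowSums(sig$value^2)) else
    abs(sig$value)
  env <- moving_rms(x, round(envelope_s * sig$fs))
  quiet <- env[sig$t <= sig$t[1] + 0.5]
  # floor at 5 percent of the envelope peak: with near-noiseless input the
  # quiet-period threshold goes to zero and the zero-phase filter's ringing
  # tails would otherwise inflate the window
  thr <- max(threshold_factor * stats::median(quiet), 0.05 * max(env))
  active <- which(env > thr)
  if (length(active) == 0) stop("no active movement detected")
  c(max(sig$t[1], sig$t[active[1]] - pad_s),
    min(sig$t[length(sig$t)], sig$t[active[length(active)]] + pad_s))
}

#' Crop a movement signal to a time window
#'
#' @param sig a [movement_signal]
#' @param window numeric `c(t_start, t_end)` (half-open at neither end)
#' @return cropped [movement_signal]
#' @export
crop_signal <- function(sig, window) {
  keep <- sig$t >= window[1] & sig$t <= window[2]
  if (!any(keep)) stop("window contains no samples")
  value <- if (is.matrix(sig$value)) sig$value[keep, , drop = FALSE] else
    sig$value[keep]
  movement_signal(sig$t[keep], value, sig$fs, frame = sig$frame,
                  units = sig$units, task = sig$task)
}

#' Run the full task-specific preprocessing chain
#'
#' Foot stomping: frame transformation, gravity compensation, 0.5 Hz
#' high-pass, task segmentation, downsampling to 50 Hz. Pronation-
#' supination: frame transformation and high-pass only (gyroscope path),
#' then segmentation and downsampling.
#'
#' @param rec an [imu_recording]
#' @param window optional manual task window `c(t_start, t_end)`
#' @param target_fs analysis sampling rate in Hz
#' @param cutoff high-pass cutoff in Hz
#' @return a [movement_signal] at `target_fs` (3-axis matrix)
#' @export
preprocess_recording <- function(rec, window = NULL, target_fs = 50,
                                 cutoff = 0.5) {
  sig <- if (rec$task == "FS") {
    highpass(gravity_compensate(to_global_frame(rec, "accel")), cutoff)
  } else {
    highpass(to_global_frame(rec, "gyro"), cutoff)
  }
  window <- segment_task(sig, protocol_hint = window)
  downsample(crop_signal(sig, window), target_fs)
}
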