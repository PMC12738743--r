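# Bradykinesia-aligned movement-quality metrics. Each operation is the
# literal published formula; compute_metric_set() orchestrates the
# task-specific chain and fills one metric row per task execution.

#' Euclidean magnitude of a triaxial series
#'
#' `sqrt(x^2 + y^2 + z^2)` element-wise.
#'
#' @param x,y,z component series of equal length
#' @return numeric magnitude series
#' @examples
#' vector_magnitude(3, 4, 0)  # 5
#' @export
vector_magnitude <- function(x, y, z) {
  if (length(y) != length(x) || length(z) != length(x)) {
    stop("component series must have equal length")
  }
  sqrt(x^2 + y^2 + z^2)
}

#' Movement rate
#'
#' `Rate = N_peaks / T` with `T` the task-window duration in seconds.
#'
#' @param n_peaks number of detected movements
#' @param duration window duration in seconds (> 0)
#' @return rate in 1/s
#' @export
movement_rate <- function(n_peaks, duration) {
  if (duration <= 0) stop("duration must be positive")
  n_peaks / duration
}

#' Mean peak velocity
#'
#' Arithmetic mean of the per-movement peak speeds.
#'
#' @param segments data.frame from [build_segments()]
#' @return mean peak speed (m/s or degrees/s)
#' @export
mean_peak <- function(segments) {
  if (NROW(segments) == 0) stop("no movement segments")
  mean(segments$peak_speed)
}

#' Mean movement amplitude
#'
#' Mean of the unsigned per-movement amplitudes `A_i`.
#'
#' @param segments data.frame from [build_segments()]
#' @return mean amplitude (m or degrees)
#' @export
mean_amplitude <- function(segments) {
  if (NROW(segments) == 0) stop("no movement segments")
  mean(abs(segments$amplitude))
}

#' Total displacement travelled
#'
#' `sum |x_i - x_(i-1)|` over the displacement series of the task window.
#'
#' @param displacement displacement series (m or degrees)
#' @return total path length in displacement units
#' @export
total_displacement <- function(displacement) {
  if (length(displacement) < 2) stop("displacement series too short")
  sum(abs(diff(displacement)))
}

#' Spectral arc length (SPARC)
#'
#' Movement smoothness as the negative arc length of the normalized
#' magnitude spectrum of the speed profile, restricted to an adaptive
#' cutoff: frequencies up to `fc` are considered, then trimmed to the last
#' frequency whose normalized amplitude exceeds `amp_th`. More negative
#' values indicate less smooth movement; the measure is invariant to
#' amplitude and temporal scaling.
#'
#' @param speed non-negative speed profile (m/s or degrees/s)
#' @param fs sampling rate in Hz
#' @param padlevel zero-padding exponent added to the FFT length
#' @param fc maximum frequency considered, in Hz
#' @param amp_th adaptive amplitude threshold on the normalized spectrum
#' @return SPARC value (<= 0, unitless)
#' @export
sparc <- function(speed, fs, padlevel = 4, fc = 10, amp_th = 0.05) {
  if (all(speed == 0)) stop("speed profile is identically zero")
  nfft <- 2^ceiling(log2(length(speed)) + padlevel)
  f <- seq(0, fs * (nfft - 1) / nfft, length.out = nfft)
  Mf <- Mod(stats::fft(c(speed, rep(0, nfft - length(speed)))))
  Mf <- Mf / max(Mf)
  sel <- which(f <= fc)
  f_sel <- f[sel]; M_sel <- Mf[sel]
  above <- which(M_sel >= amp_th)
  rng <- above[1]:above[length(above)]
  f_sel <- f_sel[rng]; M_sel <- M_sel[rng]
  frange <- f_sel[length(f_sel)] - f_sel[1]
  -sum(sqrt((diff(f_sel) / frange)^2 + diff(M_sel)^2))
}

#' Log-dimensionless jerk of a velocity profile
#'
#' `-ln( (T^3 / v_peak^2) * integral of squared jerk )`, with jerk the
#' second time-derivative of velocity (central differences), `T` the window
#' duration and `v_peak` the absolute peak velocity. Dimensionless by
#' construction and invariant to amplitude scaling; closer to zero means
#' smoother movement.
#'
#' @param velocity velocity series (m/s or degrees/s)
#' @param fs sampling rate in Hz
#' @return log-dimensionless jerk (unitless)
#' @export
log_dimensionless_jerk <- function(velocity, fs) {
  n <- length(velocity)
  if (n < 5) stop("velocity series too short")
  vpeak <- max(abs(velocity))
  if (vpeak == 0) stop("velocity is identically zero")
  dt <- 1 / fs
  grad <- function(x) {
    n <- length(x)
    c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / dt
  }
  jerk <- grad(grad(velocity))
  T_dur <- (n - 1) * dt
  integral <- sum((jerk[-1]^2 + jerk[-n]^2) / 2) * dt
  -log(T_dur^3 / vpeak^2 * integral)
}

#' Inter-movement intervals and halts
#'
#' `MeanInterval` is the mean of successive peak-time differences. A halt
#' is an interval strictly exceeding `mu + 2 * sigma`, with `mu` and
#' `sigma` the mean and standard deviation of all intervals.
#'
#' @param peak_times movement times in seconds (>= 2)
#' @return list with `mean_interval_s` and `n_halts`
#' @export
intervals_and_halts <- function(peak_times) {
  if (length(peak_times) < 2) stop("need at least two movements")
  iv <- diff(peak_times)
  mu <- mean(iv)
  sigma <- stats::sd(iv)
  if (length(iv) == 1) sigma <- 0
  list(mean_interval_s = mu, n_halts = sum(iv > mu + 2 * sigma))
}

#' Amplitude decrement
#'
#' `Delta A` is the mean amplitude of the first half of the movements minus
#' the mean of the second half (odd counts assign the middle movement to
#' the first half). The slope is the ordinary least-squares slope of
#' amplitude against peak time, `A(t) = m t + b`.
#'
#' @param segments data.frame from [build_segments()] (>= 2 rows)
#' @param peak_times regression abscissa; defaults to the segment peak times
#' @return list with `amplitude_change` and `amplitude_slope`
#' @export
decrement <- function(segments, peak_times = segments$t_peak) {
  n <- NROW(segments)
  if (n < 2) stop("need at least two movements")
  amps <- abs(segments$amplitude)
  first <- seq_len(ceiling(n / 2))
  dA <- mean(amps[first]) - mean(amps[-first])
  ct <- peak_times - mean(peak_times)
  m <- sum(ct * (amps - mean(amps))) / sum(ct^2)
  list(amplitude_change = dA, amplitude_slope = m)
}

# Pick the analysis axis: global vertical for the accelerometer path,
# largest-variance axis for the gyroscope path (sensors are aligned to the
# main axis of motion, but the bookkeeping is not guaranteed).
select_axis <- function(sig, axis = c("auto", "x", "y", "z")) {
  axis <- match.arg(axis)
  col <- switch(axis,
                auto = if (sig$task == "FS") 3L else
                  which.max(apply(sig$value, 2, stats::var)),
                x = 1L, y = 2L, z = 3L)
  movement_signal(sig$t, sig$value[, col], sig$fs, frame = sig$frame,
                  units = sig$units, task = sig$task)
}

#' Compute the full movement-quality metric set
#'
#' Runs the task-specific chain on one recording: preprocessing, peak
#' detection on a moving-RMS envelope of the analysis axis, zero-update
#' double integration (FS) or single gyroscope integration (HPS), and all
#' summary metrics.
#'
#' @param rec an [imu_recording]
#' @param window optional manual task window `c(t_start, t_end)` in seconds
#' @param target_fs analysis rate in Hz
#' @param min_distance minimum peak distance in seconds
#' @param min_prominence minimum envelope peak prominence; default
#'   2 x MAD of the envelope
#' @param envelope_s moving-RMS envelope window in seconds
#' @param axis analysis axis selection (`"auto"` or `"x"`, `"y"`, `"z"`)
#' @return object of class `metric_set`: one-row data.frame with columns
#'   `task`, `magnitude_mean`, `rate_per_s`, `mean_peak_velocity`,
#'   `mean_amplitude`, `total_displacement`, `sparc`,
#'   `log_dimensionless_jerk`, `n_halts`, `mean_interval_s`,
#'   `amplitude_change`, `amplitude_slope`, `n_movements`
#' @examples
#' sim <- gen_fs_recording(seed = 1)
#' compute_metric_set(sim$recording)
#' @export
compute_metric_set <- function(rec, window = NULL, target_fs = 50,
                               min_distance = 0.25, min_prominence = NULL,
                               envelope_s = 0.15, axis = "auto") {
  sig3 <- preprocess_recording(rec, window = window, target_fs = target_fs)
  mag <- vector_magnitude(sig3$value[, 1], sig3$value[, 2], sig3$value[, 3])
  ax <- select_axis(sig3, axis)
  # FS: impacts produce oscillatory acceleration bursts, so strikes are
  # localized on a moving-RMS envelope; HPS: each turn is already a single
  # smooth angular-velocity lobe, so peaks come from the rectified signal.
  det <- if (rec$task == "FS") {
    movement_signal(ax$t, moving_rms(ax$value, round(envelope_s * ax$fs)),
                    ax$fs, frame = ax$frame, units = ax$units,
                    task = ax$task)
  } else ax
  peaks <- detect_peaks(det, min_distance = min_distance,
                        min_prominence = min_prominence)
  if (length(peaks) == 0) stop("no movements detected in the task window")
  series <- if (rec$task == "FS") integrate_zupt(ax, peaks) else
    angular_displacement(ax, peaks)
  segments <- build_segments(series, peaks)
  duration <- diff(range(sig3$t))
  speed <- abs(series$velocity)
  ih <- if (nrow(segments) >= 2) intervals_and_halts(segments$t_peak) else
    list(mean_interval_s = NA_real_, n_halts = NA_integer_)
  dec <- if (nrow(segments) >= 2) decrement(segments) else
    list(amplitude_change = NA_real_, amplitude_slope = NA_real_)
  # rate: for trains of >= 2 movements the window-independent estimator
  # N / (peak span + one mean interval) = 1 / mean interval; single
  # movements fall back to the raw window duration
  rate_T <- if (nrow(segments) >= 2) {
    nrow(segments) * mean(diff(segments$t_peak))
  } else duration
  out <- data.frame(
    task = rec$task,
    magnitude_mean = mean(mag),
    rate_per_s = movement_rate(nrow(segments), rate_T),
    mean_peak_velocity = mean_peak(segments),
    mean_amplitude = mean_amplitude(segments),
    total_displacement = total_displacement(series$displacement),
    sparc = sparc(speed, sig3$fs),
    log_dimensionless_jerk = log_dimensionless_jerk(series$velocity,
                                                    sig3$fs),
    n_halts = ih$n_halts,
    mean_interval_s = ih$mean_interval_s,
    amplitude_change = dec$amplitude_change,
    amplitude_slope = dec$amplitude_slope,
    n_movements = nrow(segments))
  class(out) <- c("metric_set", "data.frame")
  out
}
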