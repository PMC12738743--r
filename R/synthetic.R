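# Synthetic IMU and LFP generators with closed-form ground truth. The
# generators state the world the downstream pipeline assumes: compact
# smooth movement pulses whose integrals are known analytically, and an LFP
# made of a 1/f background plus a beta-peak sinusoid whose amplitude is
# modulated per protocol segment. All randomness flows from one explicit
# seed; the caller's RNG state is left untouched.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Ground truth for a synthetic foot-stomping recording
#'
#' @param step_times stomp center times in seconds (strictly increasing)
#' @param step_heights vertical step heights in meters (positive)
#' @param peak_velocities per-step peak vertical velocity in m/s
#' @param injected_halt_indices indices of artificially stretched intervals
#' @param decrement_slope scheduled amplitude slope in m/s
#' @return object of class `fs_ground_truth`
#' @export
fs_ground_truth <- function(step_times, step_heights, peak_velocities,
                            injected_halt_indices = integer(0),
                            decrement_slope = 0) {
  n <- length(step_times)
  stopifnot(length(step_heights) == n, length(peak_velocities) == n,
            all(diff(step_times) > 0), all(step_heights > 0))
  structure(list(step_times = step_times, step_heights = step_heights,
                 peak_velocities = peak_velocities,
                 injected_halt_indices = as.integer(injected_halt_indices),
                 decrement_slope = decrement_slope, n_steps = n),
            class = "fs_ground_truth")
}

#' Ground truth for a synthetic pronation-supination recording
#'
#' @param turn_times turn center times in seconds (strictly increasing)
#' @param turn_amplitudes signed turn angles in degrees (alternating sign)
#' @param peak_angular_velocities per-turn peak angular speed in degrees/s
#' @return object of class `hps_ground_truth`
#' @export
hps_ground_truth <- function(turn_times, turn_amplitudes,
                             peak_angular_velocities) {
  n <- length(turn_times)
  stopifnot(length(turn_amplitudes) == n,
            length(peak_angular_velocities) == n,
            all(diff(turn_times) > 0))
  if (n > 1 && any(sign(turn_amplitudes[-1]) ==
                     sign(turn_amplitudes[-n]))) {
    stop("turn amplitudes must alternate in sign")
  }
  structure(list(turn_times = turn_times, turn_amplitudes = turn_amplitudes,
                 peak_angular_velocities = peak_angular_velocities,
                 n_turns = n),
            class = "hps_ground_truth")
}

#' Ground truth for a synthetic LFP session
#'
#' @param beta_peak_hz beta-peak frequency in Hz (13-30)
#' @param modulation named numeric vector of multiplicative beta-amplitude
#'   factors; names are `"block.label"` (e.g. `"nf3.nf"`) or a bare segment
#'   label applying to every block (e.g. `"nf"`). Unlisted segments use 1.
#' @param background_exponent spectral exponent of the 1/f background
#' @return object of class `lfp_ground_truth`
#' @export
lfp_ground_truth <- function(beta_peak_hz = 20,
                             modulation = c(nf = 0.85),
                             background_exponent = 1) {
  if (beta_peak_hz < 13 || beta_peak_hz > 30) {
    stop("beta_peak_hz must lie in the 13-30 Hz beta band")
  }
  if (any(modulation <= 0)) stop("modulation factors must be positive")
  structure(list(beta_peak_hz = beta_peak_hz, modulation = modulation,
                 background_exponent = background_exponent),
            class = "lfp_ground_truth")
}

# One stomp as a raised-cosine velocity lobe pair on [0, Tp]:
#   v(tau) =  v_p * sin^2(2*pi*tau/Tp)   for tau <= Tp/2  (up-stroke)
#   v(tau) = -v_p * sin^2(2*pi*tau/Tp)   for tau >  Tp/2  (down-stroke)
# with v_p = 4*h/Tp. Velocity and acceleration are zero at both pulse ends
# (so concatenation with rest is C1-continuous), the foot rises to exactly
# h at Tp/2 and returns to rest with zero net velocity and displacement.
fs_pulse_accel <- function(tau, h, Tp) {
  v_p <- 4 * h / Tp
  sgn <- ifelse(tau <= Tp / 2, 1, -1)
  sgn * v_p * (2 * pi / Tp) * sin(4 * pi * tau / Tp)
}

#' Generate a synthetic foot-stomping recording
#'
#' Emulates ten seated full-foot stomps recorded by an ankle IMU at 200 Hz:
#' a train of smooth vertical pulses with scheduled heights, optional
#' amplitude decrement and injected halts, gravity expressed in the sensor
#' frame through a (optionally drifting) orientation, and additive Gaussian
#' sensor noise.
#'
#' @param n_steps number of stomps (>= 1)
#' @param rate_hz scheduled stomp rate in Hz
#' @param base_height height of the first step in meters
#' @param decrement_slope amplitude slope in m/s (negative = decrement)
#' @param halt_spec optional `list(index =, factor =)`: the interval after
#'   step `index` is multiplied by `factor` (> 1 injects a halt)
#' @param noise_sd accelerometer noise SD in m/s^2
#' @param seed integer seed; all randomness derives from it
#' @param fs sampling rate in Hz
#' @param pulse_s stomp pulse duration in seconds
#' @param tilt_deg fixed sensor tilt about the global x-axis in degrees
#' @param drift_dps slow orientation drift about the global z-axis in
#'   degrees/s
#' @param margin_s quiet margin before the first and after the last stomp
#' @param side recorded body side
#' @return list with elements `recording` ([imu_recording]) and `truth`
#'   ([fs_ground_truth])
#' @examples
#' sim <- gen_fs_recording(n_steps = 10, rate_hz = 1.5, seed = 1)
#' sim$truth$n_steps
#' @export
gen_fs_recording <- function(n_steps = 10, rate_hz = 1.5,
                             base_height = 0.12, decrement_slope = 0,
                             halt_spec = NULL, noise_sd = 0.1, seed = 1,
                             fs = 200, pulse_s = 0.3, tilt_deg = 10,
                             drift_dps = 0.5, margin_s = 1,
                             side = "right") {
  stopifnot(n_steps >= 1, rate_hz > 0, fs > 0, base_height > 0)
  if (pulse_s >= 1 / rate_hz && n_steps > 1) {
    stop("pulse_s must be shorter than the stomp interval 1/rate_hz")
  }
  intervals <- rep(1 / rate_hz, max(n_steps - 1, 0))
  halt_idx <- integer(0)
  if (!is.null(halt_spec)) {
    if (is.null(halt_spec$index) || is.null(halt_spec$factor)) {
      stop("halt_spec must be list(index =, factor =)")
    }
    if (halt_spec$index >= n_steps || halt_spec$index < 1) {
      stop("halt_spec index ", halt_spec$index,
           " does not name an interval of a ", n_steps, "-step recording")
    }
    intervals[halt_spec$index] <- intervals[halt_spec$index] *
      halt_spec$factor
    halt_idx <- as.integer(halt_spec$index)
  }
  onsets <- margin_s + c(0, cumsum(intervals))
  centers <- onsets + pulse_s / 2
  heights <- base_height + decrement_slope * (centers - centers[1])
  if (any(heights <= 0)) {
    stop("decrement_slope drives step heights non-positive")
  }
  duration <- onsets[n_steps] + pulse_s + margin_s
  t <- seq(0, duration, by = 1 / fs)
  n <- length(t)
  az <- numeric(n)
  for (i in seq_len(n_steps)) {
    idx <- which(t >= onsets[i] & t <= onsets[i] + pulse_s)
    az[idx] <- az[idx] + fs_pulse_accel(t[idx] - onsets[i], heights[i],
                                        pulse_s)
  }
  # specific force in g, global frame: motion + gravity reaction on +z
  f_global <- cbind(0, 0, az / 9.81 + 1)
  tilt <- tilt_deg * pi / 180
  psi <- drift_dps * pi / 180 * t
  q_tilt <- axis_angle_quat(c(1, 0, 0), tilt)
  q_drift <- cbind(cos(psi / 2), 0, 0, sin(psi / 2))
  quat <- quat_multiply(q_drift, q_tilt)  # sensor -> global
  q_conj <- cbind(quat[, 1], -quat[, 2:4])
  accel_sensor <- quat_rotate(q_conj, f_global)
  omega_global <- cbind(0, 0, rep(drift_dps, n))  # deg/s
  gyro_sensor <- quat_rotate(q_conj, omega_global)
  rec <- with_seed(seed, {
    accel <- accel_sensor + matrix(stats::rnorm(3 * n, 0, noise_sd / 9.81),
                                   n, 3)
    gyro <- gyro_sensor + matrix(stats::rnorm(3 * n, 0, 0.1), n, 3)
    imu_recording(t, accel, gyro, quat, fs, task = "FS",
                  placement = "ankle", side = side)
  })
  truth <- fs_ground_truth(step_times = centers, step_heights = heights,
                           peak_velocities = 4 * heights / pulse_s,
                           injected_halt_indices = halt_idx,
                           decrement_slope = decrement_slope)
  list(recording = rec, truth = truth)
}

#' Generate a synthetic hand pronation-supination recording
#'
#' Emulates ten rapid alternating wrist rotations recorded by a wrist IMU:
#' the angular velocity about the pronation axis (sensor x) is a train of
#' alternating-sign half-sine lobes whose time-integral equals the signed
#' turn amplitude.
#'
#' @param n_turns number of half-turns (>= 1); one pronation-supination
#'   cycle comprises two turns
#' @param rate_hz turn rate in turns per second
#' @param amplitude_deg unsigned turn amplitude in degrees
#' @param noise_sd gyroscope noise SD in degrees/s
#' @param seed integer seed
#' @param fs sampling rate in Hz
#' @param duty fraction of the inter-turn interval occupied by the rotation
#' @param margin_s quiet margin in seconds
#' @param side recorded body side
#' @return list with elements `recording` ([imu_recording]) and `truth`
#'   ([hps_ground_truth])
#' @examples
#' sim <- gen_hps_recording(n_turns = 10, amplitude_deg = 160, seed = 1)
#' sum(abs(sim$truth$turn_amplitudes))  # 1600 degrees travelled
#' @export
gen_hps_recording <- function(n_turns = 10, rate_hz = 2,
                              amplitude_deg = 160, noise_sd = 5, seed = 1,
                              fs = 200, duty = 0.8, margin_s = 1,
                              side = "right") {
  stopifnot(n_turns >= 1, rate_hz > 0, amplitude_deg > 0,
            duty > 0, duty <= 1)
  pulse_s <- duty / rate_hz
  onsets <- margin_s + (seq_len(n_turns) - 1) / rate_hz
  centers <- onsets + pulse_s / 2
  signs <- rep_len(c(1, -1), n_turns)
  duration <- onsets[n_turns] + pulse_s + margin_s
  t <- seq(0, duration, by = 1 / fs)
  n <- length(t)
  # half-sine lobe: omega(tau) = s * A * pi / (2 Tp) * sin(pi tau / Tp),
  # integral = s * A, peak = A * pi / (2 Tp)
  wx <- numeric(n)
  for (i in seq_len(n_turns)) {
    idx <- which(t >= onsets[i] & t <= onsets[i] + pulse_s)
    wx[idx] <- wx[idx] + signs[i] * amplitude_deg * pi / (2 * pulse_s) *
      sin(pi * (t[idx] - onsets[i]) / pulse_s)
  }
  quat <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  rec <- with_seed(seed, {
    gyro <- cbind(wx, 0, 0) + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
    accel <- matrix(rep(c(0, 0, 1), each = n), n, 3) +
      matrix(stats::rnorm(3 * n, 0, 0.005), n, 3)
    imu_recording(t, accel, gyro, quat, fs, task = "HPS",
                  placement = "wrist", side = side)
  })
  truth <- hps_ground_truth(
    turn_times = centers,
    turn_amplitudes = signs * amplitude_deg,
    peak_angular_velocities = rep(amplitude_deg * pi / (2 * pulse_s),
                                  n_turns))
  list(recording = rec, truth = truth)
}

# Beta-amplitude factor for a segment: "block.label" beats bare "label".
segment_factor <- function(modulation, block, label) {
  key <- paste(block, label, sep = ".")
  if (key %in% names(modulation)) return(unname(modulation[key]))
  if (label %in% names(modulation)) return(unname(modulation[label]))
  1
}

#' Generate a synthetic LFP session
#'
#' Simulates a raw subthalamic LFP channel as a 1/f^a Gaussian background
#' plus a sinusoid at the beta-peak frequency whose amplitude is modulated
#' per protocol segment, then derives the 2 Hz band-power stream the
#' neurofeedback device would emit: mean complex-Morlet power inside the
#' 5 Hz feedback band, averaged over a trailing 6 s window, updated every
#' 0.5 s.
#'
#' @param protocol segment table from [session_protocol()]
#' @param truth [lfp_ground_truth] describing peak frequency, per-segment
#'   modulation, and background exponent
#' @param fs_raw raw sampling rate in Hz (device-class typical: 250)
#' @param seed integer seed
#' @param beta_amp baseline beta sinusoid amplitude (device units)
#' @param background_rms RMS of the broadband 1/f background
#' @param keep_raw whether to retain the raw channel in the session
#' @return an [lfp_session]
#' @examples
#' proto <- session_protocol(blocks = c("nf1", "nf2", "nf3"))
#' ses <- gen_lfp_session(proto, lfp_ground_truth(20, c(nf = 0.85)),
#'                        seed = 1)
#' @export
gen_lfp_session <- function(protocol, truth = lfp_ground_truth(),
                            fs_raw = 250, seed = 1, beta_amp = 1,
                            background_rms = 1, keep_raw = TRUE) {
  band <- feedback_band(truth$beta_peak_hz)
  if (band[2] >= fs_raw / 2) {
    stop("feedback band exceeds the Nyquist frequency of fs_raw")
  }
  duration <- protocol_duration(protocol)
  n <- ceiling(duration * fs_raw)
  t <- (seq_len(n) - 1) / fs_raw
  raw <- with_seed(seed, {
    # FFT-shaped 1/f^a background
    white <- stats::rnorm(n)
    W <- stats::fft(white)
    f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs_raw / n
    shape <- c(0, 1 / f[-1]^(truth$background_exponent / 2))
    bg <- Re(stats::fft(W * shape, inverse = TRUE)) / n
    bg <- bg / stats::sd(bg) * background_rms
    phase <- stats::runif(1, 0, 2 * pi)
    amp <- numeric(n)
    for (k in seq_len(nrow(protocol))) {
      idx <- t >= protocol$t_start_s[k] & t < protocol$t_end_s[k]
      amp[idx] <- beta_amp * segment_factor(truth$modulation,
                                            protocol$block[k],
                                            protocol$label[k])
    }
    bg + amp * sin(2 * pi * truth$beta_peak_hz * t + phase)
  })
  band_power <- band_power_stream(raw, fs_raw, band[1], band[2])
  lfp_session(truth$beta_peak_hz, band_power, protocol,
              raw = if (keep_raw) list(fs = fs_raw, values = raw) else NULL)
}

# Band-power stream at 2 Hz: mean Morlet power over the feedback band,
# averaged over the trailing (up to) 6-second window, one sample per 0.5 s.
band_power_stream <- function(raw, fs_raw, low_hz, high_hz,
                              update_hz = 2, window_s = 6) {
  freqs <- seq(low_hz + 0.5, high_hz - 0.5, by = 1)
  W <- cwt_morlet(raw, fs_raw, freqs)
  p_inst <- colMeans(Mod(W)^2)
  dt <- 1 / update_hz
  t_out <- seq(dt, length(raw) / fs_raw, by = dt)
  cs <- cumsum(c(0, p_inst))
  hi <- pmin(floor(t_out * fs_raw), length(p_inst))
  lo <- pmax(floor((t_out - window_s) * fs_raw), 0)
  data.frame(t_s = t_out, power = (cs[hi + 1] - cs[lo + 1]) / (hi - lo))
}

#' Generate a paired pre/post cohort with known effect size
#'
#' Draws `pre ~ Normal(0, sd)` and `post = pre + Normal(true_smd * sd, sd)`
#' so that the paired-difference SD equals `sd` and the true paired
#' standardized mean difference (Cohen's d_z) equals `true_smd`.
#'
#' @param n_subjects number of participants (>= 2)
#' @param true_smd true paired standardized mean difference
#' @param sd SD of the paired differences (and of `pre`)
#' @param seed integer seed
#' @return list with numeric vectors `pre` and `post` and participant ids
#' @examples
#' coh <- gen_paired_cohort(10, true_smd = 0.94, seed = 1)
#' @export
gen_paired_cohort <- function(n_subjects, true_smd, sd = 1, seed = 1) {
  stopifnot(n_subjects >= 2, sd > 0)
  with_seed(seed, {
    pre <- stats::rnorm(n_subjects, 0, sd)
    post <- pre + stats::rnorm(n_subjects, true_smd * sd, sd)
    list(participant = sprintf("P%02d", seq_len(n_subjects)),
         pre = pre, post = post)
  })
}
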