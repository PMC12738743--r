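# Generators: constructed invariants, closed-form integrals, and seed
# reproducibility.

test_that("FS generator matches its schedule and validates halts", {
  sim <- gen_fs_recording(n_steps = 10, rate_hz = 1.5, seed = 1)
  expect_equal(sim$truth$n_steps, 10)
  expect_equal(1 / mean(diff(sim$truth$step_times)), 1.5, tolerance = 1e-9)
  expect_s3_class(sim$recording, "imu_recording")
  expect_equal(sim$recording$fs, 200)
  # halt spec referencing a non-existent interval is rejected with message
  expect_error(gen_fs_recording(n_steps = 5,
                                halt_spec = list(index = 5, factor = 2)),
               "does not name an interval")
  halt <- gen_fs_recording(n_steps = 5, seed = 2,
                           halt_spec = list(index = 3, factor = 2))
  iv <- diff(halt$truth$step_times)
  expect_equal(which.max(iv), 3)
  # downstream halt count agrees with direct evaluation of the mu + 2 sigma
  # rule on the scheduled times (n = 5 doubling is NOT flagged: the few
  # intervals inflate sigma; at n = 10 the same doubling is)
  expect_equal(intervals_and_halts(halt$truth$step_times)$n_halts,
               brute_intervals_halts(halt$truth$step_times)$n_halts)
  halt10 <- gen_fs_recording(n_steps = 10, seed = 2,
                             halt_spec = list(index = 5, factor = 2))
  expect_equal(brute_intervals_halts(halt10$truth$step_times)$n_halts, 1)
})

test_that("noise-free stomp pulses double-integrate to the scheduled height", {
  # fine sampling isolates the generator's closed-form consistency from
  # trapezoid discretization (at 200 Hz the pulse integrates to ~0.3%)
  sim <- gen_fs_recording(n_steps = 3, noise_sd = 0, seed = 1, fs = 800,
                          tilt_deg = 0, drift_dps = 0)
  rec <- sim$recording
  az <- (rec$accel[, 3] - 1) * 9.81  # remove gravity, SI units
  dt <- 1 / rec$fs
  for (i in seq_len(3)) {
    sel <- rec$t >= sim$truth$step_times[i] - 0.16 &
      rec$t <= sim$truth$step_times[i] + 0.16
    v <- cumsum((az[sel][-1] + az[sel][-sum(sel)]) / 2) * dt
    d <- cumsum((v[-1] + v[-length(v)]) / 2) * dt
    expect_lt(abs(v[length(v)]) / sim$truth$peak_velocities[i], 1e-3)
    expect_equal(max(d), sim$truth$step_heights[i], tolerance = 1e-3)
    expect_equal(max(abs(v)), sim$truth$peak_velocities[i],
                 tolerance = 1e-3)
  }
  # at the device rate the recovery is still within half a percent
  sim200 <- gen_fs_recording(n_steps = 1, noise_sd = 0, seed = 1,
                             tilt_deg = 0, drift_dps = 0)
  az <- (sim200$recording$accel[, 3] - 1) * 9.81
  v <- cumsum((az[-1] + az[-length(az)]) / 2) / 200
  d <- cumsum((v[-1] + v[-length(v)]) / 2) / 200
  expect_equal(max(d), sim200$truth$step_heights[1], tolerance = 5e-3)
})

test_that("HPS generator produces alternating turns with exact integrals", {
  sim <- gen_hps_recording(n_turns = 4, amplitude_deg = 90, noise_sd = 0,
                           seed = 1)
  expect_equal(sim$truth$turn_amplitudes, c(90, -90, 90, -90))
  # cumulative angular displacement recovered by direct integration
  wx <- sim$recording$gyro[, 1]
  dt <- 1 / sim$recording$fs
  total <- sum(abs(diff(cumsum(c(0, (wx[-1] + wx[-length(wx)]) / 2)) * dt)))
  expect_equal(total, 4 * 90, tolerance = 0.01 * 360)
  expect_error(gen_hps_recording(n_turns = 0), "n_turns")
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- gen_fs_recording(seed = 7)
  b <- gen_fs_recording(seed = 7)
  expect_identical(a$recording$accel, b$recording$accel)
  c1 <- gen_paired_cohort(10, 0.5, seed = 3)
  c2 <- gen_paired_cohort(10, 0.5, seed = 3)
  expect_identical(c1, c2)
  proto <- session_protocol(blocks = "nf1")
  s1 <- gen_lfp_session(proto, seed = 4, keep_raw = TRUE)
  s2 <- gen_lfp_session(proto, seed = 4, keep_raw = TRUE)
  expect_identical(s1$raw$values, s2$raw$values)
  # generators leave the caller's RNG stream untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(gen_fs_recording(seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("LFP band-power stream ticks at 2 Hz and normalizes to 1", {
  proto <- session_protocol(blocks = c("nf1"))
  ses <- gen_lfp_session(proto, lfp_ground_truth(20, c(nf = 1.0)),
                         seed = 1, keep_raw = FALSE)
  dur <- protocol_duration(proto)
  expect_equal(nrow(ses$band_power), 2 * dur, tolerance = 1)
  expect_equal(median(diff(ses$band_power$t_s)), 0.5)
  sesn <- normalize_lfp(ses)
  sm <- block_summaries(sesn)
  # no modulation: every segment median ~ 1
  expect_true(all(abs(sm$median_normalized_power - 1) < 0.15))
  # rest segment is exactly 1 by construction
  expect_equal(sm$median_normalized_power[sm$label == "rest"], 1)
})

test_that("beta modulation shows up as the squared-amplitude power ratio", {
  proto <- session_protocol(blocks = c("nf1", "nf2", "nf3"))
  ses <- normalize_lfp(gen_lfp_session(proto,
                                       lfp_ground_truth(20, c(nf = 0.85)),
                                       seed = 1, keep_raw = FALSE))
  sm <- block_summaries(ses)
  nf_med <- sm$median_normalized_power[sm$label == "nf"]
  # oracle from the generating equation: power ratio between factor^2 (pure
  # beta) and 1 (pure background); with the default SNR the ratio sits near
  # factor^2 but strictly above it
  expect_true(all(nf_med < 1))
  expect_true(all(nf_med > 0.85^2 - 0.05))
  expect_true(all(sm$pct_change_vs_baseline[sm$label == "nf"] < 0))
})

test_that("band edges beyond Nyquist and bad protocols are rejected", {
  proto <- session_protocol(blocks = "nf1")
  expect_error(gen_lfp_session(proto, lfp_ground_truth(29), fs_raw = 60),
               "Nyquist")
  bad <- data.frame(block = "b", label = c("rest", "nf"),
                    t_start_s = c(0, 30), t_end_s = c(60, 90))
  expect_error(validate_segments(bad), "overlapping")
})

test_that("paired cohorts carry the requested effect size", {
  null_hits <- 0
  for (s in 1:60) {
    coh <- gen_paired_cohort(10, 0, seed = s)
    ci <- smd_bootstrap(coh$pre, coh$post, B = 400, seed = s)$ci
    null_hits <- null_hits + (ci[1] <= 0 && 0 <= ci[2])
  }
  expect_gt(null_hits / 60, 0.75)  # CI covers 0 most of the time under null
  # Monte-Carlo mean of the estimate is close to the target SMD
  ests <- vapply(1:300, function(s) {
    coh <- gen_paired_cohort(200, 1.0, seed = 10000 + s)
    d <- coh$post - coh$pre
    mean(d) / sd(d)
  }, numeric(1))
  expect_equal(mean(ests), 1.0, tolerance = 0.03)
})

test_that("detection SNR degrades monotonically with sensor noise", {
  snr_at <- function(noise_sd) {
    mean(vapply(1:5, function(s) {
      sim <- gen_fs_recording(noise_sd = noise_sd, seed = s)
      rec <- sim$recording
      full <- c(rec$t[1] + 0.1, rec$t[length(rec$t)] - 0.1)
      sig <- preprocess_recording(rec, window = full)
      env <- moving_rms(sig$value[, 3], 8)
      peaks <- vapply(sim$truth$step_times, function(ts) {
        max(env[abs(sig$t - ts) < 0.1])
      }, numeric(1))
      floor_level <- median(env[sig$t < rec$t[1] + 0.8])
      median(peaks) / floor_level
    }, numeric(1)))
  }
  snrs <- c(snr_at(0.1), snr_at(2), snr_at(8))
  expect_true(all(diff(snrs) < 0))
})
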