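# Preprocessing chain: rotation oracle, gravity arithmetic, filter
# contracts, resampling, and deterministic segmentation.

make_rec <- function(accel, quat, fs = 200, gyro = NULL, task = "FS") {
  n <- nrow(accel)
  if (is.null(gyro)) gyro <- matrix(0, n, 3)
  imu_recording(seq(0, by = 1 / fs, length.out = n), accel, gyro, quat,
                fs, task = task)
}

test_that("identity quaternions leave acceleration untouched", {
  n <- 100
  accel <- cbind(rnorm(n), rnorm(n), rnorm(n))
  quat <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  sig <- to_global_frame(make_rec(accel, quat))
  expect_equal(sig$value, accel, tolerance = 1e-12)
  expect_equal(sig$frame, "global")
})

test_that("frame transformation matches the rotation-matrix oracle", {
  # 90 degrees about x, Hamilton active convention: sensor (0,0,1) maps to
  # global (0,-1,0)
  n <- 10
  q <- axis_angle_quat(c(1, 0, 0), pi / 2)
  quat <- matrix(rep(q, each = n), n, 4)
  accel <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  sig <- to_global_frame(make_rec(accel, quat))
  expect_equal(sig$value[1, ], c(0, -1, 0), tolerance = 1e-12)
  # random rotations: compare to an independently coded rotation matrix
  set.seed(42)
  for (i in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, -pi, pi)
    R <- diag(3) * cos(th) + (1 - cos(th)) * outer(ax, ax) +
      sin(th) * rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]),
                      c(-ax[2], ax[1], 0))
    v <- rnorm(3)
    q1 <- axis_angle_quat(ax, th)
    got <- to_global_frame(make_rec(matrix(v, 1, 3), matrix(q1, 1, 4),
                                    fs = 1))$value
    expect_equal(as.numeric(got), as.numeric(R %*% v), tolerance = 1e-9)
    # rotation is an isometry
    expect_equal(sqrt(sum(got^2)), sqrt(sum(v^2)), tolerance = 1e-9)
  }
  # invalid quaternion norms are rejected with the sample index
  quat[3, ] <- c(2, 0, 0, 0)
  expect_error(imu_recording(1:10 / 200, accel, matrix(0, 10, 3), quat, 200),
               "norm")
})

test_that("gravity compensation performs the unit conversion and offset", {
  n <- 50
  quat <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  static <- to_global_frame(make_rec(matrix(rep(c(0, 0, 1), each = n),
                                            n, 3), quat))
  out <- gravity_compensate(static)
  expect_equal(max(abs(out$value)), 0, tolerance = 1e-12)
  expect_equal(out$units, "m/s^2")
  double_g <- to_global_frame(make_rec(matrix(rep(c(0, 0, 2), each = n),
                                              n, 3), quat))
  expect_equal(gravity_compensate(double_g)$value[1, 3], 9.81)
  # sensor-frame input is refused
  sensor_sig <- movement_signal(1:n / 200, matrix(0, n, 3), 200,
                                frame = "sensor", units = "g")
  expect_error(gravity_compensate(sensor_sig), "global")
})

test_that("drifting orientation still yields constant gravity on global z", {
  sim <- gen_fs_recording(noise_sd = 0, seed = 1, tilt_deg = 15,
                          drift_dps = 3)
  sig <- to_global_frame(sim$recording)
  rest <- sig$t < 0.8  # quiet margin before the first stomp
  expect_equal(mean(sig$value[rest, 3]), 1, tolerance = 1e-6)
  expect_lt(max(abs(sig$value[rest, 1:2])), 1e-6)
})

test_that("highpass removes drift and preserves the passband", {
  fs <- 200
  t <- seq(0, 20, by = 1 / fs)
  sig <- movement_signal(t, sin(2 * pi * 5 * t), fs, frame = "global")
  out <- highpass(sig)
  interior <- t > 2 & t < 18
  expect_equal(max(abs(out$value[interior])), 1, tolerance = 0.01)
  drift <- movement_signal(t, sin(2 * pi * 0.05 * t), fs, frame = "global")
  # >= 40 dB attenuation of a 0.05 Hz drift component
  expect_lt(max(abs(highpass(drift)$value[interior])), 0.01)
  expect_error(highpass(sig, cutoff = 150), "Nyquist")
})

test_that("downsampling respects its contracts", {
  fs <- 200
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  sig <- movement_signal(t, sin(2 * pi * 2 * t), fs, frame = "global")
  out <- downsample(sig, 50)
  expect_equal(out$fs, 50)
  expect_equal(max(abs(out$value)), 1, tolerance = 0.01)
  const <- movement_signal(t, rep(2, length(t)), fs, frame = "global")
  expect_equal(unique(round(downsample(const, 50)$value, 10)), 2)
  expect_identical(downsample(sig, 200), sig)
  expect_error(downsample(sig, 400), "exceeds")
})

test_that("segmentation finds the active window deterministically", {
  sim <- gen_fs_recording(n_steps = 10, rate_hz = 1.5, seed = 3)
  sig <- preprocess_recording(sim$recording)
  w <- range(sig$t)
  first <- sim$truth$step_times[1]
  last <- sim$truth$step_times[10]
  expect_lte(w[1], first - 0.15)
  expect_gte(w[2], last + 0.15)
  expect_gte(w[1], first - 0.8)
  expect_lte(w[2], last + 0.8)
  # manual hint is passed through verbatim
  any_sig <- movement_signal(seq(0, 10, 0.01), rnorm(1001), 100,
                             frame = "global")
  expect_identical(segment_task(any_sig, protocol_hint = c(2, 9)), c(2, 9))
  # pure noise has no active movement
  set.seed(1)
  quiet <- movement_signal(seq(0, 10, 0.01), rnorm(1001, 0, 1e-3), 100,
                           frame = "global")
  expect_error(segment_task(quiet), "no active movement")
})

test_that("the composed pipeline preserves the stomp count", {
  sim <- gen_fs_recording(n_steps = 10, noise_sd = 0, seed = 5)
  sig <- preprocess_recording(sim$recording)
  env <- movement_signal(sig$t, moving_rms(sig$value[, 3], 7), sig$fs,
                         frame = "global", task = "FS")
  expect_length(detect_peaks(env), 10)
})

test_that("preprocessing is pure", {
  sim <- gen_fs_recording(seed = 11)
  a <- preprocess_recording(sim$recording)
  b <- preprocess_recording(sim$recording)
  expect_identical(a, b)
})
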