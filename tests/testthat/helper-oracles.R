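# Independent oracles used across the test files. Each one re-derives the
# quantity under test from first principles (enumeration, closed form, or
# direct evaluation of the printed formula) without touching the package's
# own implementation path.

# Exact two-sided signed-rank p-value by brute-force enumeration of all
# 2^n sign assignments (mid-ranks allowed).
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  t_pos <- as.numeric(signs %*% r)
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  min(1, 2 * mean(t_pos <= w_obs + 1e-9))
}

# Minimum-jerk speed profile of a unit-displacement point-to-point
# movement of duration T: v(tau) = 30 (tau^2)(1-tau)^2 / T.
min_jerk_speed <- function(T_dur, fs) {
  tau <- seq(0, T_dur, by = 1 / fs) / T_dur
  30 * tau^2 * (1 - tau)^2 / T_dur
}

# Band-limited Gaussian noise (FFT masking), normalized to the given SD.
band_noise <- function(n, fs, lo, hi, sd_target) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  X[!(f >= lo & f <= hi)] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y) * sd_target
}

# Direct evaluation of the interval/halt formulas on a peak-time list.
brute_intervals_halts <- function(peak_times) {
  iv <- diff(peak_times)
  mu <- sum(iv) / length(iv)
  sigma <- if (length(iv) > 1) sqrt(sum((iv - mu)^2) / (length(iv) - 1)) else 0
  list(mean_interval_s = mu, n_halts = sum(iv > mu + 2 * sigma))
}

# Closed-form OLS slope of y on x.
brute_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# One noise-free stomp pulse (raised-cosine velocity lobe pair) and its
# analytic kinematics: v_peak = 4 h / Tp, peak displacement h at Tp / 2.
stomp_pulse <- function(h, Tp, fs) {
  tau <- seq(0, Tp, by = 1 / fs)
  v_p <- 4 * h / Tp
  sgn <- ifelse(tau <= Tp / 2, 1, -1)
  list(t = tau,
       accel = sgn * v_p * (2 * pi / Tp) * sin(4 * pi * tau / Tp),
       v_peak = v_p, height = h)
}
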