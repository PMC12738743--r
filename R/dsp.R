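# Signal-processing primitives used across the package. Implemented in base R
# because no DSP package is assumed at run time; each routine follows the
# textbook definition and is validated against closed-form cases in the tests.

#' Polynomial coefficients from roots
#'
#' Returns the monic polynomial with the given (possibly complex) roots,
#' coefficients in decreasing powers. Used by the Butterworth designer.
#'
#' @param r complex vector of roots
#' @return complex coefficient vector, length `length(r) + 1`
#' @keywords internal
#' @noRd
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (root in r) p <- c(p, 0) - c(0, p * root)
  p
}

#' Butterworth filter design (bilinear transform)
#'
#' Designs a digital Butterworth low- or high-pass filter of order `n` with
#' cutoff `fc` (Hz) at sampling rate `fs` (Hz), via the analog prototype,
#' frequency pre-warping, and the bilinear transform.
#'
#' @param n filter order
#' @param fc cutoff frequency in Hz (-3 dB point)
#' @param fs sampling rate in Hz
#' @param type `"low"` or `"high"`
#' @return list with numerator `b` and denominator `a` coefficient vectors
#' @examples
#' hp <- butter_design(4, 0.5, 200, "high")
#' @export
butter_design <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(n >= 1, fc > 0, fs > 0)
  if (fc >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  # analog lowpass prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k - 1 + n) / (2 * n))
  wc <- 2 * fs * tan(pi * fc / fs)  # pre-warped analog cutoff
  if (type == "low") {
    pa <- wc * p
    za <- complex(0)
    ka <- wc^n
  } else {
    pa <- wc / p
    za <- rep(0 + 0i, n)
    ka <- 1
  }
  fs2 <- 2 * fs
  pd <- (fs2 + pa) / (fs2 - pa)
  zd <- if (length(za)) (fs2 + za) / (fs2 - za) else complex(0)
  # bilinear transform maps the n - n_z zeros at infinity to z = -1
  zd <- c(zd, rep(-1 + 0i, length(pa) - length(za)))
  kd <- ka * Re(prod(fs2 - za) / prod(fs2 - pa))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# Direct-form II transposed IIR filter with optional initial state.
iir_filter <- function(b, a, x, zi = NULL) {
  nc <- max(length(a), length(b))
  b <- c(b, rep(0, nc - length(b))) / a[1]
  a <- c(a, rep(0, nc - length(a))) / a[1]
  z <- if (is.null(zi)) rep(0, nc - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nc > 2) {
      for (j in seq_len(nc - 2)) {
        z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
      }
    }
    z[nc - 1] <- b[nc] * xi - a[nc] * yi
    y[i] <- yi
  }
  y
}

# Steady-state initial filter state for a unit-step input (lfilter_zi).
iir_filter_zi <- function(b, a) {
  nc <- max(length(a), length(b))
  b <- c(b, rep(0, nc - length(b))) / a[1]
  a <- c(a, rep(0, nc - length(a))) / a[1]
  if (nc == 1) return(numeric(0))
  A <- if (nc == 2) matrix(-a[2], 1, 1) else
    cbind(-a[2:nc], rbind(diag(nc - 2), rep(0, nc - 2)))
  B <- b[2:nc] - b[1] * a[2:nc]
  solve(diag(nc - 1) - A, B)
}

#' Zero-phase IIR filtering (forward-backward)
#'
#' Applies the filter forward and backward with odd-reflection edge padding
#' and steady-state initial conditions, so the net phase response is zero and
#' the magnitude response is squared. Peak timing is therefore preserved, a
#' property the segmentation and peak-anchored integration rely on.
#'
#' @param b,a filter coefficients as from [butter_design()]
#' @param x numeric signal
#' @param pad edge padding length in samples; defaults to three times the
#'   slowest pole's time constant (capped at the signal length), so the
#'   startup transient of low-cutoff filters dies inside the padding
#' @return filtered signal, same length as `x`
#' @export
filtfilt <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) {
    rmax <- max(Mod(polyroot(rev(a))))
    tau <- if (rmax < 1) -1 / log(rmax) else n
    pad <- min(n - 1, max(3 * (max(length(a), length(b)) - 1),
                          ceiling(3 * tau)))
  }
  if (n <= pad) stop("signal too short for the requested filter")
  xt <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  zi <- iir_filter_zi(b, a)
  y <- iir_filter(b, a, xt, zi * xt[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + n)]
}

#' Fourier-domain resampling
#'
#' Resamples a uniformly sampled signal to `n_out` points by truncating or
#' zero-padding its discrete spectrum (ideal anti-alias filter). Tones below
#' the output Nyquist frequency are preserved exactly, which is the contract
#' the downsampling stage requires.
#'
#' @param x numeric signal
#' @param n_out desired output length
#' @return resampled numeric vector of length `n_out`
#' @export
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(real = rep(0, n_out), imaginary = rep(0, n_out))
  m <- min(n, n_out)
  half <- floor((m + 1) / 2)  # positive-frequency bins excluding Nyquist
  Y[1:half] <- X[1:half]
  if (half > 1) Y[(n_out - half + 2):n_out] <- X[(n - half + 2):n]
  if (m %% 2 == 0) {
    nyq <- X[m / 2 + 1]
    if (n_out < n) {
      # fold the bins beyond the new Nyquist into the boundary bin
      Y[n_out / 2 + 1] <- nyq + X[n - m / 2 + 1]
    } else {
      Y[m / 2 + 1] <- nyq / 2
      Y[n_out - m / 2 + 1] <- Conj(nyq) / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) * n_out / (n * n_out)
}

#' Moving root-mean-square envelope
#'
#' @param x numeric signal
#' @param w window length in samples (forced odd, centered)
#' @return RMS envelope, same length as `x` (edges use shrunken windows)
#' @export
moving_rms <- function(x, w) {
  w <- max(3L, as.integer(w))
  if (w %% 2 == 0) w <- w + 1L
  n <- length(x)
  cs <- cumsum(c(0, x^2))
  h <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing. Interior samples use the central
#' convolution weights; the first and last half-windows are taken from the
#' full polynomial fit of the boundary windows (equivalent to scipy's
#' `mode = "interp"`).
#'
#' @param x numeric signal
#' @param window odd window length in samples
#' @param order polynomial order (< window)
#' @return smoothed signal, same length as `x`
#' @export
sgolay_smooth <- function(x, window = 21L, order = 3L) {
  window <- as.integer(window)
  if (window %% 2 == 0) stop("window must be odd")
  if (order >= window) stop("order must be smaller than window")
  n <- length(x)
  if (n < window) stop("signal shorter than the smoothing window")
  h <- (window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:order, `^`)
  H <- A %*% solve(crossprod(A), t(A))  # projection on local polynomials
  w <- H[h + 1L, ]
  y <- as.numeric(stats::filter(x, rev(w), sides = 2))
  y[seq_len(h)] <- (H %*% x[seq_len(window)])[seq_len(h)]
  y[(n - h + 1L):n] <- (H %*% x[(n - window + 1L):n])[(h + 2L):window]
  y
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with Hann window, mean removal per segment,
#' and one-sided density scaling.
#'
#' @param x numeric signal
#' @param fs sampling rate in Hz
#' @param nperseg segment length in samples (default 2 s)
#' @param overlap fractional overlap between segments
#' @return list with `freq` (Hz) and `psd` (power per Hz)
#' @export
welch_psd <- function(x, fs, nperseg = round(2 * fs), overlap = 0.5) {
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  k <- seq_len(nperseg) - 1L
  w <- 0.5 - 0.5 * cos(2 * pi * k / nperseg)
  scale <- 1 / (fs * sum(w^2))
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 * scale
    acc <- acc + P[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even nperseg)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = psd * dbl)
}

#' Continuous wavelet transform with complex Morlet wavelets
#'
#' Complex Morlet wavelet `exp(-t'^2 / B) * exp(2i * pi * C * t')` with
#' bandwidth parameter `B` and center frequency parameter `C` (the
#' `cmorB-C` family), L2-normalized, evaluated by FFT convolution per
#' frequency.
#'
#' @param x numeric signal
#' @param fs sampling rate in Hz
#' @param freqs frequency grid in Hz
#' @param bandwidth Morlet bandwidth parameter B
#' @param center center-frequency parameter C
#' @return complex matrix, `length(freqs)` rows by `length(x)` columns
#' @export
cwt_morlet <- function(x, fs, freqs, bandwidth = 0.5, center = 5.0) {
  if (any(freqs <= 0) || any(freqs >= fs / 2)) {
    stop("frequency grid must lie strictly inside (0, Nyquist)")
  }
  n <- length(x)
  out <- matrix(complex(real = 0), nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    hw <- ceiling(5 * sqrt(bandwidth / 2) * center / f * fs)
    tw <- seq(-hw, hw) / fs
    tp <- tw * f / center
    w <- exp(-tp^2 / bandwidth) * exp(2i * pi * f * tw)
    w <- w / sqrt(sum(Mod(w)^2))
    nfft <- stats::nextn(n + length(w) - 1L, 2)
    conv <- stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                         stats::fft(c(w, rep(0, nfft - length(w)))),
                       inverse = TRUE) / nfft
    out[i, ] <- conv[(hw + 1L):(hw + n)]
  }
  out
}

# Cumulative trapezoidal integral on a uniform grid with spacing dt.
cumtrapz <- function(x, dt) {
  n <- length(x)
  if (n < 2) return(numeric(n))
  c(0, cumsum((x[-1] + x[-n]) / 2)) * dt
}
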