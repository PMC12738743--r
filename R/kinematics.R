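# Peak-anchored integration with zero-velocity updates. Stomps are
# impact-centered with rest in between, so movement segments run between
# inter-peak midpoints; velocity is forced to zero at both segment
# boundaries (the standard ZUPT-style drift limiter for cyclic stationary
# tasks), and displacement restarts at zero per segment.

#' Detect movement peaks in a 1-D signal
#'
#' Local maxima of `|signal|` filtered by topographic prominence and a
#' minimum peak distance (larger peaks win). Mirrors the behaviour of the
#' usual find-peaks routines; an empty result is a valid return.
#'
#' @param sig a 1-D [movement_signal] or numeric vector
#' @param min_distance minimum peak separation in seconds
#' @param min_prominence minimum prominence in signal units; default
#'   2 x MAD of the rectified signal
#' @param fs sampling rate, required when `sig` is a bare vector
#' @return integer vector of peak indices, in time order
#' @examples
#' s <- sin(2 * pi * seq(0, 5, by = 0.02))
#' detect_peaks(s, fs = 50)
#' @export
detect_peaks <- function(sig, min_distance = 0.25, min_prominence = NULL,
                         fs = NULL) {
  if (inherits(sig, "movement_signal")) {
    if (is.matrix(sig$value)) stop("detect_peaks expects a 1-D signal")
    x <- sig$value
    fs <- sig$fs
  } else {
    x <- as.numeric(sig)
    if (is.null(fs)) stop("fs required for bare numeric input")
  }
  a <- abs(x)
  n <- length(a)
  # default: 2 x MAD of the rectified signal, capped at a quarter of its
  # maximum (the MAD alone over-rejects when movement occupies most of the
  # window and the rectified baseline is itself large)
  if (is.null(min_prominence)) {
    min_prominence <- min(2 * stats::mad(a), max(a) / 4)
  }
  cand <- which(diff(sign(diff(a))) < 0) + 1L
  cand <- cand[a[cand] > 0]
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(p) {
    h <- a[p]
    i <- p
    lmin <- h
    while (i > 1 && a[i - 1] <= h) { i <- i - 1; lmin <- min(lmin, a[i]) }
    if (i == 1) lmin <- min(a[1:p])
    j <- p
    rmin <- h
    while (j < n && a[j + 1] <= h) { j <- j + 1; rmin <- min(rmin, a[j]) }
    if (j == n) rmin <- min(a[p:n])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) == 0) return(integer(0))
  # enforce min distance greedily, tallest first
  ord <- keep[order(a[keep], decreasing = TRUE)]
  min_gap <- min_distance * fs
  sel <- integer(0)
  for (p in ord) {
    if (all(abs(sel - p) >= min_gap)) sel <- c(sel, p)
  }
  sort(sel)
}

# Segment boundaries from peaks: inter-peak midpoints, first/last extended
# to the window edges. Returns an (n_peaks + 1) vector of indices.
segment_boundaries <- function(peaks, n) {
  mids <- if (length(peaks) > 1) {
    floor((peaks[-1] + peaks[-length(peaks)]) / 2)
  } else integer(0)
  c(1L, mids, n)
}

#' Integrate acceleration with zero-velocity updates
#'
#' Within each movement segment (delimited by inter-peak midpoints) the
#' acceleration is integrated by the cumulative trapezoidal rule; the
#' resulting velocity is linearly detrended so that it is exactly zero at
#' both segment boundaries, and a second integration of the corrected
#' velocity yields displacement, reset to zero at each segment start.
#'
#' @param sig a 1-D [movement_signal] in m/s^2
#' @param peaks integer peak indices from [detect_peaks()]
#' @return object of class `kinematic_series`: list with `t`, `velocity`,
#'   `displacement`, `fs`, `peaks`, `boundaries`, `task`
#' @export
integrate_zupt <- function(sig, peaks) {
  stopifnot(inherits(sig, "movement_signal"), !is.matrix(sig$value))
  if (length(peaks) < 1) stop("at least one peak is required")
  x <- sig$value
  n <- length(x)
  dt <- 1 / sig$fs
  bounds <- segment_boundaries(peaks, n)
  velocity <- numeric(n)
  displacement <- numeric(n)
  for (k in seq_len(length(bounds) - 1)) {
    i0 <- bounds[k]
    i1 <- bounds[k + 1]
    m <- i1 - i0 + 1
    if (m < 3) stop("segment ", k, " is shorter than 3 samples")
    v <- cumtrapz(x[i0:i1], dt)
    v <- v - seq(0, v[m], length.out = m)  # both endpoints forced to zero
    velocity[i0:i1] <- v
    displacement[i0:i1] <- cumtrapz(v, dt)
  }
  structure(list(t = sig$t, velocity = velocity,
                 displacement = displacement, fs = sig$fs,
                 peaks = as.integer(peaks), boundaries = bounds,
                 task = sig$task),
            class = "kinematic_series")
}

#' Angular displacement by single integration
#'
#' Cumulative trapezoidal integral of the angular velocity; no drift
#' correction is applied (the gyroscope path is stable enough that a
#' zero-update is unnecessary).
#'
#' @param sig a 1-D [movement_signal] in degrees/s
#' @param peaks optional peak indices to carry along for segmentation
#' @return a `kinematic_series` with `velocity` in degrees/s and
#'   `displacement` in degrees
#' @export
angular_displacement <- function(sig, peaks = integer(0)) {
  stopifnot(inherits(sig, "movement_signal"), !is.matrix(sig$value))
  disp <- cumtrapz(sig$value, 1 / sig$fs)
  structure(list(t = sig$t, velocity = sig$value, displacement = disp,
                 fs = sig$fs, peaks = as.integer(peaks),
                 boundaries = segment_boundaries(peaks, length(disp)),
                 task = sig$task),
            class = "kinematic_series")
}

#' Materialize per-movement segments
#'
#' One segment per detected peak. Peak speed is the maximum absolute
#' velocity within the segment. Amplitude is task-specific: for the
#' accelerometer path (FS) the vertical excursion above the segment-start
#' displacement; for the gyroscope path (HPS) the signed angle travelled
#' between the segment boundaries (reversal points).
#'
#' @param series a `kinematic_series`
#' @param peaks integer peak indices (defaults to those stored in `series`)
#' @return data.frame with columns `index`, `t_start`, `t_peak`, `t_end`,
#'   `peak_speed`, `amplitude`
#' @export
build_segments <- function(series, peaks = series$peaks) {
  stopifnot(inherits(series, "kinematic_series"))
  if (length(peaks) == 0) stop("peaks must be non-empty")
  bounds <- segment_boundaries(peaks, length(series$velocity))
  out <- lapply(seq_along(peaks), function(k) {
    i0 <- bounds[k]; i1 <- bounds[k + 1]
    v <- series$velocity[i0:i1]
    d <- series$displacement[i0:i1]
    amp <- if (series$task == "HPS") d[length(d)] - d[1] else max(d) - d[1]
    data.frame(index = k,
               t_start = series$t[i0],
               t_peak = series$t[peaks[k]],
               t_end = series$t[i1],
               peak_speed = max(abs(v)),
               amplitude = amp)
  })
  do.call(rbind, out)
}
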