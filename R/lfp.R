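# Subthalamic beta-band power analysis: per-block median normalization,
# spectral validation of the configured beta-peak, complex Morlet
# time-frequency representations, responder classification and change
# scores.

#' Neurofeedback display band around the beta-peak
#'
#' The feedback visualization covers the individual beta-peak +/- 2.5 Hz
#' (a 5 Hz band). Peaks outside the canonical 13-30 Hz beta range are
#' allowed (the device permits them) but trigger a warning.
#'
#' @param beta_peak_hz individual beta-peak frequency in Hz
#' @return numeric `c(low, high)` in Hz
#' @examples
#' feedback_band(19.53)  # 17.03 22.03
#' @export
feedback_band <- function(beta_peak_hz) {
  stopifnot(is.numeric(beta_peak_hz), length(beta_peak_hz) == 1,
            beta_peak_hz > 0)
  if (beta_peak_hz < 13 || beta_peak_hz > 30) {
    warning("beta-peak ", beta_peak_hz, " Hz lies outside the 13-30 Hz band")
  }
  c(beta_peak_hz - 2.5, beta_peak_hz + 2.5)
}

#' Normalize a band-power series to a baseline window
#'
#' Divides every sample by the median power inside the given rest window,
#' so the rest-period median of the normalized series is exactly 1.
#'
#' @param power data.frame with columns `t_s`, `power`
#' @param baseline_window numeric `c(t_start, t_end)` in seconds (half-open)
#' @return data.frame with the same shape, `power` normalized
#' @export
normalize_block <- function(power, baseline_window) {
  sel <- power$t_s >= baseline_window[1] & power$t_s < baseline_window[2]
  if (sum(sel) < 2) stop("baseline window contains fewer than 2 samples")
  med <- stats::median(power$power[sel])
  if (med == 0) stop("baseline median power is zero")
  power$power <- power$power / med
  power
}

#' Normalize an LFP session block by block
#'
#' Each block's band-power samples are divided by the median power of that
#' block's initial rest segment.
#'
#' @param session an [lfp_session]
#' @return the session with normalized band power (`normalized = TRUE`)
#' @export
normalize_lfp <- function(session) {
  stopifnot(inherits(session, "lfp_session"))
  if (session$normalized) return(session)
  bp <- session$band_power
  seg <- session$segments
  for (blk in unique(seg$block)) {
    s <- seg[seg$block == blk, ]
    rest <- s[s$label == "rest", ][1, ]
    if (is.na(rest$t_start_s)) stop("block '", blk, "' has no rest segment")
    blk_win <- c(min(s$t_start_s), max(s$t_end_s))
    sel <- bp$t_s >= blk_win[1] & bp$t_s < blk_win[2]
    base <- bp$t_s >= rest$t_start_s & bp$t_s < rest$t_end_s
    if (sum(base) < 2) stop("rest segment of block '", blk, "' too short")
    med <- stats::median(bp$power[base])
    if (med == 0) stop("zero baseline median in block '", blk, "'")
    bp$power[sel] <- bp$power[sel] / med
  }
  session$band_power <- bp
  session$normalized <- TRUE
  session
}

# Median normalized power of one protocol segment; NA when no samples.
segment_median <- function(session, block, label) {
  win <- protocol_window(session$segments, block, label)
  sel <- session$band_power$t_s >= win[1] & session$band_power$t_s < win[2]
  if (!any(sel)) return(NA_real_)
  stats::median(session$band_power$power[sel])
}

#' Per-segment summaries of normalized beta-power
#'
#' Median normalized power and percent change versus the block baseline
#' (rest = 1) for every protocol segment. Segments without band-power
#' samples are omitted with a warning.
#'
#' @param session a normalized [lfp_session] (normalized on the fly
#'   otherwise)
#' @return data.frame with columns `block`, `label`,
#'   `median_normalized_power`, `pct_change_vs_baseline`
#' @export
block_summaries <- function(session) {
  session <- normalize_lfp(session)
  seg <- session$segments
  med <- mapply(segment_median, seg$block, seg$label,
                MoreArgs = list(session = session))
  if (anyNA(med)) {
    warning("segments without band-power samples omitted: ",
            paste(seg$label[is.na(med)], collapse = ", "))
  }
  out <- data.frame(block = seg$block, label = seg$label,
                    median_normalized_power = med,
                    pct_change_vs_baseline = (med - 1) * 100)
  out[!is.na(med), ]
}

#' Welch spectrum and beta-peak validation
#'
#' Averaged periodogram (2 s Hann segments, 50 percent overlap) of a raw
#' LFP stretch; the beta-peak estimate is the spectral argmax within
#' 13-30 Hz, reported together with its offset from the configured peak.
#' A peak whose power fails to rise above 2 x the median beta-band power
#' is flagged low-confidence.
#'
#' @param raw numeric raw LFP samples (>= 10 s)
#' @param fs_raw sampling rate in Hz
#' @param configured_peak_hz optional device-configured peak for the offset
#' @return list with `freq`, `psd`, `peak_hz`, `offset_hz`,
#'   `low_confidence`
#' @export
spectrum_and_peak <- function(raw, fs_raw, configured_peak_hz = NULL) {
  if (is.null(raw)) stop("raw LFP channel is absent")
  if (length(raw) < 10 * fs_raw) stop("need at least 10 s of raw signal")
  sp <- welch_psd(raw, fs_raw)
  beta <- sp$freq >= 13 & sp$freq <= 30
  pk <- which.max(sp$psd * beta)
  peak_hz <- sp$freq[pk]
  low_conf <- sp$psd[pk] < 2 * stats::median(sp$psd[beta])
  offset <- if (is.null(configured_peak_hz)) NA_real_ else
    configured_peak_hz - peak_hz
  list(freq = sp$freq, psd = sp$psd, peak_hz = peak_hz,
       offset_hz = offset, low_confidence = low_conf)
}

#' Time-frequency representation with complex Morlet wavelets
#'
#' Squared-magnitude wavelet transform (`cmor` with bandwidth 0.5 and
#' center frequency 5.0) with Savitzky-Golay temporal smoothing
#' (window 21 samples, order 3) per frequency row. Smoothing can be
#' disabled for quantitative use.
#'
#' @param raw numeric raw LFP samples
#' @param fs_raw sampling rate in Hz
#' @param freqs frequency grid in Hz (inside (0, Nyquist))
#' @param smooth apply the Savitzky-Golay smoother
#' @return list with `t`, `freqs`, and `power` (freq x time matrix)
#' @export
tfr_morlet <- function(raw, fs_raw, freqs, smooth = TRUE) {
  if (is.null(raw)) stop("raw LFP channel is absent")
  if (any(freqs >= fs_raw / 2)) stop("frequency grid exceeds Nyquist")
  W <- cwt_morlet(raw, fs_raw, freqs)
  P <- Mod(W)^2
  if (smooth && ncol(P) >= 21) {
    for (i in seq_len(nrow(P))) P[i, ] <- sgolay_smooth(P[i, ], 21L, 3L)
  }
  list(t = (seq_len(ncol(P)) - 1) / fs_raw, freqs = freqs, power = P)
}

#' Classify a participant as responder or non-responder
#'
#' A responder shows reduced beta-power in the third neurofeedback
#' training block: the median normalized power of the block-3
#' downregulation phase must fall strictly below 1 (the block's own rest
#' baseline). A median of exactly 1 classifies as non-responder.
#'
#' @param session a (normalized) [lfp_session] containing blocks
#'   `nf1`-`nf3`, or a list of three numeric normalized-power series (the
#'   downregulation phases of the three training blocks)
#' @return `"responder"` or `"non_responder"`
#' @export
classify_responder <- function(session) {
  if (inherits(session, "lfp_session")) {
    session <- normalize_lfp(session)
    blocks <- c("nf1", "nf2", "nf3")
    if (!all(blocks %in% session$segments$block)) {
      stop("session lacks the three neurofeedback training blocks")
    }
    med3 <- segment_median(session, "nf3", "nf")
    if (is.na(med3)) stop("no band-power samples in training block 3")
  } else {
    if (!is.list(session) || length(session) != 3) {
      stop("expected an lfp_session or a list of three normalized series")
    }
    if (length(session[[3]]) == 0) stop("training block 3 is empty")
    med3 <- stats::median(session[[3]])
  }
  if (med3 < 1) "responder" else "non_responder"
}

#' Beta-power change score
#'
#' `Delta beta = median(pre) - median(post)`: larger values reflect greater
#' beta reduction from the pre- to the post-neurofeedback segment.
#'
#' @param pre,post normalized band-power samples of the two segments
#' @return numeric change score
#' @export
beta_change <- function(pre, post) {
  if (length(pre) == 0 || length(post) == 0) stop("empty segment series")
  stats::median(pre) - stats::median(post)
}
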