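---
title: "Methods: movement quality from IMUs and subthalamic beta-power during neurofeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement quality from IMUs and subthalamic beta-power during neurofeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Parkinsonian bradykinesia shows up in repetitive motor tasks as reduced
speed and amplitude, irregular timing (halts), diminished smoothness, and
progressive amplitude decrement. `betamove` quantifies these features from
a single wearable inertial sensor during two seated probes: ten rapid
full-foot stomps (ankle sensor, accelerometer path) and ten alternating
wrist rotations (wrist sensor, gyroscope path). In parallel it analyzes
the subthalamic local field potential that sensing-enabled DBS implants
record: power in a 5 Hz band centered on the individual beta-peak,
streamed at 2 Hz, which participants attempt to downregulate through
visual neurofeedback. The analysis questions are (i) does movement quality
improve from the pre- to the post-neurofeedback execution, and (ii) does
the size of the beta reduction predict the size of the behavioral gain.

## IMU processing chain and its assumptions

The accelerometer path applies, in fixed order: quaternion rotation from
the sensor to the global frame, conversion from g to m/s² with subtraction
of 9.81 m/s² from the global z-axis, zero-phase high-pass filtering at
0.5 Hz, task-window segmentation, and downsampling to 50 Hz. The gyroscope
path uses only the rotation and the high-pass filter before segmentation
and downsampling.

Assumptions a user should know about:

- **Orientation is taken as given.** Quaternions (Hamilton convention,
  scalar-first, active sensor→global) come from the device; no sensor
  fusion is performed. Gravity compensation therefore only works if the
  quaternions are trustworthy.
- **Filter realization.** Only the 0.5 Hz cutoff is dictated by the
  method; the realization is a design choice. We use a 4th-order
  Butterworth applied forward–backward. Zero phase matters because peak
  *timing* anchors the segment boundaries and the interval/halt metrics;
  a causal filter would delay impacts by a signal-dependent lag. Edge
  padding is odd-reflection with length three times the slowest pole's
  time constant, so the startup transient of the low cutoff dies inside
  the padding.
- **Downsampling is Fourier-domain resampling** (spectrum truncation at
  the new Nyquist — an ideal anti-alias filter). An IIR anti-alias filter
  of reasonable order cannot keep a 20 Hz tone within 1% when decimating
  200→50 Hz; spectral truncation can, for integer and non-integer ratios
  alike. The cost is the implicit periodicity assumption, which is benign
  here because high-passed task signals start and end near zero.
- **Zero-velocity updates.** Velocity is the cumulative trapezoidal
  integral of acceleration within each movement segment (segments run
  between inter-peak midpoints; stomps are impact-centered with rest in
  between), then linearly detrended so that it is exactly zero at both
  boundaries. This is the standard ZUPT-style drift limiter for cyclic
  stationary tasks; it assumes the limb really is at rest between
  movements. Displacement restarts at zero per segment. The gyroscope path
  integrates once without correction — angular drift over a few seconds is
  negligible relative to 160° turns.
- **Linear, not higher-order, drift correction.** The method leaves the
  correction order open; linear detrending is exact for a constant
  accelerometer bias and is the least-assuming choice.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cutoff` (high-pass) | 0.5 | Hz | stated by the method; removes orientation-error and integration drift |
| `target_fs` | 50 | Hz | stated; movement energy is < 15 Hz |
| `min_distance` (peaks) | 0.25 | s | conservative: fastest plausible repetition ~3/s |
| `min_prominence` | min(2·MAD, max/4) | signal units | MAD alone over-rejects high-duty rectified signals (wrist-rotation lobes where MAD ≈ half the amplitude); the max/4 cap restores sanity while staying scale-free |
| `envelope_s` (strike envelope) | 0.15 | s | impacts are oscillatory bursts; the moving-RMS envelope gives one hump per stomp |
| `threshold_factor` (segmentation) | 5 × quiet median, floored at 5% of envelope peak | — | deterministic stand-in for visual segmentation; the floor prevents near-noiseless recordings (threshold → 0) from having their window inflated by zero-phase ringing tails |
| `pad_s` (segmentation) | 0.25 | s | keeps onset/offset ramps of the first/last movement inside the window |
| SPARC `fc`, `amp_th`, `padlevel` | 10 Hz, 0.05, 4 | — | the published defaults of the spectral-arc-length measure |
| Savitzky–Golay window/order | 21 / 3 | samples | the source prints window 20, which odd-window implementations reject; 21 is the nearest valid value |
| Morlet bandwidth / center | 0.5 / 5.0 | — | the `cmor0.5-5.0` family used for the time–frequency maps |
| TOST SESOI | 0.3 × SD(pre) | — | stated smallest effect size of interest |
| bootstrap `B` | 5000 | resamples | stated resample count |

Two metric-level choices were genuinely open and are worth flagging:

- **Rate.** `N / T` depends entirely on the window convention: any window
  that covers the pulses of a 1.5 Hz train gives 1.59–1.67 /s, not 1.5.
  For N ≥ 2 we report `N / (peak span + one mean interval)`, which equals
  the reciprocal mean inter-peak interval — window-independent and
  unbiased for regular trains. Single-movement recordings fall back to
  `N / window duration`.
- **Log-dimensionless jerk.** The integrand is the squared *second*
  time-derivative of velocity; with the first derivative the quantity
  would not be dimensionless. The implementation reproduces the analytic
  minimum-jerk value `−ln(204.8)` to within discretization error.
- **ΔA split.** With an odd movement count the middle movement joins the
  first half — an arbitrary but deterministic tie-break.
- **Responder rule.** Median normalized beta-power of training block 3
  strictly below 1; exactly 1 classifies as non-responder.
- **Magnitude summary.** The per-execution "acceleration magnitude" is the
  mean of the magnitude series over the task window.

## The synthetic world

The generators state the world the pipeline assumes; their defaults are
the experiment's stated conditions where known (10 stomps, 10 turns,
200 Hz IMU rate, 60 s rests, 60 s neurofeedback phases, 35 s inter-task
rest, 5 Hz feedback band, 2 Hz band-power rate) and a documented one-time
choice elsewhere:

- **Stomps** are raised-cosine velocity lobe pairs: v and a are continuous
  and zero at the pulse edges, the foot rises to exactly the scheduled
  height and returns to rest with zero net velocity, and the peak velocity
  is 4·h/Tp in closed form. Default rate 1.5 Hz, height 0.12 m, pulse
  0.3 s. Gravity is injected on the sensor z-axis before rotation through
  a 10° tilt plus slow z-drift, so the frame-transformation path is
  exercised non-trivially. Sensor noise defaults to 0.1 m/s².
- **Turns** are alternating half-sine angular-velocity lobes whose
  time-integral is exactly ±amplitude (default 160°) at 2 turns/s. The
  rate matters: slower trains push the angle waveform's fundamental toward
  the 0.5 Hz high-pass corner, and amplitude recovery would then measure
  filter roll-off, not kinematics.
- **LFP** is 1/f Gaussian background plus a beta-peak sinusoid whose
  amplitude is scaled per protocol segment; the 2 Hz stream is mean Morlet
  power in the feedback band over a trailing 6 s window. Raw sampling rate
  defaults to 250 Hz (typical for the implant class; the source never
  states it). Because power is quadratic in amplitude, a modulation factor
  f maps to a band-power ratio between f² (strong beta) and 1 (pure
  background); with the default SNR a 0.85 factor yields ≈ −27%.

What the generators do **not** emulate: tremor, stimulation and movement
artifacts, medication fluctuations, inter-subject kinematic variability,
non-stationary beta bursts. A green parameter-recovery test therefore
establishes that the pipeline inverts its own stated world — not that it
is robust to everything a clinic produces.

## Statistical layer

Differences are post − pre; zero differences are dropped (the printed
p-values of the source analysis are only consistent with reduced effective
n); absolute differences are ranked with mid-ranks; the two-sided exact
p-value is `min(1, 2·P(T⁺ ≤ W))` from the null distribution computed by a
dynamic program over doubled mid-ranks — exact for any tie pattern and
verified against full 2ⁿ enumeration. No multiple-testing correction is
applied anywhere; every metric is reported raw, deliberately.

Effect sizes are paired Cohen's d_z = mean(d)/sd(d) with a seeded
percentile bootstrap over pairs. **Known limitation:** at n = 10 the
percentile bootstrap CI of d_z undercovers — about 85% observed coverage
instead of 95% in our calibration runs. We keep the percentile method
because it is the prescribed analysis, and we surface the shortfall
rather than silently substituting a different interval; treat the CIs as
descriptive at small n. The exact Wilcoxon test itself is calibrated
(type-I ≈ 0.049 at the 0.05 level, the usual conservatism of a discrete
null).

Equivalence uses two one-sided paired t-tests against ±0.3·SD(pre);
`p_max` is the larger one-sided p, equivalence declared at `p_max < 0.05`.
Coupling analyses z-score both series, report Pearson or Spearman
coefficients with asymptotic p-values and percentile bootstrap CIs, and
the change-score analysis uses Δβ = β_pre − β_post (larger = more
reduction) against Δspeed = speed_post − speed_pre (larger = faster).

## Degenerate inputs and tie-breaks

All-zero differences: error ("degenerate pairing"). Zero pre-variance in
TOST, constant inputs to correlation, zero baseline median in
normalization, all-zero speed profiles in SPARC/LDJ: errors, not NAs.
Segments shorter than 3 samples abort integration with the segment named.
An empty peak-detection result is a valid return (no error); the metric
orchestrator converts it into an explicit "no movements detected" failure.

## Known limitations

- The 0.5 Hz high-pass biases the first/last turn amplitudes of the
  gyroscope path (transient of the alternating-angle waveform); mean turn
  amplitude reads ~5% low. Pre/post comparisons are unaffected because the
  bias is common to both executions.
- At the native 200 Hz, trapezoidal double integration of a 0.3 s pulse
  carries ~0.3% discretization error (quadratic in the step size).
- The LFP band-power stream crosses segment boundaries with its trailing
  6 s window, exactly as the real device does; medians over 60 s segments
  make this negligible, but very short custom segments would smear.
- Automatic segmentation is a deterministic surrogate for visual
  segmentation; a manual window always wins when provided.
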