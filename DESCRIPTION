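Package: betamove
Title: Movement Quality Metrics and Subthalamic Beta-Power Analysis for
    DBS Neurofeedback Studies
Version: 0.1.0
Authors@R:
    person("betamove", "maintainers", email = "betamove@example.org",
           role = c("aut", "cre"))
Description: Quantifies movement quality from wearable inertial sensors
    during two standardized motor tasks (seated foot stomping and hand
    pronation-supination) and analyzes subthalamic beta-band power during
    deep-brain-stimulation-based neurofeedback. Provides the full chain
    from raw 200 Hz IMU streams (quaternion frame transformation, gravity
    compensation, high-pass filtering, downsampling) through
    zero-velocity-update kinematic integration to a bradykinesia-aligned
    metric set (rate, peak velocity, amplitude, spectral arc length,
    log-dimensionless jerk, halts, amplitude decrement); local field
    potential band-power normalization, Welch spectra, complex Morlet
    time-frequency analysis, and responder classification; and the
    statistical layer used in small paired neurofeedback cohorts: exact
    Wilcoxon signed-rank tests, bootstrapped standardized mean
    differences, TOST equivalence testing, and beta-behavior coupling
    analyses. A synthetic-data module generates IMU and LFP recordings
    with known ground truth so every stage is testable by parameter
    recovery without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
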