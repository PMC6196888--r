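Package: pttbp
Title: Baroreflex-Coupled Error Analysis of Pulse-Transit-Time Blood Pressure Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying why cuff-less blood pressure estimation from
    pulse transit time (PTT) fails in the low-frequency band. Implements a
    beat-to-beat cardiovascular cohort simulator with a logistic arterial
    baroreflex (ABR) heart-rate curve and heart-rate-variability coupling into
    PTT; ECG/PPG/BP waveform synthesis and fiducial extraction (R peaks, PPG
    upstroke, per-cycle systolic/diastolic pressures); inverse and logarithmic
    PTT-to-BP calibration by ordinary least squares; variational mode
    decomposition (VMD) of beat-to-beat pressure series into low-frequency
    (0.1-0.15 Hz) and high-frequency (0.2-0.35 Hz) components; dynamic
    baroreflex sensitivity by sliding-window two-quadrant sequence regression;
    and cohort-level correlation statistics comparing band-wise estimation
    errors against baroreflex sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
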