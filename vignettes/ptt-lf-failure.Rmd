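---
title: "Why PTT-based blood-pressure estimation fails in the low-frequency band: models, simulator design and numerical choices"
author: "pttbp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Beat-to-beat blood pressure carries two characteristic oscillations: a
high-frequency component (HF, 0.2–0.35 Hz) driven mechanically by
respiration, and a low-frequency component (LF, 0.1–0.15 Hz, Mayer waves)
mediated by the autonomic nervous system. Cuff-less estimators that map
pulse transit time (PTT) to pressure through a subject-specific calibration
track the HF component well but systematically mistrack the LF component.
The working hypothesis implemented here is that the arterial baroreflex
(ABR) is the culprit: where the baroreflex operates in its sensitive
region, LF pressure swings drive large heart-rate variability (HRV), HRV
perturbs PTT through mechanisms unrelated to the calibrated pressure–PTT
relation, and the estimator inherits an LF-band error that grows with the
subject's baroreflex gain. The package's analysis chain quantifies this by
correlating, within each subject, the magnitude of the band-wise estimation
error with dynamically estimated baroreflex sensitivity (BRS), then
comparing the LF and HF correlation groups across a cohort.

## The analysis chain

1. **Beat series.** Per cardiac cycle: R-wave time, RR interval (RRi, ms),
   PTT (ms), systolic and diastolic pressure (SBP/DBP, mmHg). From raw
   waveforms these come from `extract_beat_series()`; from the simulator
   they are exact.
2. **Calibration** (`fit_ptt_bp()`): ordinary least squares of reference
   pressure on `1/PTT` (inverse form, the default — experimentally `1/PTT`
   rather than PTT is linearly related to pressure) or on `ln PTT`.
   One fit per subject per target over the full recording; a single fit is
   the minimal reading of an "adaptively trained" per-subject calibration,
   and sliding recalibration is deliberately left out of scope.
3. **Band decomposition** (`decompose_lf_hf()`): the uneven beat series is
   cubic-spline resampled to a uniform 4 Hz grid, decomposed by
   variational mode decomposition (VMD), band components are formed by
   summing modes whose centre frequency falls inside the band, and the
   result is interpolated back to the beat times so errors stay per-beat.
4. **Dynamic BRS** (`dynamic_brs()`): the time-domain sequence method on a
   sliding window of 16 first-difference pairs, advancing one beat at a
   time. Within a window, pairs with `dRRi < 0 & dSBP < 0` and pairs with
   `dRRi > 0 & dSBP > 0` form two sets; the OLS slope of dRRi on dSBP is
   computed in each and the window's BRS is their mean. Zero differences
   join neither set (the inequalities are strict). A set with fewer than
   two pairs — or with degenerate dSBP variance — contributes no slope; if
   one set remains the window falls back to it alone, and if none does the
   window is flagged invalid rather than given an undefined average. The
   window's BRS is indexed to its start beat.
5. **Cohort statistics** (`run_full_analysis()`): six error series per
   subject (overall, LF and HF, for SBP and DBP; always estimate minus
   reference), each correlated with BRS across the valid windows; cohort
   mean, population standard deviation (divisor N) and minimum absolute
   value of the per-subject correlations per group; pooled two-sample t
   tests between the LF and HF groups per target.

### Signed errors versus error magnitudes

The error–BRS correlation defaults to `error_type = "absolute"` (correlate
|error| with BRS). The signed alternative remains available, but it cannot
carry the effect of interest: a band-limited error series is a zero-mean
oscillation, and its correlation with the slowly varying BRS series reduces
to a phase artifact of the pairing convention. Empirically (lag-scan
experiments during development) the signed per-subject correlation
oscillates between roughly −0.1 and +0.1 as the error–window pairing lag is
varied and its sign flips with the subject's LF frequency — it measures
alignment, not coupling. Error magnitude, by contrast, co-varies with the
momentary baroreflex gain, which is exactly the mechanism under study, and
is the only reading compatible with cohorts whose per-subject LF
correlations are uniformly strongly positive.

## The cohort simulator

The simulator is beat-domain first: the analysis operates on beat series,
so ground truth is kept exact there, and waveforms are rendered only to
exercise the fiducial detectors.

Per beat at time *t*:

* `SBP(t) = baseline + lf_amp·sin(2π·lf_freq·t + φ_LF) +
  hf_amp·sin(2π·hf_freq·t + φ_HF) + ε`, with phases drawn uniformly per
  subject and ε white Gaussian (`noise_sd`).
* Heart rate follows the logistic ABR curve
  `HR(P) = HR_l + (HR_h − HR_l)/(1 + e^{−ε(P−P_n)})` evaluated at an
  effective pressure blending two baroreflex pathways: a fast beat-scale
  arm (weight 0.5, the vagally mediated response the sequence method
  relies on) and a slow arm seeing the running mean of SBP over one
  respiratory cycle (`1/hf_freq` seconds). The averaging window nulls its
  own frequency response at the respiratory rate — respiratory gating — so
  the slow pathway transmits Mayer-wave pressure variation and suppresses
  HF variation. `RRi = 60000/HR` advances the beat clock.
* `PTT = k1_true/(SBP − k2_true) + hrv_ptt_gain·ΔHR_slow + η`, where
  `ΔHR_slow` is the beat difference of the slow-pathway (sympathetically
  mediated) heart-rate component and `hrv_ptt_gain ≤ 0`. Sympathetic tone
  sets vascular stiffness, which is why the PTT disturbance rides on the
  slow component; because that component is LF-selective, the estimator's
  LF error scales with the subject's momentary baroreflex gain while its
  HF error stays noise-dominated.
* `DBP = SBP − PP` with
  `PP = pp_baseline + dbp_mod_scale·(SBP − sbp_baseline) + ε_d`:
  pulse pressure widens affinely as pressure rises. This keeps SBP > DBP
  by construction, scales DBP band amplitudes by `1 − dbp_mod_scale`, and
  makes DBP obey its own inverse PTT law (`K1_DBP = 0.65·k1_true` at the
  default scale). An additive pulse-pressure process that carries scaled
  LF/HF terms but not the scaled baseline shift was tried first and
  rejected: it breaks the inverse law for DBP, so the DBP calibration
  acquires a forcing-proportional bias independent of baroreflex gain that
  swamps the coupling signal.

Two further design points deserve emphasis:

* **Orientation of the ABR curve.** The logistic curve is implemented
  verbatim for either sign of ε. With ε > 0 heart rate *rises* with
  pressure; since the simulator's RRi is then an exactly decreasing
  function of SBP, same-direction (dRRi, dSBP) pairs never occur and the
  sequence method degenerates (every window invalid). Cohort defaults
  therefore use the classical reflex orientation, ε < 0 (heart rate falls
  as pressure rises), with sensitivity magnitudes drawn from
  0.05–0.5 /mmHg.
* **Session structure.** `simulate_cohort()` defaults to a two-state
  rest/recovery session (`"prepost"`, 20 min total by default, split in
  equal halves): the second half's systolic baseline rises by 8–18 mmHg,
  the baroreceptor set point resets by the same amount, and ABR
  sensitivity is scaled by 0.25–0.5 (exercise withdraws vagal tone and
  roughly halves baroreflex gain, or more). This protocol-driven
  nonstationarity is what gives BRS meaningful within-subject variation;
  on a fully stationary recording every within-subject error–BRS
  correlation is statistically indistinguishable from zero, for magnitude
  and signed errors alike. Single-segment recordings remain available via
  `session = "single"`.

What the generator deliberately does **not** emulate: ECG morphology
beyond the R wave, pulse-morphology change with vascular tone, motion
artifacts, respiratory-rate drift, circadian or thermoregulatory
very-low-frequency variability, and any feedforward HR→BP effect. Passing
tests therefore demonstrate the correctness and internal consistency of
the analysis chain and the plausibility of the ABR mechanism — not that
real recordings will show correlations of any particular size.

### Default parameter ranges

Cohort draws are uniform and independent per subject
(see `cohort_ranges()`): HR plateaus 50–65 / 95–130 bpm, baseline SBP
110–135 mmHg with the logistic midpoint within ±5 mmHg of it, pulse
pressure 35–50 mmHg, LF amplitude 2–5 mmHg at 0.10–0.15 Hz, HF amplitude
1.5–4 mmHg at 0.20–0.35 Hz, `k1_true` 25 000–35 000 mmHg·ms, `k2_true`
0–20 mmHg, coupling gain −1.5 to −0.5 ms per beats/min, SBP noise 0.6–1.2
mmHg (PTT noise defaults to twice the SBP noise in ms; DBP noise to half).
These are chosen once, from resting-physiology ranges for healthy young
adults, so that PTT sits near 250–280 ms, beat-to-beat systolic
variability is a few mmHg, and sequence-method BRS spans a wide
physiological range across subjects.

## Waveform synthesis and fiducial extraction

The renderer places a Gaussian R wave (SD 8 ms) at each beat time, a PPG
pulse (raised-cosine upstroke of 120 ms, exponential decay with a dicrotic
bump) anchored so that the steepest upstroke sample sits exactly at
R + PTT, and a per-cycle pressure contour whose maximum and minimum equal
the beat's SBP and DBP. Records carry a 0.5 s baseline pad on each side so
the first and last templates are not clipped.

Conditioning follows common acquisition-system defaults: 0.5–35 Hz for
ECG, 0.05–10 Hz for PPG, each corner a 4th-order Butterworth applied
forward-backward (zero phase) so fiducial timing is not shifted. R peaks
are detected with a derivative-energy (Pan–Tompkins-style) detector with a
150 ms integration window, a robust-quantile threshold, a 250 ms
refractory period, and refinement to the local ECG maximum. PPG fiducials
are searched within the half-open RR window after each R peak, peak first,
then the steepest upstroke before the peak (on a 10 ms smoothed first
difference), then the foot minimum before the upstroke — which enforces
the PTT3 ≤ PTT2 ≤ PTT1 ordering on clean pulses. The last beat has no
closing window and is dropped; beats with PTT outside 50–600 ms, RRi
outside 300–2000 ms, flagged PPG windows, or degenerate pressure extrema
are dropped with a logged reason. The default PTT variant is PTT2 (the
maximal first-derivative point), the most robust of the three in practice.
On a 42-subject synthetic cohort at 1000 Hz, the median PTT round-trip
error is well under 1 ms (tolerance target: 2 ms).

## VMD: numerical choices

The decomposition is the standard ADMM scheme: spectral-domain Wiener
updates `u_k = (f − Σ_{j≠k} u_j − λ/2)/(1 + α(ω − ω_k)²)`, centre
frequencies as power-weighted mean frequencies, dual ascent only when
`τ > 0`. Defaults follow the reference implementation of the method:
K = 5 modes, α = 2000, τ = 0, tolerance 1e−7 on the summed spectral mode
change, at most 500 iterations, uniform centre-frequency initialisation,
no enforced DC mode. The signal mean is removed first (it belongs to
neither band). Two implementation notes:

* The iteration runs on the positive half-spectrum only — the negative
  half is identically zero through every update — which halves the work
  without changing any result.
* Boundary treatment: the usual even mirror extension leaves a slope
  discontinuity exactly at the crop points, and the resulting edge ringing
  alone can push the relative reconstruction error of a clean two-tone
  signal above 5 %. The extension here cross-fades over 16 samples from
  point reflection (slope-continuous at the fold) into the even mirror,
  which removes the kink while keeping the extension bounded; on the
  two-tone construction the reconstruction error drops to about 3 % and
  centre-frequency errors to a few 1e−4 Hz, robustly over random phases.

Band assignment is by centre-frequency membership in [0.10, 0.15] Hz or
[0.20, 0.35] Hz; modes falling between the bands belong to neither, and an
empty band yields a zero series with a warning rather than an error.
Long noisy beat series occasionally hit the 500-iteration cap; the result
is then returned with `converged = FALSE` and a warning, and in practice
the band components are already stable at that point.

## Problem sizes used in the test suite

The automated tests run everything at sizes that keep the suite within
minutes on a single core, stated here as the package's reference
configurations: the headline cohort property uses 42 subjects per cohort,
600 s per subject (two 300 s states), 10 coupled and 10 null cohort seeds;
the fiducial round trip uses 42 subjects of 60 s at 1000 Hz; the BRS
ranking uses a 5-point sensitivity grid × 10 seeds of 300 s subjects; the
BRS oracle comparison uses 1000 random series of 24–40 beats. The default
`cohort_ranges()` duration remains the full 20-minute protocol.

## Known limitations

* The LF/HF contrast in the error–BRS coupling is a property of the
  modelled mechanism (LF-selective sympathetic disturbance of PTT); the
  package demonstrates that the analysis chain detects it when present and
  stays silent on null cohorts, not that the mechanism is the only or main
  cause of LF mistracking in humans.
* The sequence method here sees an RRi that responds to pressure within
  the beat (the fast pathway); with purely sluggish HR control, window
  regressions of dRRi on dSBP estimate essentially nothing — a real
  methodological caveat for populations with depressed vagal function.
* Calibration is one OLS fit per recording; drift and posture/state
  changes within a recording are absorbed into the error series rather
  than recalibrated away.
* `pearson_r()` evaluates the product-moment formula on mean-shifted data;
  the raw-sums form, applied to a nearly constant series riding on a large
  offset (a weakly forced subject's BRS), loses all significant digits to
  cancellation.
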