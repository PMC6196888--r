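#' Specification of one synthetic subject
#'
#' Collects every parameter of the beat-domain cardiovascular simulator. The
#' systolic pressure follows
#' `SBP(t) = sbp_baseline + lf_amp sin(2 pi lf_freq t + phi_LF) +
#' hf_amp sin(2 pi hf_freq t + phi_HF) + noise`,
#' with the low-frequency (LF) oscillation in 0.1-0.15 Hz emulating
#' autonomically mediated Mayer-wave variability and the high-frequency (HF)
#' oscillation in 0.2-0.35 Hz emulating respiration-driven variability.
#' Heart rate responds to pressure through the logistic ABR curve
#' ([abr_params()]) applied to an *effective* pressure blending two
#' baroreflex pathways: a fast beat-scale arm (weight `abr_fast_weight`,
#' emulating the vagally mediated response the sequence method relies on)
#' and a slow arm that sees the time-weighted running mean of systolic
#' pressure over the past `abr_avg_s` seconds (baroreceptor afferent
#' integration plus sluggish sympathetic effector response). The averaging
#' window passes the Mayer-wave band but suppresses respiratory-rate
#' pressure oscillations (its frequency response nulls near
#' `1/abr_avg_s` Hz), so heart-rate variability tracks the LF pressure
#' oscillation while largely ignoring the HF one. Setting `abr_avg_s = 0`
#' or `abr_fast_weight = 1` recovers a memoryless beat-by-beat logistic
#' map. The RR interval `60000 / HR` advances the beat clock.
#'
#' PTT follows the inverse calibration model
#' `PTT = k1_true / (SBP - k2_true)` perturbed by heart-rate-variability
#' coupling `hrv_ptt_gain * dHR_slow` plus measurement noise, where
#' `dHR_slow` is the beat-to-beat change of the *sympathetically mediated*
#' heart-rate component (the logistic curve applied to the slow-pathway
#' pressure). The gain is non-positive: a heart-rate rise depresses PTT.
#' Sympathetic tone also sets vascular stiffness, which is why the PTT
#' disturbance rides on the slow HR component; since that component is
#' LF-selective, the perturbation corrupts the low-frequency content of
#' PTT-estimated pressure in proportion to the subject's momentary
#' baroreflex gain - the mechanism under study.
#'
#' Diastolic pressure is SBP minus a pulse-pressure process: pulse pressure
#' equals `pp_baseline` plus `dbp_mod_scale` times the momentary SBP
#' excursion from baseline, so it widens as pressure rises (as it does with
#' exercise). This keeps SBP above DBP by construction, scales every DBP
#' band amplitude by `1 - dbp_mod_scale`, and makes DBP an affine function
#' of SBP - hence DBP obeys its own inverse PTT law with
#' `k1 = (1 - dbp_mod_scale) k1_true`.
#'
#' With `session = "prepost"` the recording emulates the rest/recovery pair
#' of a treadmill-exercise protocol: during the second half the systolic
#' baseline rises by `post_sbp_shift`, the baroreceptor set point resets by
#' the same amount, and the ABR sensitivity is multiplied by
#' `post_sens_scale` (exercise withdraws vagal tone, depressing baroreflex
#' gain).
#'
#' @param abr An [abr_params()] object (the resting-state curve).
#' @param sbp_baseline Baseline systolic pressure, mmHg.
#' @param pp_baseline Baseline pulse pressure (SBP - DBP), mmHg.
#' @param lf_amp,hf_amp LF / HF systolic oscillation amplitudes, mmHg.
#' @param lf_freq LF frequency, Hz (in 0.1-0.15).
#' @param hf_freq HF frequency, Hz (in 0.2-0.35).
#' @param k1_true,k2_true Ground-truth inverse-model calibration parameters,
#'   mmHg*ms and mmHg.
#' @param hrv_ptt_gain HRV-to-PTT coupling, ms per beats/min; `<= 0`.
#' @param noise_sd White Gaussian beat-to-beat SBP noise, mmHg.
#' @param ptt_noise_sd PTT measurement noise, ms. Default `2 * noise_sd`, so
#'   a noiseless spec is noiseless throughout.
#' @param dbp_noise_sd Independent DBP measurement noise, mmHg. Default
#'   `0.5 * noise_sd`; keeps DBP from being a deterministic affine copy of
#'   SBP.
#' @param abr_avg_s Length of the slow-pathway pressure-averaging window, s.
#'   The default (`NULL`) is one respiratory cycle, `1 / hf_freq`, which
#'   nulls the averaging window's response at the respiratory frequency
#'   (respiratory gating); 0 disables the slow arm.
#' @param abr_fast_weight Weight of the fast (beat-scale, vagally mediated)
#'   pathway in the effective pressure the ABR curve sees; the remainder
#'   passes through the slow averaged pathway. In (0, 1], default 0.5
#'   (balanced vagal/sympathetic blend).
#' @param dbp_mod_scale Fraction of the LF/HF forcing routed into pulse
#'   pressure rather than DBP (0-1).
#' @param duration Total recording length, s.
#' @param session `"single"` (default) for one continuous segment or
#'   `"prepost"` for the two-state exercise protocol above (equal halves).
#' @param post_sbp_shift Baseline + set-point shift of the second half, mmHg.
#' @param post_sens_scale Multiplier on ABR sensitivity in the second half.
#' @param seed Integer seed making the subject reproducible.
#' @return An object of class `"subject_spec"`.
#' @export
subject_spec <- function(abr,
                         sbp_baseline = 120,
                         pp_baseline = 45,
                         lf_amp = 3.5,
                         hf_amp = 2.5,
                         lf_freq = 0.12,
                         hf_freq = 0.28,
                         k1_true = 30000,
                         k2_true = 10,
                         hrv_ptt_gain = -1,
                         noise_sd = 1,
                         ptt_noise_sd = NULL,
                         dbp_noise_sd = NULL,
                         abr_avg_s = NULL,
                         abr_fast_weight = 0.5,
                         dbp_mod_scale = 0.35,
                         duration = 600,
                         session = c("single", "prepost"),
                         post_sbp_shift = 12,
                         post_sens_scale = 0.4,
                         seed = 1L) {
  session <- match.arg(session)
  if (is.null(ptt_noise_sd)) ptt_noise_sd <- 2 * noise_sd
  if (is.null(dbp_noise_sd)) dbp_noise_sd <- 0.5 * noise_sd
  if (is.null(abr_avg_s)) abr_avg_s <- 1 / hf_freq
  stopifnot(inherits(abr, "abr_params"),
            lf_amp >= 0, hf_amp >= 0, noise_sd >= 0, ptt_noise_sd >= 0,
            dbp_noise_sd >= 0,
            duration > 0, k1_true > 0, pp_baseline > 0, abr_avg_s >= 0,
            abr_fast_weight > 0, abr_fast_weight <= 1,
            dbp_mod_scale >= 0, dbp_mod_scale <= 1, post_sens_scale > 0)
  if (lf_freq >= hf_freq)
    stop("lf_freq must be below hf_freq", call. = FALSE)
  if (hrv_ptt_gain > 0)
    stop("hrv_ptt_gain must be <= 0 (HRV depresses PTT)", call. = FALSE)
  structure(
    list(abr = abr, sbp_baseline = sbp_baseline, pp_baseline = pp_baseline,
         lf_amp = lf_amp, hf_amp = hf_amp, lf_freq = lf_freq,
         hf_freq = hf_freq, k1_true = k1_true, k2_true = k2_true,
         hrv_ptt_gain = hrv_ptt_gain, noise_sd = noise_sd,
         ptt_noise_sd = ptt_noise_sd, dbp_noise_sd = dbp_noise_sd,
         abr_avg_s = abr_avg_s,
         abr_fast_weight = abr_fast_weight, dbp_mod_scale = dbp_mod_scale, duration = duration,
         session = session, post_sbp_shift = post_sbp_shift,
         post_sens_scale = post_sens_scale, seed = as.integer(seed)),
    class = "subject_spec"
  )
}

#' @export
print.subject_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic subject spec (seed %d): %g s %s session\n",
    "  SBP %g mmHg + LF %g mmHg @ %g Hz + HF %g mmHg @ %g Hz, noise %g mmHg\n",
    "  ABR sensitivity %g /mmHg (tau %g s); k1 %g mmHg*ms, k2 %g mmHg; HRV->PTT gain %g ms/bpm\n"),
    x$seed, x$duration, x$session,
    x$sbp_baseline, x$lf_amp, x$lf_freq, x$hf_amp, x$hf_freq, x$noise_sd,
    x$abr$sensitivity, x$abr_avg_s, x$k1_true, x$k2_true, x$hrv_ptt_gain))
  invisible(x)
}

#' Simulate one subject beat by beat
#'
#' Runs the beat-domain simulator described in [subject_spec()]: at each beat
#' the systolic pressure is sampled from the LF + HF + noise process, heart
#' rate responds through the logistic ABR curve applied to baroreceptor-
#' filtered pressure, the RR interval advances the beat clock, and PTT is
#' generated from the inverse pressure model plus the HRV coupling term.
#' Ground-truth LF and HF pressure components are stored exactly as the two
#' sinusoid terms evaluated at the beat times.
#'
#' @param spec A [subject_spec()].
#' @return An object of class `"subject_truth"`: a list with elements
#'   `beats` (a [beat_series()]), `true_lf_sbp`, `true_hf_sbp`,
#'   `true_lf_dbp`, `true_hf_dbp` (mmHg, per beat), `hr_bpm` (per beat),
#'   `true_brs_like` (mean analytic |dRRi/dSBP| along the trajectory,
#'   ms/mmHg) and `spec`.
#' @examples
#' ab <- abr_params(55, 110, 120, -0.2)
#' tr <- simulate_subject(subject_spec(ab, duration = 120, seed = 7))
#' tr$beats
#' @export
simulate_subject <- function(spec) {
  stopifnot(inherits(spec, "subject_spec"))
  withr::with_seed(spec$seed, simulate_subject_impl(spec))
}

simulate_subject_impl <- function(spec) {
  phi_lf <- stats::runif(1, 0, 2 * pi)
  phi_hf <- stats::runif(1, 0, 2 * pi)
  n_guess <- ceiling(spec$duration / (60 / spec$abr$hr_high)) + 1L
  tt <- hr <- rri <- ptt <- sbp <- dbp <- lf <- hf <- slope <- numeric(n_guess)
  t_cur <- 0
  i <- 0L
  hr_prev <- hr_slow_prev <- NA_real_
  while (t_cur < spec$duration) {
    i <- i + 1L
    post <- spec$session == "prepost" && t_cur >= spec$duration / 2
    base <- spec$sbp_baseline + if (post) spec$post_sbp_shift else 0
    abr_cur <- if (post) {
      abr_params(spec$abr$hr_low, spec$abr$hr_high,
                 spec$abr$p_mid + spec$post_sbp_shift,
                 spec$abr$sensitivity * spec$post_sens_scale)
    } else spec$abr
    lf_i <- spec$lf_amp * sin(2 * pi * spec$lf_freq * t_cur + phi_lf)
    hf_i <- spec$hf_amp * sin(2 * pi * spec$hf_freq * t_cur + phi_hf)
    sbp_i <- base + lf_i + hf_i + stats::rnorm(1, 0, spec$noise_sd)
    if (sbp_i <= spec$k2_true)
      stop("SBP fell to k2_true or below: PTT undefined for this spec",
           call. = FALSE)
    # slow pathway: time-weighted running mean of SBP over the past
    # abr_avg_s seconds (current beat included)
    if (spec$abr_avg_s > 0 && i > 1L) {
      recent <- which(tt[seq_len(i - 1L)] >= t_cur - spec$abr_avg_s)
      # beats weighted by their RR interval; the current (incomplete) beat
      # by the running mean interval
      wts <- c(rri[recent], mean(rri[recent]))
      p_slow <- sum(c(sbp[recent], sbp_i) * wts) / sum(wts)
    } else {
      p_slow <- sbp_i
    }
    p_eff <- spec$abr_fast_weight * sbp_i +
      (1 - spec$abr_fast_weight) * p_slow
    hr_i <- abr_heart_rate(p_eff, abr_cur)
    hr_slow_i <- abr_heart_rate(p_slow, abr_cur)
    dhr_slow <- if (is.na(hr_slow_prev)) 0 else hr_slow_i - hr_slow_prev
    ptt_i <- spec$k1_true / (sbp_i - spec$k2_true) +
      spec$hrv_ptt_gain * dhr_slow +
      stats::rnorm(1, 0, spec$ptt_noise_sd)
    pp_i <- spec$pp_baseline + spec$dbp_mod_scale * (sbp_i - spec$sbp_baseline) +
      stats::rnorm(1, 0, spec$dbp_noise_sd)
    tt[i] <- t_cur; hr[i] <- hr_i; rri[i] <- 60000 / hr_i
    ptt[i] <- ptt_i; sbp[i] <- sbp_i; dbp[i] <- sbp_i - pp_i
    lf[i] <- lf_i; hf[i] <- hf_i
    slope[i] <- abs(abr_rri_slope(p_eff, abr_cur))
    hr_prev <- hr_i
    hr_slow_prev <- hr_slow_i
    t_cur <- t_cur + 60 / hr_i
  }
  keep <- seq_len(i)
  beats <- beat_series(tt[keep], rri[keep], ptt[keep], sbp[keep], dbp[keep],
                       variant = "ptt2")
  structure(
    list(beats = beats,
         true_lf_sbp = lf[keep],
         true_hf_sbp = hf[keep],
         true_lf_dbp = (1 - spec$dbp_mod_scale) * lf[keep],
         true_hf_dbp = (1 - spec$dbp_mod_scale) * hf[keep],
         hr_bpm = hr[keep],
         true_brs_like = mean(slope[keep]),
         spec = spec),
    class = "subject_truth"
  )
}

#' @export
print.subject_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic subject (seed %d): %d beats, mean HR %.1f bpm, analytic BRS proxy %.2f ms/mmHg\n",
    x$spec$seed, nrow(x$beats), mean(x$hr_bpm), x$true_brs_like))
  invisible(x)
}

#' Parameter ranges for a synthetic cohort
#'
#' Each entry is a `c(lo, hi)` interval sampled uniformly and independently
#' per subject. The defaults describe healthy young adults in a rest /
#' post-exercise-recovery protocol: baselines and band amplitudes span
#' typical beat-to-beat systolic variability, the ABR sensitivity magnitude
#' spans 0.05-0.5 /mmHg so cohort baroreflex sensitivities cover a wide
#' range, and the HRV-to-PTT coupling gain spans -1.5 to -0.5 ms per
#' beats/min. `abr_orientation` fixes the sign applied to the sampled
#' sensitivity magnitude; the default `-1` is the classical reflex
#' orientation (heart rate falls as pressure rises), which the sequence
#' method requires (see [abr_params()]).
#'
#' @param ... Named `c(lo, hi)` overrides of the defaults listed below.
#' @return A named list of ranges with class `"cohort_ranges"`.
#' @export
cohort_ranges <- function(...) {
  ranges <- list(
    hr_low = c(50, 65),
    hr_high = c(95, 130),
    sensitivity = c(0.05, 0.5),
    abr_orientation = c(-1, -1),
    p_mid_offset = c(-5, 5),
    sbp_baseline = c(110, 135),
    pp_baseline = c(35, 50),
    lf_amp = c(2, 5),
    hf_amp = c(1.5, 4),
    lf_freq = c(0.10, 0.15),
    hf_freq = c(0.20, 0.35),
    k1_true = c(25000, 35000),
    k2_true = c(0, 20),
    hrv_ptt_gain = c(-1.5, -0.5),
    noise_sd = c(0.6, 1.2),
    abr_fast_weight = c(0.5, 0.5),
    post_sbp_shift = c(8, 18),
    post_sens_scale = c(0.25, 0.5),
    duration = c(1200, 1200)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(ranges))
    if (length(bad)) stop("unknown range(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    for (nm in names(dots)) {
      v <- dots[[nm]]
      if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) || v[2] < v[1])
        stop("range '", nm, "' must be a finite c(lo, hi) with hi >= lo",
             call. = FALSE)
      ranges[[nm]] <- v
    }
  }
  structure(ranges, class = "cohort_ranges")
}

#' Simulate a cohort of subjects
#'
#' Draws `n_subjects` independent [subject_spec()]s from `ranges` and runs
#' [simulate_subject()] on each. Per-subject seeds are derived from `seed`,
#' so the whole cohort is reproducible. The default session is the
#' two-state rest/recovery protocol (`"prepost"`) of the study design the
#' cohort emulates; pass `session = "single"` for stationary recordings.
#'
#' @param n_subjects Number of subjects (`>= 2`); the emulated protocol
#'   used 42.
#' @param seed Integer cohort seed.
#' @param ranges A [cohort_ranges()] list.
#' @param session Passed to every [subject_spec()].
#' @return A list of `"subject_truth"` objects, one per subject.
#' @export
simulate_cohort <- function(n_subjects = 42, seed = 1L,
                            ranges = cohort_ranges(),
                            session = "prepost") {
  stopifnot(n_subjects >= 2, inherits(ranges, "cohort_ranges"))
  specs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_subjects), function(j) {
      draw <- function(nm) stats::runif(1, ranges[[nm]][1], ranges[[nm]][2])
      sbp0 <- draw("sbp_baseline")
      orientation <- sign(draw("abr_orientation"))
      if (orientation == 0) orientation <- 1
      abr <- abr_params(
        hr_low = draw("hr_low"), hr_high = draw("hr_high"),
        p_mid = sbp0 + draw("p_mid_offset"),
        sensitivity = orientation * draw("sensitivity"))
      subject_spec(
        abr = abr, sbp_baseline = sbp0, pp_baseline = draw("pp_baseline"),
        lf_amp = draw("lf_amp"), hf_amp = draw("hf_amp"),
        lf_freq = draw("lf_freq"), hf_freq = draw("hf_freq"),
        k1_true = draw("k1_true"), k2_true = draw("k2_true"),
        hrv_ptt_gain = draw("hrv_ptt_gain"), noise_sd = draw("noise_sd"),
        abr_fast_weight = draw("abr_fast_weight"),
        duration = draw("duration"),
        session = session, post_sbp_shift = draw("post_sbp_shift"),
        post_sens_scale = draw("post_sens_scale"),
        seed = sample.int(.Machine$integer.max, 1L))
    })
  })
  lapply(specs, simulate_subject)
}
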