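#' Synchronised sampled ECG / PPG / BP channels
#'
#' @param ecg,ppg,bp Numeric channels of one common length (arbitrary units
#'   for ECG/PPG, mmHg for BP).
#' @param fs Sampling rate, Hz (`> 0`).
#' @param start Time of the first sample, s.
#' @return An object of class `"waveform_record"`.
#' @export
waveform_record <- function(ecg, ppg, bp, fs, start = 0) {
  n <- length(ecg)
  stopifnot(is.numeric(ecg), is.numeric(ppg), is.numeric(bp),
            length(ppg) == n, length(bp) == n, fs > 0, n > 0)
  structure(list(ecg = ecg, ppg = ppg, bp = bp, fs = fs, start = start),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("Waveform record: %d samples @ %g Hz (%.1f s), channels ecg/ppg/bp\n",
              length(x$ecg), x$fs, length(x$ecg) / x$fs))
  invisible(x)
}

#' Read / write a waveform record as multi-channel CSV
#'
#' Columns `time_s, ecg, ppg, bp`; the sampling rate is recovered from the
#' time column on read.
#' @param x A [waveform_record()].
#' @param path File path.
#' @export
write_waveform_record <- function(x, path) {
  stopifnot(inherits(x, "waveform_record"))
  n <- length(x$ecg)
  df <- data.frame(time_s = x$start + (seq_len(n) - 1) / x$fs,
                   ecg = x$ecg, ppg = x$ppg, bp = x$bp)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_record
#' @export
read_waveform_record <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "ecg", "ppg", "bp") %in% names(df)),
            nrow(df) >= 2)
  dt <- diff(df$time_s)
  if (stats::sd(dt) > 1e-6 * mean(dt))
    stop("time column is not uniformly sampled", call. = FALSE)
  waveform_record(df$ecg, df$ppg, df$bp, fs = 1 / mean(dt),
                  start = df$time_s[1])
}

# PPG pulse template on a fine relative grid: raised-cosine upstroke of
# `up_s` seconds followed by an exponential decay with a small dicrotic
# bump. Returns the sampled template and the index of its steepest-ascent
# sample (used to anchor the template to R time + PTT).
ppg_template <- function(len_s, up_s, fs) {
  tau <- seq(0, len_s, by = 1 / fs)
  up <- tau <= up_s
  y <- numeric(length(tau))
  y[up] <- 0.5 - 0.5 * cos(pi * tau[up] / up_s)
  td <- tau[!up] - up_s
  y[!up] <- exp(-td / 0.25) * (1 + 0.15 * exp(-((td - 0.18) / 0.05)^2))
  y[!up] <- y[!up] / y[!up][1]   # continuous at the junction
  list(y = y, steepest = which.max(diff(y)))
}

#' Synthesize ECG / PPG / BP waveforms from a simulated subject
#'
#' Renders a [simulate_subject()] beat series into sampled waveforms so the
#' fiducial extractors can be exercised against exact ground truth:
#' \itemize{
#'   \item ECG: a narrow Gaussian R wave (SD 8 ms) at each beat time;
#'   \item PPG: an asymmetric pulse (raised-cosine upstroke, exponential
#'     decay with dicrotic bump) placed so that the steepest point of its
#'     upstroke lies exactly at that beat's R time + PTT;
#'   \item BP: a per-cycle pressure contour rising from DBP to the cycle's
#'     SBP at 30 % of the RR interval and relaxing back, so the per-cycle
#'     maximum and minimum equal the beat's SBP and DBP.
#' }
#'
#' @param truth A `"subject_truth"` from [simulate_subject()].
#' @param fs Sampling rate, Hz (`>= 250`; the acquisition standard is 1000).
#' @param pad Baseline lead-in/lead-out, s (default 0.5). The record starts
#'   at `-pad` so beat times stay on the simulator's clock.
#' @return A [waveform_record()] with attribute `"fiducials"`: a data frame
#'   of ground-truth sample indices (`r_sample`, `ppg_upstroke_sample`) and
#'   the rendered beat table.
#' @export
synthesize_waveforms <- function(truth, fs = 1000, pad = 0.5) {
  stopifnot(inherits(truth, "subject_truth"))
  if (fs < 250)
    stop("fs must be >= 250 Hz to place waveform templates reliably",
         call. = FALSE)
  beats <- truth$beats
  nb <- nrow(beats)
  if (nb < 1L) stop("no beats to synthesize", call. = FALSE)
  if (any(beats$ptt_ms / 1000 >= beats$rri_ms / 1000 * 0.95))
    stop("PTT too close to the RR interval: PPG pulses would collide",
         call. = FALSE)
  t_end <- beats$beat_time_s[nb] + beats$rri_ms[nb] / 1000
  n <- ceiling((t_end + 2 * pad) * fs) + 1L
  tgrid_dt <- 1 / fs
  at <- function(t) round((t + pad) * fs) + 1L   # time -> sample index
  ecg <- numeric(n)
  ppg <- numeric(n)
  bp <- numeric(n)

  # ECG: Gaussian R waves, truncated at 4 SD
  r_sd <- 0.008
  half_w <- ceiling(4 * r_sd * fs)
  r_samples <- integer(nb)
  for (i in seq_len(nb)) {
    c_i <- at(beats$beat_time_s[i])
    r_samples[i] <- c_i
    idx <- max(1L, c_i - half_w):min(n, c_i + half_w)
    tt <- (idx - 1L) * tgrid_dt - pad
    ecg[idx] <- ecg[idx] + exp(-((tt - beats$beat_time_s[i]) / r_sd)^2 / 2)
  }

  # PPG: template anchored so its steepest-ascent sample sits at R + PTT
  up_samples <- integer(nb)
  for (i in seq_len(nb)) {
    rri_s <- beats$rri_ms[i] / 1000
    len_s <- min(0.9 * rri_s, 0.8)
    tpl <- ppg_template(len_s, up_s = 0.12, fs = fs)
    anchor <- at(beats$beat_time_s[i] + beats$ptt_ms[i] / 1000)
    start <- anchor - tpl$steepest
    idx <- start:(start + length(tpl$y) - 1L)
    ok <- idx >= 1L & idx <= n
    ppg[idx[ok]] <- ppg[idx[ok]] + tpl$y[ok]
    up_samples[i] <- anchor
  }

  # BP: per-cycle contour, systolic peak at 30 % of the cycle
  for (i in seq_len(nb)) {
    i0 <- at(beats$beat_time_s[i])
    i1 <- if (i < nb) at(beats$beat_time_s[i + 1L]) - 1L else at(t_end)
    idx <- i0:min(i1, n)
    tau <- (idx - i0) / max(length(idx) - 1L, 1L)
    a <- 0.3
    w <- ifelse(tau <= a,
                0.5 - 0.5 * cos(pi * tau / a),
                0.5 + 0.5 * cos(pi * (tau - a) / (1 - a)))
    bp[idx] <- beats$dbp_mmhg[i] + (beats$sbp_mmhg[i] - beats$dbp_mmhg[i]) * w
  }

  # flat baseline pressure in the pads so per-cycle extrema stay per cycle
  bp[1:(at(0) - 1L)] <- beats$dbp_mmhg[1]
  bp[at(t_end):n] <- beats$dbp_mmhg[nb]
  rec <- waveform_record(ecg, ppg, bp, fs = fs, start = -pad)
  attr(rec, "fiducials") <- data.frame(
    beat = seq_len(nb),
    r_sample = r_samples,
    ppg_upstroke_sample = up_samples)
  rec
}
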