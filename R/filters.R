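#' Zero-phase Butterworth conditioning of ECG and PPG channels
#'
#' Standard acquisition-system defaults: the ECG channel is band-limited with
#' a 0.5 Hz high-pass and a 35 Hz low-pass, the PPG channel with a 0.05 Hz
#' high-pass and a 10 Hz low-pass. Each corner is a 4th-order Butterworth
#' applied forward-backward ([signal::filtfilt()]), so fiducial timing is not
#' shifted by filter delay.
#'
#' @param record A [waveform_record()]; `fs` must exceed twice the low-pass
#'   corner.
#' @param high_pass,low_pass Corner frequencies, Hz.
#' @param order Butterworth order per pass (default 4).
#' @return The record with the channel replaced by its filtered version.
#' @export
filter_ecg <- function(record, high_pass = 0.5, low_pass = 35, order = 4) {
  stopifnot(inherits(record, "waveform_record"))
  record$ecg <- butter_bandlimit(record$ecg, record$fs, high_pass, low_pass,
                                 order)
  record
}

#' @rdname filter_ecg
#' @export
filter_ppg <- function(record, high_pass = 0.05, low_pass = 10, order = 4) {
  stopifnot(inherits(record, "waveform_record"))
  record$ppg <- butter_bandlimit(record$ppg, record$fs, high_pass, low_pass,
                                 order)
  record
}

butter_bandlimit <- function(x, fs, high_pass, low_pass, order) {
  if (fs <= 2 * low_pass)
    stop("sampling rate must exceed twice the low-pass corner (",
         low_pass, " Hz)", call. = FALSE)
  bh <- signal::butter(order, high_pass / (fs / 2), type = "high")
  bl <- signal::butter(order, low_pass / (fs / 2), type = "low")
  y <- signal::filtfilt(bh, x)
  signal::filtfilt(bl, y)
}

#' Detect R peaks in a filtered ECG
#'
#' Derivative-energy detector in the Pan-Tompkins tradition: the squared
#' first difference is integrated over a 150 ms moving window, candidate
#' regions are thresholded at a fraction of a high quantile of the
#' integrated energy (robust to a few outliers), a refractory period
#' suppresses double fires, and each detection is refined to the ECG maximum
#' within +/- 50 ms.
#'
#' @param ecg Filtered ECG samples.
#' @param fs Sampling rate, Hz.
#' @param refractory Minimum peak separation, s (default 0.25).
#' @param threshold_frac Fraction of the 99.9th percentile of integrated
#'   energy used as detection threshold.
#' @return R-peak times in seconds (possibly empty, with a warning, for a
#'   flat record).
#' @export
detect_r_peaks <- function(ecg, fs, refractory = 0.25,
                           threshold_frac = 0.25) {
  stopifnot(is.numeric(ecg), fs > 0)
  n <- length(ecg)
  if (n < fs) stop("ECG too short for beat detection", call. = FALSE)
  d <- c(0, diff(ecg))
  energy <- d^2
  win <- max(3L, round(0.15 * fs))
  kernel <- rep(1 / win, win)
  integ <- as.numeric(stats::filter(energy, kernel, sides = 2))
  integ[is.na(integ)] <- 0
  thr <- threshold_frac * stats::quantile(integ, 0.999, names = FALSE)
  if (!is.finite(thr) || thr <= 0 || max(integ) <= .Machine$double.eps) {
    warning("no QRS energy detected; returning no beats")
    return(numeric(0))
  }
  above <- integ > thr
  # rising edges of the thresholded energy
  edges <- which(above & !c(FALSE, above[-n]))
  refr <- round(refractory * fs)
  half <- round(0.05 * fs)
  peaks <- integer(0)
  last <- -Inf
  for (e in edges) {
    if (e - last < refr) next
    idx <- e:min(n, e + 2L * half)
    p <- idx[which.max(ecg[idx])]
    if (length(peaks) && p - peaks[length(peaks)] < refr) next
    peaks <- c(peaks, p)
    last <- e
  }
  (peaks - 1L) / fs
}

#' Per-beat PPG fiducial points
#'
#' Within each cardiac cycle (the half-open RR window following an R peak)
#' three fiducials are located on the PPG: the pulse peak, the maximal
#' first-derivative point of the upstroke (computed on a smoothed first
#' difference), and the pulse-foot minimum. By construction of a normal
#' pulse the three are ordered minimum <= steepest <= peak in time. The
#' steepest point is searched before the peak and the minimum before the
#' steepest point, which enforces that ordering on clean data; beats whose
#' window carries no upstroke (flat or monotone-falling PPG) are flagged.
#'
#' The final beat has no complete RR window and is skipped.
#'
#' @param ppg Filtered PPG samples.
#' @param fs Sampling rate, Hz.
#' @param beat_times R-peak times, s (length `>= 2`).
#' @param smooth_ms Width of the moving-average smoothing of the first
#'   difference, ms.
#' @return Data frame with one row per complete beat: `beat`, `peak_sample`,
#'   `upstroke_sample`, `min_sample` (1-based indices into `ppg`, `NA` when
#'   flagged) and `flagged`.
#' @export
ppg_fiducials <- function(ppg, fs, beat_times, smooth_ms = 10) {
  stopifnot(is.numeric(ppg), fs > 0)
  nb <- length(beat_times)
  if (nb < 2L) stop("need at least 2 beats", call. = FALSE)
  d <- c(0, diff(ppg))
  win <- max(1L, round(smooth_ms / 1000 * fs))
  if (win > 1L) {
    d <- as.numeric(stats::filter(d, rep(1 / win, win), sides = 2))
    d[is.na(d)] <- 0
  }
  n <- length(ppg)
  out <- data.frame(beat = seq_len(nb - 1L),
                    peak_sample = NA_integer_,
                    upstroke_sample = NA_integer_,
                    min_sample = NA_integer_,
                    flagged = FALSE)
  for (i in seq_len(nb - 1L)) {
    i0 <- round(beat_times[i] * fs) + 1L
    i1 <- round(beat_times[i + 1L] * fs)
    i0 <- max(1L, i0); i1 <- min(n, i1)
    if (i1 - i0 < 3L || max(d[i0:i1]) <= 0) {
      out$flagged[i] <- TRUE
      next
    }
    seg <- i0:i1
    pk <- seg[which.max(ppg[seg])]
    up_seg <- i0:pk
    up <- up_seg[which.max(d[up_seg])]
    mn_seg <- i0:up
    mn <- mn_seg[which.min(ppg[mn_seg])]
    if (pk == i1 || up == i0) {   # no interior upstroke in this window
      out$flagged[i] <- TRUE
      next
    }
    out$peak_sample[i] <- pk
    out$upstroke_sample[i] <- up
    out$min_sample[i] <- mn
  }
  out
}

#' Extract a per-beat series from a waveform record
#'
#' Full fiducial pipeline: R peaks from the ECG ([detect_r_peaks()]), PPG
#' fiducials per cycle ([ppg_fiducials()]), PTT as the fiducial-to-R delay
#' (variant `"ptt2"`, the maximal first-derivative point, by default;
#' `"ptt1"` peak, `"ptt3"` minimum), RR intervals from consecutive R peaks,
#' and SBP / DBP as the per-cycle maximum / minimum of the BP channel.
#' Beats violating plausibility rules (PTT outside `ptt_limits`, RRi outside
#' `rri_limits`, flagged PPG, SBP <= DBP) are dropped; the drop log is
#' attached as attribute `"dropped"`.
#'
#' @param record A [waveform_record()] with all three channels.
#' @param variant PTT variant, `"ptt2"` (default), `"ptt1"` or `"ptt3"`.
#' @param prefiltered Set `TRUE` if the channels are already conditioned;
#'   otherwise [filter_ecg()] and [filter_ppg()] are applied first.
#' @param ptt_limits,rri_limits Plausibility windows, ms.
#' @param min_beats Minimum surviving beats (default 20).
#' @return A [beat_series()]; dropped beats are logged in the `"dropped"`
#'   attribute (data frame of beat index and reason).
#' @export
extract_beat_series <- function(record, variant = c("ptt2", "ptt1", "ptt3"),
                                prefiltered = FALSE,
                                ptt_limits = c(50, 600),
                                rri_limits = c(300, 2000),
                                min_beats = 20L) {
  variant <- match.arg(variant)
  stopifnot(inherits(record, "waveform_record"))
  if (!prefiltered) {
    record <- filter_ecg(record)
    record <- filter_ppg(record)
  }
  fs <- record$fs
  r_times <- detect_r_peaks(record$ecg, fs) + record$start
  if (length(r_times) < 3L)
    stop("fewer than 3 R peaks detected", call. = FALSE)
  fid <- ppg_fiducials(record$ppg, fs, r_times - record$start)
  col <- switch(variant, ptt1 = "peak_sample", ptt2 = "upstroke_sample",
                ptt3 = "min_sample")
  nb <- nrow(fid)   # complete beats (last R dropped: no closing window)
  rri <- diff(r_times) * 1000
  ptt <- ((fid[[col]] - 1L) / fs + record$start - r_times[seq_len(nb)]) * 1000
  sbp <- dbp <- rep(NA_real_, nb)
  n <- length(record$bp)
  for (i in seq_len(nb)) {
    i0 <- max(1L, round((r_times[i] - record$start) * fs) + 1L)
    i1 <- min(n, round((r_times[i + 1L] - record$start) * fs))
    if (i1 > i0) {
      sbp[i] <- max(record$bp[i0:i1])
      dbp[i] <- min(record$bp[i0:i1])
    }
  }
  reason <- character(nb)
  reason[fid$flagged] <- "ppg_flagged"
  bad_ptt <- !fid$flagged &
    (is.na(ptt) | ptt < ptt_limits[1] | ptt > ptt_limits[2])
  reason[bad_ptt] <- "ptt_out_of_range"
  bad_rri <- rri < rri_limits[1] | rri > rri_limits[2]
  reason[reason == "" & bad_rri] <- "rri_out_of_range"
  bad_bp <- is.na(sbp) | is.na(dbp) | sbp <= dbp
  reason[reason == "" & bad_bp] <- "bp_degenerate"
  reason[reason == "" & (is.na(ptt) | ptt <= 0 | ptt >= rri)] <- "ptt_vs_rri"
  keep <- reason == ""
  if (sum(keep) < min_beats)
    stop("fewer than ", min_beats, " valid beats extracted", call. = FALSE)
  out <- beat_series(r_times[seq_len(nb)][keep], rri[keep], ptt[keep],
                     sbp[keep], dbp[keep], variant = variant)
  attr(out, "dropped") <- data.frame(
    beat = which(!keep), reason = reason[!keep])
  out
}
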