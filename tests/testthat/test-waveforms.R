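test_that("filters pass their band and reject out-of-band content", {
  fs <- 1000
  t <- seq(0, 30, by = 1 / fs)
  mid <- seq(5 * fs, 25 * fs)   # avoid filtfilt edge transients
  amp_of <- function(y, f) 2 * abs(mean(y[mid] * exp(-2i * pi * f * t[mid])))
  # ECG chain: 0.1 Hz drift attenuated > 20 dB, 10 Hz tone within 1 dB
  rec <- waveform_record(sin(2 * pi * 0.1 * t) + sin(2 * pi * 10 * t),
                         numeric(length(t)), numeric(length(t)), fs)
  e <- filter_ecg(rec)$ecg
  expect_lt(amp_of(e, 0.1) / amp_of(rec$ecg, 0.1), 10^(-20 / 20))
  expect_gt(amp_of(e, 10), 10^(-1 / 20))
  # PPG chain: 20 Hz attenuated > 20 dB, 1 Hz within 1 dB, DC removed
  rec2 <- waveform_record(numeric(length(t)),
                          3 + sin(2 * pi * 1 * t) + sin(2 * pi * 20 * t),
                          numeric(length(t)), fs)
  p <- filter_ppg(rec2)$ppg
  expect_lt(amp_of(p, 20), 10^(-20 / 20))
  expect_gt(amp_of(p, 1), 10^(-1 / 20))
  expect_lt(abs(mean(p[mid])), 0.05)
  # zero in, zero out; fs below 2x low-pass corner rejected
  z <- filter_ecg(waveform_record(numeric(5000), numeric(5000),
                                  numeric(5000), fs))
  expect_equal(max(abs(z$ecg)), 0)
  expect_error(
    filter_ecg(waveform_record(numeric(500), numeric(500), numeric(500),
                               fs = 60)),
    "twice the low-pass")
})

test_that("R-peak detection is accurate on clean and noisy synthetic ECG", {
  tr <- quick_subject(duration = 60, seed = 3)
  rec <- synthesize_waveforms(tr, fs = 1000)
  truth_t <- tr$beats$beat_time_s
  # clean: one detection per beat within +/- 5 ms
  det <- detect_r_peaks(filter_ecg(rec)$ecg, 1000) + rec$start
  expect_gte(length(det), length(truth_t) - 1L)
  expect_lte(length(det), length(truth_t) + 1L)
  m <- vapply(det, function(t) min(abs(truth_t - t)), 1)
  expect_lt(max(m) * 1000, 5)
  # additive noise at 20 dB below the R amplitude: >= 99 % matched to 10 ms
  noisy <- rec
  noisy$ecg <- noisy$ecg + withr::with_seed(1, rnorm(length(rec$ecg), 0, 0.1))
  det_n <- detect_r_peaks(filter_ecg(noisy)$ecg, 1000) + rec$start
  hits <- vapply(truth_t, function(t) any(abs(det_n - t) < 0.010), TRUE)
  expect_gte(mean(hits), 0.99)
  # flat record: no peaks, a warning, no crash
  expect_warning(
    z <- detect_r_peaks(numeric(5000), 1000), "no QRS")
  expect_length(z, 0L)
})

test_that("PPG fiducials are ordered and flat windows are flagged", {
  tr <- quick_subject(duration = 60, seed = 8)
  rec <- synthesize_waveforms(tr, fs = 1000)
  bt <- tr$beats$beat_time_s - rec$start
  fid <- ppg_fiducials(filter_ppg(rec)$ppg, 1000, bt)
  ok <- !fid$flagged
  expect_gt(mean(ok), 0.95)
  expect_true(all(fid$min_sample[ok] <= fid$upstroke_sample[ok]))
  expect_true(all(fid$upstroke_sample[ok] <= fid$peak_sample[ok]))
  # upstroke within +/- 2 ms of the generator's anchor
  anchor <- attr(rec, "fiducials")$ppg_upstroke_sample[seq_len(nrow(fid))]
  expect_lt(stats::median(abs(fid$upstroke_sample[ok] - anchor[ok])), 2)
  # flat signal: every beat flagged
  flat <- ppg_fiducials(numeric(5000), 1000, c(0.5, 1.5, 2.5, 3.5))
  expect_true(all(flat$flagged))
})

test_that("extract_beat_series round-trips the generator within tolerance", {
  tr <- quick_subject(duration = 60, seed = 11)
  rec <- synthesize_waveforms(tr, fs = 1000)
  bs <- extract_beat_series(rec)
  truth <- tr$beats
  m <- vapply(bs$beat_time_s,
              function(t) which.min(abs(truth$beat_time_s - t)), 1L)
  expect_lt(stats::median(abs(bs$ptt_ms - truth$ptt_ms[m])), 2)
  expect_lt(max(abs(bs$sbp_mmhg - truth$sbp_mmhg[m])), 0.01)
  expect_lt(max(abs(bs$dbp_mmhg - truth$dbp_mmhg[m])), 0.01)
  expect_lt(max(abs(bs$rri_ms - truth$rri_ms[m])), 2)
  # variant ordering on the same record
  b1 <- extract_beat_series(rec, "ptt1")
  b3 <- extract_beat_series(rec, "ptt3")
  n <- min(nrow(b1), nrow(bs), nrow(b3))
  expect_true(all(b3$ptt_ms[1:n] <= bs$ptt_ms[1:n] + 1e-9))
  expect_true(all(bs$ptt_ms[1:n] <= b1$ptt_ms[1:n] + 1e-9))
  # output always satisfies the beat-series invariants
  expect_silent(pttbp:::validate_beat_series(bs))
})

test_that("waveform synthesis honours its construction contracts", {
  tr <- quick_subject(duration = 30, seed = 2)
  rec <- synthesize_waveforms(tr, fs = 1000)
  # per-cycle BP maximum equals the beat's SBP up to grid quantisation
  b <- tr$beats
  for (i in c(1, 10, 20)) {
    i0 <- round((b$beat_time_s[i] - rec$start) * 1000) + 1
    i1 <- round((b$beat_time_s[i] + b$rri_ms[i] / 1000 - rec$start) * 1000)
    expect_equal(max(rec$bp[i0:i1]), b$sbp_mmhg[i], tolerance = 1e-4)
    expect_equal(min(rec$bp[i0:i1]), b$dbp_mmhg[i], tolerance = 1e-4)
  }
  # degenerate inputs
  expect_error(synthesize_waveforms(tr, fs = 100), ">= 250")
  empty <- tr
  empty$beats <- empty$beats[0, ]
  expect_error(synthesize_waveforms(empty), "no beats")
})

test_that("waveform CSV round-trips preserve the record", {
  tr <- quick_subject(duration = 10, seed = 4)
  rec <- synthesize_waveforms(tr, fs = 250)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_record(rec, path)
  back <- read_waveform_record(path)
  expect_equal(back$fs, rec$fs, tolerance = 1e-6)
  expect_equal(back$bp, rec$bp, tolerance = 1e-6)
  expect_equal(back$start, rec$start, tolerance = 1e-6)
})
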