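test_that("resampling returns grid-point values and preserves sinusoid amplitude", {
  # values already on a uniform grid come back unchanged at the grid points
  t <- seq(0, 20, by = 0.25)
  v <- sin(t)
  rs <- resample_uniform(t, v, target_fs = 4)
  expect_equal(rs$value, v, tolerance = 1e-12)
  # 0.12 Hz sinusoid sampled at a 70 bpm rhythm, resampled to 4 Hz
  beat_t <- seq(0, 120, by = 60 / 70)
  x <- sin(2 * pi * 0.12 * beat_t)
  rs2 <- resample_uniform(beat_t, x, target_fs = 4)
  truth <- sin(2 * pi * 0.12 * rs2$time)
  interior <- rs2$time > 5 & rs2$time < 115
  expect_lt(max(abs(rs2$value[interior] - truth[interior])), 0.02)
  # degenerate inputs
  expect_error(resample_uniform(1, 1), "at least 20")
  expect_error(resample_uniform(c(1:19, 19), rnorm(20)),
               "strictly increasing")
})

test_that("VMD separates a two-tone signal with accurate centre frequencies", {
  tt <- two_tone()
  ms <- vmd(tt$x, n_modes = 2, fs = 4)
  expect_true(ms$converged)
  expect_lt(abs(ms$center_freqs[1] - 0.12), 0.01)
  expect_lt(abs(ms$center_freqs[2] - 0.28), 0.01)
  expect_gt(cor(ms$modes[, 1], tt$s1), 0.95)
  expect_gt(cor(ms$modes[, 2], tt$s2), 0.95)
  recon <- rowSums(ms$modes)
  expect_lt(sqrt(sum((recon - tt$x)^2) / sum(tt$x^2)), 0.05)
})

test_that("a constant signal yields a DC-like mode and negligible others", {
  x <- rep(3.5, 256)
  ms <- vmd(x, n_modes = 2, fs = 4, detrend = FALSE)
  expect_lt(ms$center_freqs[1], 0.05)
  energies <- colSums(ms$modes^2)
  expect_gt(energies[1] / sum(energies), 0.99)
})

test_that("band selection partitions the reconstruction and handles empty bands", {
  tt <- two_tone()
  ms <- vmd(tt$x, n_modes = 2, fs = 4)
  lf <- select_band_modes(ms, c(0.10, 0.15))
  hf <- select_band_modes(ms, c(0.20, 0.35))
  expect_gt(cor(lf, tt$s1), 0.95)
  # LF + HF + unselected modes = full mode-sum reconstruction
  expect_equal(as.numeric(lf + hf), rowSums(ms$modes), tolerance = 1e-9)
  expect_warning(z <- select_band_modes(ms, c(0.45, 0.6)), "no VMD mode")
  expect_true(all(z == 0))
  expect_error(select_band_modes(ms, c(0.2, 0.1)), "lo < hi")
})

test_that("band components agree with a zero-phase Butterworth band-pass oracle", {
  tt <- two_tone(f1 = 0.125, f2 = 0.27)
  dec <- vmd(tt$x, n_modes = 2, fs = 4)
  bp_filter <- function(x, band, fs) {
    b <- signal::butter(4, band / (fs / 2), type = "pass")
    signal::filtfilt(b, x)
  }
  mid <- seq(100, length(tt$x) - 100)   # clip filter edge transients
  lf_vmd <- select_band_modes(dec, c(0.10, 0.15))
  lf_bw <- bp_filter(tt$x, c(0.10, 0.15), 4)
  expect_gt(cor(lf_vmd[mid], lf_bw[mid]), 0.95)
  hf_vmd <- select_band_modes(dec, c(0.20, 0.35))
  hf_bw <- bp_filter(tt$x, c(0.20, 0.35), 4)
  expect_gt(cor(hf_vmd[mid], hf_bw[mid]), 0.95)
})

test_that("permuting the centre-frequency initialisation leaves band content invariant", {
  tt <- two_tone(phi1 = 1.1, phi2 = 2.3)
  x <- tt$x + withr::with_seed(44, rnorm(length(tt$x), 0, 0.1))
  init <- c(0.05, 0.15, 0.25, 0.35, 0.45)
  a <- suppressWarnings(vmd(x, n_modes = 5, fs = 4, init_omega = init))
  b <- suppressWarnings(vmd(x, n_modes = 5, fs = 4, init_omega = rev(init)))
  for (band in list(c(0.10, 0.15), c(0.20, 0.35))) {
    u_a <- select_band_modes(a, band)
    u_b <- select_band_modes(b, band)
    expect_gt(cor(u_a, u_b), 0.99)
  }
  # the tone-carrying centre frequencies agree; empty filler modes may not
  near <- function(ms, f) min(abs(ms$center_freqs - f))
  expect_lt(near(a, 0.12), 0.01); expect_lt(near(b, 0.12), 0.01)
  expect_lt(near(a, 0.28), 0.01); expect_lt(near(b, 0.28), 0.01)
})

test_that("degenerate VMD inputs are rejected and non-convergence is flagged", {
  expect_error(vmd(rnorm(8), n_modes = 2), "too short")
  expect_error(vmd(c(rnorm(100), NA), n_modes = 2), "finite")
  expect_error(vmd(rnorm(100), n_modes = 1), "n_modes >= 2")
  tt <- two_tone(dur = 60)
  expect_warning(ms <- vmd(tt$x, n_modes = 2, fs = 4, max_iter = 2),
                 "did not converge")
  expect_false(ms$converged)
  expect_identical(ms$iterations, 2L)
})

test_that("decompose_lf_hf recovers a simulated subject's band structure", {
  tr <- quick_subject(duration = 300, seed = 17)
  b <- tr$beats
  dec <- suppressWarnings(decompose_lf_hf(b$beat_time_s, b$sbp_mmhg))
  expect_gt(cor(dec$lf, tr$true_lf_sbp), 0.9)
  expect_gt(cor(dec$hf, tr$true_hf_sbp), 0.9)
  # no LF forcing: LF energy a small fraction of HF energy
  tr0 <- quick_subject(duration = 300, seed = 18, lf_amp = 0, noise_sd = 0)
  dec0 <- decompose_lf_hf(tr0$beats$beat_time_s, tr0$beats$sbp_mmhg)
  expect_lt(sum(dec0$lf^2), 0.05 * sum(dec0$hf^2))
})

test_that("band decomposition is approximately linear on two-tone signals", {
  tt <- two_tone()
  y <- 0.6 * tt$x + 0.2 * tt$s1   # a second 'estimated' signal
  diff_dec <- vmd(tt$x - y, n_modes = 2, fs = 4)
  x_dec <- vmd(tt$x, n_modes = 2, fs = 4)
  y_dec <- vmd(y, n_modes = 2, fs = 4)
  lf_of <- function(d) select_band_modes(d, c(0.10, 0.15))
  lhs <- lf_of(diff_dec)
  rhs <- lf_of(x_dec) - lf_of(y_dec)
  expect_gt(cor(lhs, rhs), 0.99)
  expect_lt(sqrt(sum((lhs - rhs)^2) / max(sum(rhs^2), 1e-12)), 0.1)
})
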