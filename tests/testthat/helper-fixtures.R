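# Shared fixtures: small, fast, fully synthetic.

default_abr <- function(sensitivity = -0.25, p_mid = 120) {
  abr_params(hr_low = 55, hr_high = 110, p_mid = p_mid,
             sensitivity = sensitivity)
}

# short clean subject; override any subject_spec argument via ...
quick_subject <- function(duration = 120, seed = 7, ...) {
  simulate_subject(subject_spec(default_abr(), duration = duration,
                                seed = seed, ...))
}

two_tone <- function(f1 = 0.12, f2 = 0.28, fs = 4, dur = 300,
                     phi1 = 0, phi2 = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  list(t = t, x = sin(2 * pi * f1 * t + phi1) + sin(2 * pi * f2 * t + phi2),
       s1 = sin(2 * pi * f1 * t + phi1), s2 = sin(2 * pi * f2 * t + phi2))
}

# independently coded sequence-method oracle: naive loops, explicit
# quadrant masks, per-quadrant two-pass OLS slope
brs_oracle <- function(rri, sbp, window = 16L) {
  dr <- diff(rri)
  ds <- diff(sbp)
  n_win <- length(dr) - window + 1L
  brs <- rep(NA_real_, n_win)
  for (w in seq_len(n_win)) {
    r1 <- r2 <- NA_real_
    i_dn <- integer(0); i_up <- integer(0)
    for (i in w:(w + window - 1L)) {
      if (dr[i] < 0 && ds[i] < 0) i_dn <- c(i_dn, i)
      if (dr[i] > 0 && ds[i] > 0) i_up <- c(i_up, i)
    }
    slope <- function(ii) {
      if (length(ii) < 2L) return(NA_real_)
      x <- ds[ii]; y <- dr[ii]
      if (sum((x - mean(x))^2) == 0) return(NA_real_)
      sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    }
    r1 <- slope(i_dn); r2 <- slope(i_up)
    vals <- c(r1, r2)
    vals <- vals[!is.na(vals)]
    if (length(vals)) brs[w] <- mean(vals)
  }
  brs
}
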