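make_sides <- function(n = 50, seed = 1) {
  withr::with_seed(seed, {
    ref <- list(sbp = rnorm(n, 120), dbp = rnorm(n, 75),
                lf_sbp = rnorm(n), hf_sbp = rnorm(n),
                lf_dbp = rnorm(n), hf_dbp = rnorm(n))
    est <- lapply(ref, function(v) v + rnorm(n, 0, 0.5))
    list(est = est, ref = ref)
  })
}

test_that("band errors are estimate minus reference, elementwise", {
  s <- make_sides()
  e <- band_errors(s$est, s$ref)
  expect_equal(e$e_sbp, s$est$sbp - s$ref$sbp)
  expect_equal(e$e_lfdbp, s$est$lf_dbp - s$ref$lf_dbp)
  # identity and constant-offset contracts
  z <- band_errors(s$ref, s$ref)
  expect_true(all(as.matrix(z) == 0))
  shifted <- s$ref
  shifted$sbp <- shifted$sbp + 3
  expect_equal(band_errors(shifted, s$ref)$e_sbp, rep(3, 50))
  # length mismatch rejected
  bad <- s$est
  bad$sbp <- bad$sbp[-1]
  expect_error(band_errors(bad, s$ref), "one length")
})

test_that("band errors decompose the overall error when bands partition the signal", {
  tt <- two_tone()
  ref_sig <- 120 + tt$x
  est_sig <- 120 + 0.9 * tt$s1 + 1.05 * tt$s2
  dr <- vmd(ref_sig, n_modes = 2, fs = 4)
  de <- vmd(est_sig, n_modes = 2, fs = 4)
  lf_r <- select_band_modes(dr, c(0.1, 0.15))
  hf_r <- select_band_modes(dr, c(0.2, 0.35))
  lf_e <- select_band_modes(de, c(0.1, 0.15))
  hf_e <- select_band_modes(de, c(0.2, 0.35))
  e_total <- est_sig - ref_sig
  e_bands <- (lf_e - lf_r) + (hf_e - hf_r)
  resid_bands <- (de$residual + de$mean) - (dr$residual + dr$mean)
  expect_equal(as.numeric(e_bands + resid_bands), e_total,
               tolerance = 1e-9)
  # the two band errors carry almost all of the error energy here
  expect_lt(sum((e_total - e_bands)^2) / sum(e_total^2), 0.05)
})

test_that("pearson_r matches its defining cases and an independent oracle", {
  expect_equal(pearson_r(1:3, 1:3), 1)
  expect_equal(pearson_r(1:3, -(1:3)), -1)
  for (s in 1:20) {
    x <- withr::with_seed(300 + s, rnorm(40))
    y <- withr::with_seed(400 + s, rnorm(40))
    oracle <- mean((x - mean(x)) * (y - mean(y))) /
      (stats::sd(x) * stats::sd(y)) * length(x) / (length(x) - 1)
    expect_equal(pearson_r(x, y), oracle, tolerance = 1e-12)
    expect_equal(pearson_r(x, y), stats::cor(x, y), tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  # numerically stable for a tiny-variance series on a large offset
  y <- 5 + 1e-8 * withr::with_seed(7, rnorm(100))
  x <- withr::with_seed(8, rnorm(100))
  expect_lt(abs(pearson_r(x, y) - stats::cor(x, y)), 1e-6)
})

test_that("alignment pairs valid windows with errors and tracks M", {
  s <- make_sides(n = 60)
  errs <- band_errors(s$est, s$ref)
  sbp <- withr::with_seed(11, 120 + cumsum(rnorm(60)))
  rri <- withr::with_seed(12, 800 + 6 * (sbp - 120) + rnorm(60, 0, 4))
  brs <- dynamic_brs(rri, sbp)
  paired <- align_error_brs(errs, brs)
  expect_identical(nrow(paired), sum(brs$valid))
  expect_equal(paired$e_sbp,
               errs$e_sbp[brs$window_start[brs$valid]])
  # dropping k windows reduces M by exactly k
  brs2 <- brs
  kill <- which(brs2$valid)[1:3]
  brs2$valid[kill] <- FALSE
  brs2$brs[kill] <- NA_real_
  expect_identical(nrow(align_error_brs(errs, brs2)), nrow(paired) - 3L)
  # all-invalid BRS excludes the subject
  brs3 <- brs
  brs3$valid[] <- FALSE
  expect_error(align_error_brs(errs, brs3), "excluded")
})

test_that("cohort criteria use the population SD and the minimum absolute value", {
  r <- c(0.5, -0.2, 0.8)
  cc <- cohort_criteria(r)
  expect_equal(cc$mu, mean(r), tolerance = 1e-12)
  expect_equal(cc$sd, sqrt(sum((r - mean(r))^2) / 3), tolerance = 1e-12)
  expect_equal(cc$mav, 0.2)
  # identical values: zero SD, MAV is the common magnitude
  cc2 <- cohort_criteria(c(-0.4, -0.4, -0.4))
  expect_equal(cc2$sd, 0)
  expect_equal(cc2$mav, 0.4)
  # MAV invariant under sign flips of any subset
  rr <- withr::with_seed(13, runif(10, -1, 1))
  flip <- withr::with_seed(14, sample(c(-1, 1), 10, replace = TRUE))
  expect_equal(cohort_criteria(rr)$mav, cohort_criteria(rr * flip)$mav)
  expect_error(cohort_criteria(0.5), "at least 2")
  expect_error(cohort_criteria(c(0.5, 1.2)), "within")
})

test_that("the LF-vs-HF t test matches stats::t.test and handles degeneracy", {
  for (s in 1:10) {
    a <- withr::with_seed(500 + s, rnorm(15, 0.5, 0.2))
    b <- withr::with_seed(600 + s, rnorm(12, 0.3, 0.2))
    got <- lf_hf_ttest(a, b)
    want <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
  }
  same <- lf_hf_ttest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  jit <- withr::with_seed(15, rnorm(4, 0, 1e-8))
  sep <- lf_hf_ttest(1 + jit, rnorm(4, 0, 1e-8))
  expect_lt(sep$p_value, 1e-6)
  expect_warning(inf <- lf_hf_ttest(c(1, 1), c(0, 0)), "infinite")
  expect_identical(inf$statistic, Inf)
  expect_equal(inf$p_value, 0)
})

test_that("run_full_analysis is deterministic and reports the six groups", {
  co <- simulate_cohort(4, seed = 77, ranges = cohort_ranges(duration = c(150, 150)))
  a <- suppressWarnings(run_full_analysis(co))
  b <- suppressWarnings(run_full_analysis(co))
  expect_identical(a$per_subject, b$per_subject)
  expect_setequal(a$criteria$group,
                  c("e_sbp", "e_dbp", "e_lfsbp", "e_lfdbp",
                    "e_hfsbp", "e_hfdbp"))
  expect_true(all(abs(a$per_subject$e_lfsbp) <= 1))
  expect_true(all(c("sbp", "dbp") %in% names(a$tests)))
})
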