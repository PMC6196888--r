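#' First-order forward difference
#'
#' `d_i = x_{i+1} - x_i`; the output is one element shorter than the input.
#'
#' @param x Numeric vector, length `>= 2`.
#' @return Numeric vector of length `length(x) - 1`.
#' @export
first_difference <- function(x) {
  stopifnot(is.numeric(x))
  if (length(x) < 2L) stop("need at least 2 points to difference",
                           call. = FALSE)
  x[-1L] - x[-length(x)]
}

#' Dynamic baroreflex sensitivity by sliding-window sequence regression
#'
#' Time-domain baroreflex sensitivity (BRS, ms/mmHg): within a sliding window
#' over the first-order forward differences of RR interval and systolic
#' pressure, beats whose differences move in the same direction are collected
#' into two sets (`dRRi < 0 & dSBP < 0`, and `dRRi > 0 & dSBP > 0`); the OLS
#' regression slope of dRRi on dSBP is computed within each set, and the
#' window's BRS is the mean of the two slopes. The window advances one beat
#' at a time.
#'
#' A quadrant with fewer than two pairs (or zero dSBP variance) contributes
#' no slope; such windows fall back to the remaining quadrant alone, and
#' windows where both quadrants fail are flagged invalid (`NA` BRS). Zero
#' differences join neither quadrant (strict inequalities).
#'
#' @param rri RR intervals, ms.
#' @param sbp Systolic pressures, mmHg; same length as `rri`,
#'   `>= window + 1` beats.
#' @param window Window length in difference pairs (default 16).
#' @param step Window advance in beats (default 1).
#' @return A data frame of class `"brs_series"` with one row per window:
#'   `window_start` (index of the first beat of the window), `brs`
#'   (ms/mmHg, `NA` when invalid), `n_down` and `n_up` (pairs per quadrant),
#'   `valid`.
#' @examples
#' set.seed(1)
#' sbp <- 120 + cumsum(rnorm(60))
#' rri <- 800 + 8 * (sbp - 120) + rnorm(60, 0, 2)
#' dynamic_brs(rri, sbp)
#' @export
dynamic_brs <- function(rri, sbp, window = 16L, step = 1L) {
  stopifnot(is.numeric(rri), is.numeric(sbp))
  window <- as.integer(window)
  step <- as.integer(step)
  if (window < 2L) stop("window must be >= 2", call. = FALSE)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  if (length(rri) != length(sbp))
    stop("rri and sbp must have equal length", call. = FALSE)
  if (length(rri) < window + 1L)
    stop("need at least window + 1 beats", call. = FALSE)
  d_rri <- first_difference(rri)
  d_sbp <- first_difference(sbp)
  starts <- seq.int(1L, length(d_rri) - window + 1L, by = step)
  brs <- rep(NA_real_, length(starts))
  n_down <- n_up <- integer(length(starts))
  for (j in seq_along(starts)) {
    idx <- starts[j]:(starts[j] + window - 1L)
    dr <- d_rri[idx]
    ds <- d_sbp[idx]
    down <- dr < 0 & ds < 0
    up <- dr > 0 & ds > 0
    n_down[j] <- sum(down)
    n_up[j] <- sum(up)
    r1 <- quadrant_slope(ds[down], dr[down])
    r2 <- quadrant_slope(ds[up], dr[up])
    slopes <- c(r1, r2)
    slopes <- slopes[!is.na(slopes)]
    if (length(slopes)) brs[j] <- mean(slopes)
  }
  out <- data.frame(window_start = starts, brs = brs,
                    n_down = n_down, n_up = n_up, valid = !is.na(brs))
  class(out) <- c("brs_series", "data.frame")
  attr(out, "window") <- window
  attr(out, "step") <- step
  out
}

# OLS slope of y on x within one quadrant; NA when fewer than 2 pairs or
# degenerate x variance.
quadrant_slope <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  mx <- mean(x)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(NA_real_)
  sum((x - mx) * (y - mean(y))) / sxx
}

#' @export
print.brs_series <- function(x, ...) {
  ok <- x$brs[x$valid]
  cat(sprintf(
    "Dynamic BRS: %d windows of %d pairs (step %d); %d valid (%.0f%%)\n",
    nrow(x), attr(x, "window"), attr(x, "step"), sum(x$valid),
    100 * mean(x$valid)))
  if (length(ok))
    cat(sprintf("  BRS median %.2f ms/mmHg (IQR %.2f-%.2f)\n",
                stats::median(ok), stats::quantile(ok, 0.25),
                stats::quantile(ok, 0.75)))
  NextMethod()
}
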