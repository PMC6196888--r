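#' Logistic arterial baroreflex parameters
#'
#' The arterial baroreflex (ABR) is modelled as a logistic heart-rate response
#' to arterial pressure,
#' \deqn{HR(P) = HR_l + \frac{HR_h - HR_l}{1 + e^{-\varepsilon (P - P_n)}},}
#' where `hr_low` and `hr_high` are the lower and upper heart-rate plateaus
#' (beats/min), `p_mid` is the pressure at the midpoint of the heart-rate
#' range (mmHg) and `sensitivity` (\eqn{\varepsilon}, 1/mmHg) sets the slope
#' of the linear region of the curve.
#'
#' `sensitivity` may take either sign. A positive value gives a heart rate
#' that rises with pressure (the curve as printed in the physiological
#' literature on overall ABR regulation); a negative value gives the classical
#' reflex orientation in which heart rate falls as pressure rises and the
#' beat-to-beat RR interval moves in the same direction as systolic pressure.
#' The sequence method for baroreflex sensitivity only finds same-direction
#' RR/SBP pairs under the classical orientation, so cohort simulations default
#' to negative sensitivities (see [cohort_ranges()]).
#'
#' @param hr_low,hr_high Lower and upper heart-rate plateaus, beats/min.
#'   Must satisfy `hr_high > hr_low > 0`.
#' @param p_mid Pressure at the heart-rate midpoint, mmHg (30-250).
#' @param sensitivity Logistic slope parameter, 1/mmHg. Finite, either sign.
#' @return An object of class `"abr_params"`.
#' @examples
#' ab <- abr_params(hr_low = 55, hr_high = 110, p_mid = 120, sensitivity = -0.2)
#' abr_heart_rate(120, ab)   # midpoint: (55 + 110) / 2
#' @export
abr_params <- function(hr_low, hr_high, p_mid, sensitivity) {
  stopifnot(
    is.numeric(hr_low), is.numeric(hr_high), is.numeric(p_mid),
    is.numeric(sensitivity), length(hr_low) == 1L, length(hr_high) == 1L,
    length(p_mid) == 1L, length(sensitivity) == 1L
  )
  if (!is.finite(hr_low) || !is.finite(hr_high) || hr_low <= 0 || hr_high <= hr_low)
    stop("need hr_high > hr_low > 0", call. = FALSE)
  if (!is.finite(p_mid) || p_mid < 30 || p_mid > 250)
    stop("p_mid must lie in the physiologic range 30-250 mmHg", call. = FALSE)
  if (!is.finite(sensitivity))
    stop("sensitivity must be finite", call. = FALSE)
  structure(
    list(hr_low = hr_low, hr_high = hr_high, p_mid = p_mid,
         sensitivity = sensitivity),
    class = "abr_params"
  )
}

#' @export
print.abr_params <- function(x, ...) {
  cat(sprintf(
    "ABR logistic curve: HR %g-%g bpm, midpoint %g mmHg, sensitivity %g /mmHg\n",
    x$hr_low, x$hr_high, x$p_mid, x$sensitivity))
  invisible(x)
}

#' Heart rate from arterial pressure under the logistic ABR curve
#'
#' Evaluates the logistic ABR regulation curve (see [abr_params()]) at one or
#' more pressures. The result is strictly monotone in pressure when
#' `sensitivity != 0` (increasing for positive, decreasing for negative
#' sensitivity) and bounded by the open interval `(hr_low, hr_high)`. At
#' `p_mid` it equals the plateau midpoint, and the slope there is
#' `sensitivity * (hr_high - hr_low) / 4`.
#'
#' @param pressure Arterial pressure, mmHg. Vectorised; must be finite.
#' @param abr An [abr_params()] object.
#' @return Heart rate(s), beats/min.
#' @export
abr_heart_rate <- function(pressure, abr) {
  stopifnot(inherits(abr, "abr_params"), is.numeric(pressure))
  if (length(pressure) == 0L || any(!is.finite(pressure)))
    stop("pressure must be finite", call. = FALSE)
  abr$hr_low + (abr$hr_high - abr$hr_low) /
    (1 + exp(-abr$sensitivity * (pressure - abr$p_mid)))
}

# Analytic dRRi/dSBP (ms/mmHg) of the simulator at a given pressure: the
# quantity the sequence method estimates. Used for ground-truth BRS proxies.
abr_rri_slope <- function(pressure, abr) {
  hr <- abr_heart_rate(pressure, abr)
  sig <- (hr - abr$hr_low) / (abr$hr_high - abr$hr_low)
  dhr_dp <- abr$sensitivity * (abr$hr_high - abr$hr_low) * sig * (1 - sig)
  -60000 / hr^2 * dhr_dp
}
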