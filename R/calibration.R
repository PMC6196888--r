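#' Fit a PTT-to-BP calibration model by ordinary least squares
#'
#' Two classical subject-specific calibration forms are supported:
#' the inverse model `BP = K1 / PTT + K2` (regressor `x = 1/PTT`), which
#' experimental work favours because `1/PTT` rather than PTT is linearly
#' related to BP, and the logarithmic model `BP = K1 ln(PTT) + K2`
#' (regressor `x = ln PTT`). Parameters minimise
#' `sum((K1 x_i + K2 - BPref_i)^2)` and are obtained in closed form from the
#' normal equations. SBP and DBP are calibrated separately with the same PTT
#' regressor.
#'
#' @param ptt Pulse transit times, ms (`> 0`).
#' @param bp_ref Reference pressures, mmHg; same length as `ptt` (`>= 3`).
#' @param form `"inverse"` (default) or `"log"`.
#' @param target Label only: `"SBP"` or `"DBP"`.
#' @return An object of class `"calibration_model"` with elements `form`,
#'   `target`, `k1`, `k2`, `r_squared`, `residual_sd`, `se_k1`, `se_k2`, `n`.
#' @examples
#' ptt <- seq(220, 320, length.out = 50)
#' sbp <- 30000 / ptt + 10
#' fit_ptt_bp(ptt, sbp)   # recovers K1 = 30000, K2 = 10
#' @export
fit_ptt_bp <- function(ptt, bp_ref, form = c("inverse", "log"),
                       target = c("SBP", "DBP")) {
  form <- match.arg(form)
  target <- match.arg(target)
  stopifnot(is.numeric(ptt), is.numeric(bp_ref))
  if (length(ptt) != length(bp_ref))
    stop("ptt and bp_ref must have equal length", call. = FALSE)
  if (length(ptt) < 3L) stop("need at least 3 beats to calibrate", call. = FALSE)
  if (any(!is.finite(ptt)) || any(ptt <= 0))
    stop("ptt must be positive and finite", call. = FALSE)
  x <- if (form == "inverse") 1 / ptt else log(ptt)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  if (sxx < .Machine$double.eps * n * max(1, mean(x)^2))
    stop("zero variance in the PTT regressor: rank-deficient design",
         call. = FALSE)
  k1 <- sum((x - mean(x)) * (bp_ref - mean(bp_ref))) / sxx
  k2 <- mean(bp_ref) - k1 * mean(x)
  fitted <- k1 * x + k2
  rss <- sum((bp_ref - fitted)^2)
  tss <- sum((bp_ref - mean(bp_ref))^2)
  sigma2 <- rss / max(n - 2, 1)
  structure(
    list(form = form, target = target, k1 = k1, k2 = k2,
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         residual_sd = sqrt(sigma2),
         se_k1 = sqrt(sigma2 / sxx),
         se_k2 = sqrt(sigma2 * (1 / n + mean(x)^2 / sxx)),
         n = n),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  rhs <- if (x$form == "inverse") "1/PTT" else "ln(PTT)"
  cat(sprintf("PTT-%s calibration (%s form): %s = %.6g * %s + %.6g\n",
              x$target, x$form, x$target, x$k1, rhs, x$k2))
  cat(sprintf("  n = %d beats, R^2 = %.4f, residual SD = %.3f mmHg\n",
              x$n, x$r_squared, x$residual_sd))
  invisible(x)
}

#' Predict blood pressure from PTT with a fitted calibration model
#'
#' Applies the fitted form elementwise. For the inverse form with `K1 > 0`
#' the prediction is strictly decreasing in PTT.
#'
#' @param model A [fit_ptt_bp()] result.
#' @param ptt Pulse transit times, ms (`> 0`).
#' @return Estimated pressures, mmHg, of the same length as `ptt`.
#' @export
predict_bp <- function(model, ptt) {
  stopifnot(inherits(model, "calibration_model"), is.numeric(ptt))
  if (any(!is.finite(ptt)) || any(ptt <= 0))
    stop("ptt must be positive and finite", call. = FALSE)
  x <- if (model$form == "inverse") 1 / ptt else log(ptt)
  model$k1 * x + model$k2
}

#' Serialise / deserialise a calibration model as JSON
#' @param model A `"calibration_model"`.
#' @param path File path.
#' @return `read_calibration_model` returns the model; the writer returns
#'   `path` invisibly.
#' @export
write_calibration_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_model
#' @export
read_calibration_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "calibration_model")
}
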