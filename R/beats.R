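#' Per-beat aligned cardiovascular series
#'
#' A `beat_series` is a data frame with one row per cardiac cycle and columns
#' `beat_time_s` (R-wave instant, seconds, strictly increasing), `rri_ms`
#' (interval to the next R wave, ms), `ptt_ms` (pulse transit time, ms),
#' `sbp_mmhg` and `dbp_mmhg` (per-cycle systolic/diastolic pressure, mmHg).
#' The PTT variant (`"ptt1"`: R to PPG peak, `"ptt2"`: R to maximal PPG first
#' derivative, `"ptt3"`: R to PPG minimum) is carried as the `"variant"`
#' attribute.
#'
#' @param beat_time_s,rri_ms,ptt_ms,sbp_mmhg,dbp_mmhg Numeric vectors of one
#'   common length.
#' @param variant PTT variant tag, one of `"ptt1"`, `"ptt2"`, `"ptt3"`.
#' @param validate Check the invariants (increasing times, `0 < ptt < rri`,
#'   `sbp > dbp`)? Default `TRUE`.
#' @return A data frame of class `"beat_series"`.
#' @export
beat_series <- function(beat_time_s, rri_ms, ptt_ms, sbp_mmhg, dbp_mmhg,
                        variant = c("ptt2", "ptt1", "ptt3"), validate = TRUE) {
  variant <- match.arg(variant)
  n <- length(beat_time_s)
  stopifnot(length(rri_ms) == n, length(ptt_ms) == n,
            length(sbp_mmhg) == n, length(dbp_mmhg) == n)
  out <- data.frame(beat_time_s = as.numeric(beat_time_s),
                    rri_ms = as.numeric(rri_ms),
                    ptt_ms = as.numeric(ptt_ms),
                    sbp_mmhg = as.numeric(sbp_mmhg),
                    dbp_mmhg = as.numeric(dbp_mmhg))
  class(out) <- c("beat_series", "data.frame")
  attr(out, "variant") <- variant
  if (validate) validate_beat_series(out)
  out
}

validate_beat_series <- function(x) {
  stopifnot(inherits(x, "beat_series"))
  if (nrow(x) == 0L) stop("beat series is empty", call. = FALSE)
  if (any(diff(x$beat_time_s) <= 0))
    stop("beat times must be strictly increasing", call. = FALSE)
  if (any(x$ptt_ms <= 0 | x$ptt_ms >= x$rri_ms))
    stop("PTT must satisfy 0 < ptt < rri for every beat", call. = FALSE)
  if (any(x$sbp_mmhg <= x$dbp_mmhg))
    stop("SBP must exceed DBP for every beat", call. = FALSE)
  invisible(x)
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("Beat series: %d beats over %.1f s (PTT variant %s)\n",
              nrow(x), diff(range(x$beat_time_s)), attr(x, "variant")))
  cat(sprintf("  RRi %.0f-%.0f ms, PTT %.0f-%.0f ms, SBP %.0f-%.0f mmHg\n",
              min(x$rri_ms), max(x$rri_ms), min(x$ptt_ms), max(x$ptt_ms),
              min(x$sbp_mmhg), max(x$sbp_mmhg)))
  NextMethod()
}

#' Read / write beat series as CSV
#'
#' Plain-CSV serialisation with columns `beat_time_s, rri_ms, ptt_ms,
#' sbp_mmhg, dbp_mmhg`; the PTT variant is stored in a `# variant:` header
#' comment line.
#'
#' @param x A [beat_series()].
#' @param path File path.
#' @return `read_beat_series` returns a [beat_series()];
#'   `write_beat_series` returns `path` invisibly.
#' @export
write_beat_series <- function(x, path) {
  stopifnot(inherits(x, "beat_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# variant: %s", attr(x, "variant")), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beat_series
#' @export
read_beat_series <- function(path) {
  first <- readLines(path, n = 1L)
  variant <- "ptt2"
  if (grepl("^# variant:", first))
    variant <- trimws(sub("^# variant:", "", first))
  df <- utils::read.csv(path, comment.char = "#")
  beat_series(df$beat_time_s, df$rri_ms, df$ptt_ms, df$sbp_mmhg, df$dbp_mmhg,
              variant = variant)
}
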