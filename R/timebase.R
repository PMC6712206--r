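#' Sampling grid for a recording
#'
#' A `timebase` describes a uniform sampling grid aligned to the stimulus:
#' the stimulus is applied at t = 0 ms and sample `k` (0-based) lies at
#' `t0_ms + k * dt_ms`. All traces in this package carry a timebase so that
#' latencies, fit windows and baselines are always stimulus-relative.
#'
#' @param t0_ms time of the first sample (ms, stimulus at 0; negative means
#'   pre-stimulus samples are present).
#' @param dt_ms sample interval in ms. Whole-cell analysis runs on a 0.1 ms
#'   grid; raw acquisition at 100 kHz corresponds to `dt_ms = 0.01` and is
#'   reduced with [decimate()]. Diode-array data are sampled at 1 ms.
#' @param n_samples number of samples (>= 2).
#' @return An object of class `"timebase"`.
#' @examples
#' tb <- timebase(-100, 0.1, 2000)   # 100 ms pre- + 100 ms post-stimulus
#' range(tb_times(tb))
#' @export
timebase <- function(t0_ms, dt_ms, n_samples) {
  if (!is.numeric(dt_ms) || length(dt_ms) != 1L || !is.finite(dt_ms) || dt_ms <= 0)
    stop("'dt_ms' must be a single positive number", call. = FALSE)
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L)
    stop("'n_samples' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(t0_ms) || length(t0_ms) != 1L || !is.finite(t0_ms))
    stop("'t0_ms' must be a single finite number", call. = FALSE)
  structure(list(t0_ms = t0_ms, dt_ms = dt_ms, n_samples = n_samples),
            class = "timebase")
}

#' Sample times of a timebase
#'
#' @param tb a [timebase()].
#' @return Numeric vector of sample times in ms.
#' @export
tb_times <- function(tb) {
  stopifnot(inherits(tb, "timebase"))
  tb$t0_ms + (seq_len(tb$n_samples) - 1L) * tb$dt_ms
}

#' @export
print.timebase <- function(x, ...) {
  cat(sprintf("<timebase> %d samples, dt = %g ms, t in [%g, %g] ms\n",
              x$n_samples, x$dt_ms, x$t0_ms,
              x$t0_ms + (x$n_samples - 1L) * x$dt_ms))
  invisible(x)
}

#' @export
format.timebase <- function(x, ...) {
  sprintf("%d x %g ms from %g ms", x$n_samples, x$dt_ms, x$t0_ms)
}

same_timebase <- function(a, b, tol = 1e-9) {
  abs(a$t0_ms - b$t0_ms) < tol && abs(a$dt_ms - b$dt_ms) < tol &&
    a$n_samples == b$n_samples
}

## index range of a [start, end] ms window (closed), error if empty/outside
tb_window_idx <- function(tb, window_ms, what = "window") {
  if (length(window_ms) != 2L || !all(is.finite(window_ms)) ||
      window_ms[1] >= window_ms[2])
    stop(sprintf("'%s' must be c(start, end) with start < end", what),
         call. = FALSE)
  t <- tb_times(tb)
  idx <- which(t >= window_ms[1] - 1e-9 & t <= window_ms[2] + 1e-9)
  if (length(idx) == 0L)
    stop(sprintf("%s [%g, %g] ms lies outside the recorded span [%g, %g] ms",
                 what, window_ms[1], window_ms[2], t[1], t[length(t)]),
         call. = FALSE)
  idx
}

## half-open [start, end) indices: pre-stimulus baselines must exclude the
## stimulus sample at t = 0
tb_baseline_idx <- function(tb, window_ms, what = "baseline window") {
  t <- tb_times(tb)
  idx <- which(t >= window_ms[1] - 1e-9 & t < window_ms[2] - 1e-9)
  if (length(idx) == 0L)
    stop(sprintf("%s [%g, %g) ms lies outside the recorded span [%g, %g] ms",
                 what, window_ms[1], window_ms[2], t[1], t[length(t)]),
         call. = FALSE)
  idx
}

## pre-stimulus baseline window: c(start, end), start < end <= 0
check_baseline_window <- function(window_ms) {
  if (length(window_ms) != 2L || !all(is.finite(window_ms)) ||
      window_ms[1] >= window_ms[2] || window_ms[2] > 1e-9)
    stop("baseline window must be c(start_ms, end_ms) with start < end <= 0",
         call. = FALSE)
  window_ms
}
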