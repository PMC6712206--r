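#' Detect a stimulus-evoked response
#'
#' A response is detected when the signal deviates from the pre-stimulus
#' baseline mean by more than `k_sd` times the baseline standard deviation
#' (8 by default) within `search_ms` (30 ms) after the stimulus. The onset
#' latency is the first threshold crossing after the stimulus-artifact blank,
#' and the peak is the extremum of the signal, in the polarity of the
#' crossing, between the onset and the end of the peak search window.
#'
#' Detection is two-sided by default (`|signal - baseline mean|`), covering
#' both inward synaptic currents (negative at -70 mV) and depolarising
#' potentials; `polarity` can force one side.
#'
#' @param x an [ei_sweep()], or a numeric trace with `timebase` supplied.
#' @param timebase needed when `x` is a bare numeric vector.
#' @param baseline_ms pre-stimulus window for the baseline mean and SD.
#' @param k_sd threshold in baseline SDs, default 8.
#' @param search_ms detection search window after the stimulus, default 30.
#' @param artifact_blank_ms initial post-stimulus span excluded from the
#'   search (stimulus artifact), default 0.5 ms.
#' @param polarity `"both"`, `"positive"` or `"negative"`.
#' @param peak_search_ms end of the peak search window; defaults to
#'   `search_ms`.
#' @return Object of class `"event_detection"`: `detected`, `latency_ms`,
#'   `peak_amplitude` (baseline-subtracted, signed), `peak_time_ms`,
#'   `threshold_used`, `baseline_sd`.
#' @export
detect_response <- function(x, timebase = NULL, baseline_ms = c(-100, 0),
                            k_sd = 8, search_ms = 30,
                            artifact_blank_ms = 0.5,
                            polarity = c("both", "positive", "negative"),
                            peak_search_ms = search_ms) {
  polarity <- match.arg(polarity)
  tr <- as_trace(x, timebase)
  check_baseline_window(baseline_ms)
  bidx <- tb_baseline_idx(tr$tb, baseline_ms)
  b_mean <- mean(tr$v[bidx])
  b_sd <- stats::sd(tr$v[bidx])
  dev <- tr$v - b_mean
  if (b_sd == 0 && all(dev == 0))
    stop("baseline SD is zero and the trace is flat: threshold undefined",
         call. = FALSE)
  thr <- k_sd * b_sd
  t <- tb_times(tr$tb)
  sidx <- which(t > artifact_blank_ms + 1e-9 & t <= search_ms + 1e-9)
  if (length(sidx) == 0L)
    stop("trace does not cover the search window", call. = FALSE)
  crossed <- switch(polarity,
                    both = abs(dev[sidx]) > thr,
                    positive = dev[sidx] > thr,
                    negative = dev[sidx] < -thr)
  res <- list(detected = FALSE, latency_ms = NA_real_,
              peak_amplitude = NA_real_, peak_time_ms = NA_real_,
              threshold_used = thr, baseline_sd = b_sd)
  if (any(crossed)) {
    i_on <- sidx[which(crossed)[1]]
    sign_on <- if (polarity == "negative" ||
                   (polarity == "both" && dev[i_on] < 0)) -1 else 1
    pidx <- which(t >= t[i_on] - 1e-9 & t <= peak_search_ms + 1e-9)
    i_pk <- pidx[which.max(sign_on * dev[pidx])]
    res$detected <- TRUE
    res$latency_ms <- t[i_on]
    res$peak_amplitude <- dev[i_pk]
    res$peak_time_ms <- t[i_pk]
  }
  structure(res, class = "event_detection")
}

#' @export
print.event_detection <- function(x, ...) {
  if (x$detected)
    cat(sprintf(
      "<event_detection> onset %.2f ms, peak %.3g at %.2f ms (thr %.3g)\n",
      x$latency_ms, x$peak_amplitude, x$peak_time_ms, x$threshold_used))
  else
    cat(sprintf("<event_detection> no response (thr %.3g)\n",
                x$threshold_used))
  invisible(x)
}

#' Detect action potentials in a voltage trace
#'
#' Local-extremum spike detection in the style of the classic `peakdet`
#' routine: a sample is a spike peak if it is a local maximum that rises by
#' at least `prominence_mV` above the lowest point since the previous
#' detected peak, and exceeds `min_peak_mV`.
#'
#' @param x an [ei_sweep()] voltage trace, or numeric with `timebase`.
#' @param timebase needed for bare numeric traces.
#' @param prominence_mV minimum rise from the preceding trough, default 20.
#' @param min_peak_mV minimum absolute peak voltage, default -10.
#' @return Object of class `"spike_train"`: `spike_times_ms` (increasing),
#'   `spike_peaks_mV`, `count`.
#' @export
detect_spikes <- function(x, timebase = NULL, prominence_mV = 20,
                          min_peak_mV = -10) {
  if (!is.finite(prominence_mV) || prominence_mV <= 0)
    stop("'prominence_mV' must be > 0", call. = FALSE)
  tr <- as_trace(x, timebase)
  v <- tr$v
  t <- tb_times(tr$tb)
  times <- peaks <- numeric(0)
  mn <- Inf; mx <- -Inf; mxpos <- NA_integer_
  look_for_max <- TRUE
  for (i in seq_along(v)) {
    if (v[i] > mx) { mx <- v[i]; mxpos <- i }
    if (v[i] < mn) mn <- v[i]
    if (look_for_max) {
      if (v[i] < mx - prominence_mV) {
        if (mx >= min_peak_mV) {
          times <- c(times, t[mxpos]); peaks <- c(peaks, mx)
        }
        mn <- v[i]; look_for_max <- FALSE
      }
    } else if (v[i] > mn + prominence_mV) {
      mx <- v[i]; mxpos <- i; look_for_max <- TRUE
    }
  }
  spike_train(times, peaks)
}

#' Construct a spike train
#'
#' @param spike_times_ms strictly increasing spike times (ms).
#' @param spike_peaks_mV peak voltages, same length.
#' @return Object of class `"spike_train"`.
#' @export
spike_train <- function(spike_times_ms = numeric(0),
                        spike_peaks_mV = numeric(0)) {
  if (length(spike_times_ms) != length(spike_peaks_mV))
    stop("times and peaks must have equal length", call. = FALSE)
  if (length(spike_times_ms) > 1L && any(diff(spike_times_ms) <= 0))
    stop("spike times must be strictly increasing", call. = FALSE)
  structure(list(spike_times_ms = as.numeric(spike_times_ms),
                 spike_peaks_mV = as.numeric(spike_peaks_mV),
                 count = length(spike_times_ms)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes%s\n", x$count,
              if (x$count) paste0(" at ",
                                  paste(round(x$spike_times_ms, 2),
                                        collapse = ", "), " ms") else ""))
  invisible(x)
}

#' Latency of the first evoked spike
#'
#' @param train a [spike_train()].
#' @return The earliest spike time in ms, or `NA` for an empty train.
#' @export
first_spike_latency <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (train$count == 0L) NA_real_ else min(train$spike_times_ms)
}

#' Temporal spike-density histogram
#'
#' Pools spikes across trains into fixed-width time bins (1 ms by default),
#' giving the temporal distribution of population firing.
#'
#' @param trains list of [spike_train()] objects.
#' @param bin_ms bin width (ms), default 1.
#' @param window_ms histogram span `c(start, end)`; spikes outside are
#'   dropped. Bins are left-closed: a spike at time `t` falls in
#'   `[start + k*bin, start + (k+1)*bin)`.
#' @return Named list `counts` (per bin), `breaks_ms` (length
#'   `length(counts) + 1`), `n_spikes` (sum of counts).
#' @export
spike_density <- function(trains, bin_ms = 1, window_ms = c(0, 30)) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  stopifnot(all(vapply(trains, inherits, logical(1), "spike_train")))
  if (!is.finite(bin_ms) || bin_ms <= 0)
    stop("'bin_ms' must be > 0", call. = FALSE)
  breaks <- seq(window_ms[1], window_ms[2] + bin_ms - 1e-12, by = bin_ms)
  if (breaks[length(breaks)] < window_ms[2]) breaks <- c(breaks, breaks[length(breaks)] + bin_ms)
  all_t <- unlist(lapply(trains, function(tr) tr$spike_times_ms))
  all_t <- all_t[all_t >= window_ms[1] & all_t < breaks[length(breaks)]]
  counts <- if (length(all_t))
    tabulate(findInterval(all_t, breaks), nbins = length(breaks) - 1L)
  else rep(0L, length(breaks) - 1L)
  list(counts = counts, breaks_ms = breaks, n_spikes = sum(counts))
}
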