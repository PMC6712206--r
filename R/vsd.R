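#' Photodiode-array voltage-sensitive dye recording
#'
#' Container for diode-array optical data: one row per diode of
#' high-pass-filtered absorbance change `dA(t)` (arbitrary units, sign
#' convention: depolarisation positive), the per-diode absolute light level
#' `Amax` recorded at low gain, and the 2-D diode positions. The reference
#' instrument is a 464-channel array digitised at 1 kHz with ~150 um
#' inter-diode pitch; other geometries are accepted.
#'
#' @param frames numeric matrix, `n_diodes x n_samples`.
#' @param amax per-diode absolute light level (> 0), length `n_diodes`.
#' @param coords_um `n_diodes x 2` matrix of diode positions (um), unique.
#' @param timebase a [timebase()] (1 ms sampling by default usage).
#' @param gain acquisition gain factor (metadata only).
#' @param normalized has `frames` already been divided by `amax`?
#' @return Object of class `"diode_array"`.
#' @export
diode_array <- function(frames, amax, coords_um, timebase, gain = 1,
                        normalized = FALSE) {
  frames <- as.matrix(frames)
  stopifnot(inherits(timebase, "timebase"))
  if (ncol(frames) != timebase$n_samples)
    stop("ncol(frames) must equal timebase$n_samples", call. = FALSE)
  if (length(amax) != nrow(frames))
    stop("'amax' must have one entry per diode", call. = FALSE)
  if (any(!is.finite(amax)) || any(amax <= 0))
    stop("'amax' must be positive for every diode", call. = FALSE)
  coords_um <- as.matrix(coords_um)
  if (nrow(coords_um) != nrow(frames) || ncol(coords_um) != 2L)
    stop("'coords_um' must be an n_diodes x 2 matrix", call. = FALSE)
  if (anyDuplicated(coords_um) > 0)
    stop("diode coordinates must be unique", call. = FALSE)
  structure(list(frames = frames, amax = as.numeric(amax),
                 coords_um = coords_um, timebase = timebase, gain = gain,
                 normalized = isTRUE(normalized)),
            class = "diode_array")
}

#' @export
print.diode_array <- function(x, ...) {
  cat(sprintf("<diode_array> %d diodes x %d samples (%s)%s\n",
              nrow(x$frames), ncol(x$frames), format(x$timebase),
              if (x$normalized) ", normalized dA/Amax" else ", raw dA"))
  invisible(x)
}

#' Normalise absorbance changes to the absolute light level
#'
#' Divides each diode's `dA(t)` by its `Amax`, giving the fractional signal
#' `dA/Amax` that is comparable across diodes and proportional to membrane
#' depolarisation (positive = depolarisation for this dye).
#'
#' @param rec a [diode_array()].
#' @return The recording with `frames = dA/Amax` and `normalized = TRUE`.
#' @export
vsd_normalize <- function(rec) {
  stopifnot(inherits(rec, "diode_array"))
  rec$frames <- rec$frames / rec$amax
  rec$normalized <- TRUE
  rec
}

#' Subtract the instrumentation offset
#'
#' Removes, per diode, the mean signal over a pre-stimulus window (100 ms by
#' default) so that the pre-stimulus mean of the result is zero.
#'
#' @param rec a [diode_array()].
#' @param pre_window_ms length of the pre-stimulus window in ms, or an
#'   explicit `c(start, end)` window with `end <= 0`.
#' @return The recording with per-diode offsets removed.
#' @export
vsd_subtract_offset <- function(rec, pre_window_ms = 100) {
  stopifnot(inherits(rec, "diode_array"))
  win <- if (length(pre_window_ms) == 1L) c(-pre_window_ms, 0)
         else pre_window_ms
  check_baseline_window(win)
  idx <- tb_baseline_idx(rec$timebase, win, "pre-stimulus window")
  rec$frames <- rec$frames - rowMeans(rec$frames[, idx, drop = FALSE])
  rec
}

#' Spatial Gaussian filtering on the diode graph
#'
#' Smooths each frame in space with a 2-D Gaussian kernel evaluated on the
#' actual (irregular, hexagonally packed) diode positions: every diode's
#' value becomes the weighted average of all diodes, with weights
#' `exp(-d^2 / (2 sigma^2))` normalised to sum to 1 per target diode. The
#' default kernel width is one inter-diode distance (sigma = 150 um).
#' Distance-based weights avoid the interpolation artifacts of resampling an
#' irregular layout onto a grid, and weight normalisation preserves
#' spatially constant frames exactly.
#'
#' @param rec a [diode_array()].
#' @param sigma_um Gaussian kernel width (standard deviation) in um.
#' @return The spatially filtered recording.
#' @export
vsd_spatial_filter <- function(rec, sigma_um = 150) {
  stopifnot(inherits(rec, "diode_array"))
  if (!is.finite(sigma_um) || sigma_um <= 0)
    stop("'sigma_um' must be > 0", call. = FALSE)
  d2 <- as.matrix(stats::dist(rec$coords_um))^2
  W <- exp(-d2 / (2 * sigma_um^2))
  W <- W / rowSums(W)
  out <- W %*% rec$frames
  dimnames(out) <- NULL
  rec$frames <- out
  rec
}

#' Temporal running-average filtering
#'
#' Centred moving average over a fixed window (5 ms by default), applied per
#' diode. At the trace edges the window shrinks to the available samples, so
#' constant traces (DC) pass through unchanged everywhere.
#'
#' @param rec a [diode_array()], or a bare numeric matrix/vector (then
#'   `dt_ms` must be given).
#' @param window_ms averaging window length in ms.
#' @param dt_ms sample interval for bare matrices.
#' @return The temporally filtered object (same type as the input).
#' @export
vsd_temporal_filter <- function(rec, window_ms = 5, dt_ms = NULL) {
  if (inherits(rec, "diode_array")) {
    rec$frames <- running_average(rec$frames, window_ms, rec$timebase$dt_ms)
    return(rec)
  }
  if (is.null(dt_ms)) stop("'dt_ms' required for bare matrices", call. = FALSE)
  running_average(rec, window_ms, dt_ms)
}

running_average <- function(frames, window_ms, dt_ms) {
  vec <- is.null(dim(frames))
  if (vec) frames <- matrix(frames, nrow = 1)
  half <- max(0L, floor(window_ms / dt_ms / 2))
  if (half == 0L) return(if (vec) frames[1, ] else frames)
  n <- ncol(frames)
  ## truncated-window mean via cumulative sums (per row)
  cs <- t(apply(frames, 1, cumsum))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  out <- (cs[, hi, drop = FALSE] -
            cbind(0, cs)[, lo, drop = FALSE]) / rep(hi - lo + 1L,
                                                    each = nrow(frames))
  if (vec) out[1, ] else out
}

#' Region-of-interest response
#'
#' Averages the selected diodes per timepoint and quantifies the first
#' positive deflection after the stimulus: the search starts at the first
#' positive sample inside the search window and ends at the first return
#' below zero, and the peak is the maximum of that deflection. The
#' undershoot following the response is excluded by construction.
#'
#' @param rec a [diode_array()], normally after [vsd_normalize()],
#'   [vsd_subtract_offset()] and the two filters.
#' @param mask integer vector of diode indices (1-based, unique), or a
#'   list-like ROI with an `indices` element and optional `label`.
#' @param search_window_ms window for the first positive deflection, default
#'   `c(0, 200)` ms.
#' @param min_snr noise guard: a positive run only counts as the response
#'   deflection if its maximum exceeds `min_snr` times the pre-stimulus SD
#'   of the ROI trace (default 5). With noise-free input (baseline SD 0)
#'   the first positive run is taken as-is.
#' @return Object of class `"vsd_response"`: `trace` (dA/Amax, masked-diode
#'   mean), `peak_amplitude`, `peak_time_ms`, `timebase`, `label`,
#'   `n_diodes`.
#' @export
roi_response <- function(rec, mask, search_window_ms = c(0, 200),
                         min_snr = 5) {
  stopifnot(inherits(rec, "diode_array"))
  label <- ""
  if (is.list(mask)) { label <- mask$label %||% ""; mask <- mask$indices }
  mask <- as.integer(mask)
  if (length(mask) == 0L) stop("ROI mask is empty", call. = FALSE)
  if (anyDuplicated(mask) || any(mask < 1L) || any(mask > nrow(rec$frames)))
    stop("ROI mask indices must be unique and valid", call. = FALSE)
  trace <- colMeans(rec$frames[mask, , drop = FALSE])
  t <- tb_times(rec$timebase)
  widx <- which(t >= search_window_ms[1] - 1e-9 &
                  t <= search_window_ms[2] + 1e-9)
  pre <- which(t < 0)
  thr <- if (length(pre) > 1L) min_snr * stats::sd(trace[pre]) else 0
  peak <- NA_real_; peak_t <- NA_real_
  ## contiguous positive runs inside the window, in temporal order; the
  ## response is the first run clearing the noise threshold
  r <- rle(trace[widx] > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    seg <- widx[starts[j]:ends[j]]
    if (max(trace[seg]) > thr) {
      ip <- seg[which.max(trace[seg])]
      peak <- trace[ip]; peak_t <- t[ip]
      break
    }
  }
  structure(list(trace = trace, peak_amplitude = peak, peak_time_ms = peak_t,
                 timebase = rec$timebase, label = label,
                 n_diodes = length(mask)),
            class = "vsd_response")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vsd_response <- function(x, ...) {
  cat(sprintf("<vsd_response>%s %d diodes; peak dA/Amax = %.4g at %g ms\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$n_diodes, x$peak_amplitude, x$peak_time_ms))
  invisible(x)
}

#' Average repeated diode-array recordings
#'
#' Pointwise mean of at least `min_repeats` artifact-free realisations of the
#' same stimulus (the frames are averaged; `amax` and geometry are taken from
#' the first recording and must match).
#'
#' @param recs list of [diode_array()] recordings with identical geometry.
#' @param min_repeats minimum number of repeats required, default 3.
#' @return A single averaged [diode_array()].
#' @export
vsd_average_repeats <- function(recs, min_repeats = 3) {
  stopifnot(is.list(recs), all(vapply(recs, inherits, logical(1),
                                      "diode_array")))
  if (length(recs) < min_repeats)
    stop(sprintf("need >= %d repeats, got %d", min_repeats, length(recs)),
         call. = FALSE)
  r1 <- recs[[1]]
  for (r in recs[-1]) {
    if (!same_timebase(r$timebase, r1$timebase) ||
        !identical(dim(r$frames), dim(r1$frames)))
      stop("recordings must share geometry and timebase", call. = FALSE)
  }
  r1$frames <- Reduce(`+`, lapply(recs, `[[`, "frames")) / length(recs)
  attr(r1, "n_averaged") <- length(recs)
  r1
}

#' The full diode-array processing chain
#'
#' Convenience wrapper applying, in order: normalisation to `Amax`, repeat
#' averaging (when a list of recordings is given), pre-stimulus offset
#' subtraction, spatial Gaussian filtering and the temporal running average.
#' Every step is linear, so the chain itself is linear in the input frames.
#'
#' @param recs a [diode_array()] or list of repeats.
#' @param pre_window_ms offset window (ms), default 100.
#' @param sigma_um spatial kernel width, default 150.
#' @param tavg_ms temporal window, default 5.
#' @param min_repeats passed to [vsd_average_repeats()].
#' @return A processed [diode_array()].
#' @export
vsd_process <- function(recs, pre_window_ms = 100, sigma_um = 150,
                        tavg_ms = 5, min_repeats = 3) {
  if (inherits(recs, "diode_array")) recs <- list(recs)
  recs <- lapply(recs, function(r) if (r$normalized) r else vsd_normalize(r))
  rec <- if (length(recs) > 1L)
    vsd_average_repeats(recs, min_repeats) else recs[[1]]
  rec <- vsd_subtract_offset(rec, pre_window_ms)
  rec <- vsd_spatial_filter(rec, sigma_um)
  vsd_temporal_filter(rec, tavg_ms)
}
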