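#' Single recorded trace
#'
#' A sweep is one trace (membrane current in pA, membrane voltage in mV, or a
#' dimensionless optical signal) on a [timebase()]. Voltage-clamp sweeps carry
#' the holding potential; current-clamp sweeps leave it `NA`.
#'
#' @param values numeric vector of samples.
#' @param timebase a [timebase()]; its `n_samples` must equal `length(values)`.
#' @param holding_potential_mV clamp level in mV, or `NA` for current clamp.
#' @param condition stimulus condition, one of `"AIP"`, `"LA"`, `"DUO"`,
#'   `"STEP"`, `"OTHER"`.
#' @param repeat_index 1-based repetition index.
#' @param units unit label of `values` (`"pA"`, `"mV"`, or `""`).
#' @return An object of class `"ei_sweep"`.
#' @export
ei_sweep <- function(values, timebase, holding_potential_mV = NA_real_,
                     condition = "OTHER", repeat_index = 1L, units = "pA") {
  stopifnot(inherits(timebase, "timebase"))
  values <- as.numeric(values)
  if (length(values) != timebase$n_samples)
    stop("length(values) must equal timebase$n_samples", call. = FALSE)
  condition <- match.arg(condition, c("AIP", "LA", "DUO", "STEP", "OTHER"))
  if (!is.na(holding_potential_mV) && !is.finite(holding_potential_mV))
    stop("'holding_potential_mV' must be finite or NA", call. = FALSE)
  structure(list(values = values, timebase = timebase,
                 holding_potential_mV = as.numeric(holding_potential_mV),
                 condition = condition,
                 repeat_index = as.integer(repeat_index),
                 units = units),
            class = "ei_sweep")
}

#' @export
print.ei_sweep <- function(x, ...) {
  hp <- if (is.na(x$holding_potential_mV)) "current clamp"
        else sprintf("V_h = %g mV", x$holding_potential_mV)
  cat(sprintf("<ei_sweep> %s, %s, repeat %d, %s [%s]\n", x$condition, hp,
              x$repeat_index, format(x$timebase), x$units))
  invisible(x)
}

#' Collection of sweeps sharing one timebase and condition
#'
#' The container for a voltage-clamp protocol: repeated sweeps at several
#' holding potentials for one stimulus condition. Conductance decomposition
#' ([ei_decompose()]) requires at least two distinct holding potentials.
#'
#' @param sweeps list of [ei_sweep()] objects sharing a timebase and condition.
#' @return An object of class `"ei_sweepset"` with elements `sweeps`,
#'   `condition`, `timebase`, `holding_potentials_mV` (sorted unique) and
#'   `n_repeats` (maximum repeat count per potential).
#' @export
ei_sweepset <- function(sweeps) {
  if (!is.list(sweeps) || length(sweeps) == 0L ||
      !all(vapply(sweeps, inherits, logical(1), "ei_sweep")))
    stop("'sweeps' must be a non-empty list of ei_sweep objects", call. = FALSE)
  tb <- sweeps[[1]]$timebase
  cond <- sweeps[[1]]$condition
  for (s in sweeps) {
    if (!same_timebase(s$timebase, tb))
      stop("all sweeps must share one timebase", call. = FALSE)
    if (!identical(s$condition, cond))
      stop("all sweeps must share one condition", call. = FALSE)
  }
  hp <- vapply(sweeps, function(s) s$holding_potential_mV, numeric(1))
  hps <- sort(unique(hp[!is.na(hp)]))
  nrep <- if (length(hps)) max(table(hp)) else length(sweeps)
  structure(list(sweeps = sweeps, condition = cond, timebase = tb,
                 holding_potentials_mV = hps, n_repeats = as.integer(nrep)),
            class = "ei_sweepset")
}

#' @export
print.ei_sweepset <- function(x, ...) {
  cat(sprintf("<ei_sweepset> %s: %d sweeps, V_h = {%s} mV, %s\n",
              x$condition, length(x$sweeps),
              paste(x$holding_potentials_mV, collapse = ", "),
              format(x$timebase)))
  invisible(x)
}

#' @export
length.ei_sweepset <- function(x) length(x$sweeps)

## n_samples x n_sweeps matrix of values for the sweeps at given potentials
sweep_matrix <- function(ss, potentials = ss$holding_potentials_mV) {
  keep <- vapply(ss$sweeps, function(s)
    !is.na(s$holding_potential_mV) &&
      any(abs(s$holding_potential_mV - potentials) < 1e-9), logical(1))
  sw <- ss$sweeps[keep]
  vals <- vapply(sw, function(s) s$values, numeric(ss$timebase$n_samples))
  list(values = vals,
       potentials = vapply(sw, function(s) s$holding_potential_mV, numeric(1)))
}

#' Subtract the stimulus-independent background
#'
#' Removes the mean over a pre-stimulus baseline window from a sweep (or from
#' every sweep of a sweep set), so that the remaining current is the
#' stimulus-evoked synaptic current on top of a zero baseline. The default
#' window is the 100 ms immediately preceding the stimulus.
#'
#' The operation is linear (`f(a + b) = f(a) + f(b)` for a shared window) and
#' idempotent on already-centred traces.
#'
#' @param x an [ei_sweep()] or [ei_sweepset()].
#' @param window_ms pre-stimulus window `c(start, end)` in ms, `start < end <= 0`.
#' @return Object of the same class with baseline-subtracted values.
#' @export
subtract_background <- function(x, window_ms = c(-100, 0)) {
  UseMethod("subtract_background")
}

#' @export
subtract_background.ei_sweep <- function(x, window_ms = c(-100, 0)) {
  check_baseline_window(window_ms)
  idx <- tb_baseline_idx(x$timebase, window_ms)
  x$values <- x$values - mean(x$values[idx])
  x
}

#' @export
subtract_background.ei_sweepset <- function(x, window_ms = c(-100, 0)) {
  x$sweeps <- lapply(x$sweeps, subtract_background, window_ms = window_ms)
  x
}

#' Average repeated sweeps
#'
#' Collapses a sweep set to one sweep per holding potential by pointwise
#' averaging across repetitions (recordings are averaged over three
#' repetitions before decomposition). The number of repeats averaged is
#' recorded in the attribute `"n_averaged"` of each output sweep.
#'
#' @param ss an [ei_sweepset()].
#' @return An [ei_sweepset()] with one sweep per holding potential.
#' @export
average_repeats <- function(ss) {
  stopifnot(inherits(ss, "ei_sweepset"))
  hp <- vapply(ss$sweeps, function(s) s$holding_potential_mV, numeric(1))
  key <- ifelse(is.na(hp), "cc", format(hp, digits = 12))
  out <- lapply(split(seq_along(ss$sweeps), key), function(idx) {
    vals <- rowMeans(vapply(ss$sweeps[idx], function(s) s$values,
                            numeric(ss$timebase$n_samples)))
    s <- ss$sweeps[[idx[1]]]
    s$values <- vals
    s$repeat_index <- 1L
    attr(s, "n_averaged") <- length(idx)
    s
  })
  ord <- order(vapply(out, function(s) s$holding_potential_mV, numeric(1)),
               na.last = TRUE)
  ei_sweepset(out[ord])
}

#' Reduce the sampling rate by boxcar averaging
#'
#' Raw sweeps acquired at 100 kHz (`dt = 0.01` ms) are reduced to the 0.1 ms
#' analysis grid by averaging consecutive non-overlapping blocks of samples.
#' Trailing samples that do not fill a block are dropped.
#'
#' @param x an [ei_sweep()] or [ei_sweepset()].
#' @param factor integer decimation factor (e.g. 10 for 0.01 -> 0.1 ms).
#' @return Object of the same class on the coarser timebase.
#' @export
decimate <- function(x, factor) UseMethod("decimate")

#' @export
decimate.ei_sweep <- function(x, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("'factor' must be a positive integer",
                                         call. = FALSE)
  if (factor == 1L) return(x)
  n_out <- x$timebase$n_samples %/% factor
  if (n_out < 2L) stop("decimation leaves fewer than 2 samples", call. = FALSE)
  v <- x$values[seq_len(n_out * factor)]
  vals <- colMeans(matrix(v, nrow = factor))
  ## block centre: mean time of the samples averaged into each output sample
  tb <- x$timebase
  t0 <- tb$t0_ms + (factor - 1) / 2 * tb$dt_ms
  x$values <- vals
  x$timebase <- timebase(t0, tb$dt_ms * factor, n_out)
  x
}

#' @export
decimate.ei_sweepset <- function(x, factor) {
  ei_sweepset(lapply(x$sweeps, decimate, factor = factor))
}
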