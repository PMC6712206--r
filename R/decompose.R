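#' Synaptic reversal potentials
#'
#' @param E_exc_mV reversal potential of the excitatory (glutamatergic)
#'   conductance; 0 mV by default.
#' @param E_inh_mV reversal potential of the inhibitory (GABA-A, chloride)
#'   conductance; -70 mV by default, which is also the holding potential at
#'   which inhibition is invisible in the recorded current.
#' @return An object of class `"reversal_potentials"`.
#' @export
reversal_potentials <- function(E_exc_mV = 0, E_inh_mV = -70) {
  if (!is.finite(E_exc_mV) || !is.finite(E_inh_mV))
    stop("reversal potentials must be finite", call. = FALSE)
  if (abs(E_exc_mV - E_inh_mV) < 1e-9)
    stop("E_exc_mV and E_inh_mV must differ", call. = FALSE)
  structure(list(E_exc_mV = E_exc_mV, E_inh_mV = E_inh_mV),
            class = "reversal_potentials")
}

#' Per-timepoint linear I/V regression
#'
#' At every timepoint the membrane currents recorded across holding
#' potentials are regressed on the holding potential by ordinary least
#' squares, yielding the instantaneous linear I/V relation
#' `I_m(t) = a(t) * V_m + b(t)`. The slope `a(t)` is the total evoked
#' conductance in nS (with V in mV and I in pA, nS * mV = pA exactly) and the
#' intercept `b(t)` carries the reversal information used by
#' [decompose_conductance()].
#'
#' Timepoints where the current is identical at all potentials fit a flat
#' line perfectly and are assigned `r2 = 1` by convention.
#'
#' @param ss a background-subtracted, repeat-averaged [ei_sweepset()] with at
#'   least two distinct holding potentials.
#' @return An object of class `"iv_fit"`: list with `a_nS`, `b_pA`, `r2`
#'   traces, `n_potentials`, `potentials_mV`, `timebase`.
#' @export
fit_iv <- function(ss) {
  stopifnot(inherits(ss, "ei_sweepset"))
  if (length(ss$holding_potentials_mV) < 2L)
    stop("I/V regression needs >= 2 distinct holding potentials",
         call. = FALSE)
  sm <- sweep_matrix(ss)
  if (ncol(sm$values) > length(ss$holding_potentials_mV))
    sm <- sweep_matrix(average_repeats(ss))
  I <- sm$values                      # n_samples x n_potentials
  V <- sm$potentials
  if (any(!is.finite(I))) stop("non-finite current samples", call. = FALSE)
  Vc <- V - mean(V)
  Sxx <- sum(Vc^2)
  a <- as.numeric(I %*% Vc) / Sxx
  b <- rowMeans(I) - a * mean(V)
  fitted <- outer(a, V) + b
  ss_res <- rowSums((I - fitted)^2)
  ss_tot <- rowSums((I - rowMeans(I))^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, 1)
  r2 <- pmin(pmax(r2, 0), 1)
  structure(list(a_nS = a, b_pA = b, r2 = r2,
                 n_potentials = length(V), potentials_mV = V,
                 timebase = ss$timebase),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf("<iv_fit> %d potentials, %s; median r2 = %.4f\n",
              x$n_potentials, format(x$timebase),
              stats::median(x$r2, na.rm = TRUE)))
  invisible(x)
}

#' Split the total conductance into excitation and inhibition
#'
#' From the instantaneous I/V relation, the inhibitory conductance is
#' `G_inh(t) = (b(t) + a(t) * E_exc) / (E_exc - E_inh)` and the excitatory
#' conductance is the remainder `G_exc(t) = a(t) - G_inh(t)`. Both rest on
#' the assumption that the two synaptic conductances are voltage independent
#' with fixed reversal potentials.
#'
#' Estimation noise can push either conductance slightly negative; by default
#' negative values are reported as-is (clipping destroys the linearity of the
#' estimator) and `clip_negative = TRUE` zeroes them, recording a flag.
#'
#' @param ivfit an [fit_iv()] result.
#' @param reversals a [reversal_potentials()].
#' @param clip_negative clip negative conductance estimates to 0?
#' @return An object of class `"conductance_trace"`: `G_exc_nS`, `G_inh_nS`,
#'   `r2`, `timebase`, `clipped`.
#' @export
decompose_conductance <- function(ivfit, reversals = reversal_potentials(),
                                  clip_negative = FALSE) {
  stopifnot(inherits(ivfit, "iv_fit"), inherits(reversals,
                                                "reversal_potentials"))
  if (any(!is.finite(ivfit$a_nS)) || any(!is.finite(ivfit$b_pA)))
    stop("I/V fit contains non-finite coefficients", call. = FALSE)
  Ee <- reversals$E_exc_mV
  Ei <- reversals$E_inh_mV
  g_inh <- (ivfit$b_pA + ivfit$a_nS * Ee) / (Ee - Ei)
  g_exc <- ivfit$a_nS - g_inh
  clipped <- FALSE
  if (clip_negative) {
    clipped <- any(g_inh < 0) || any(g_exc < 0)
    g_inh <- pmax(g_inh, 0)
    g_exc <- pmax(g_exc, 0)
  }
  structure(list(G_exc_nS = g_exc, G_inh_nS = g_inh, r2 = ivfit$r2,
                 timebase = ivfit$timebase, reversals = reversals,
                 clipped = clipped),
            class = "conductance_trace")
}

#' @export
print.conductance_trace <- function(x, ...) {
  cat(sprintf(
    "<conductance_trace> %s; peak G_exc = %.3g nS, peak G_inh = %.3g nS%s\n",
    format(x$timebase), max(x$G_exc_nS), max(x$G_inh_nS),
    if (isTRUE(x$clipped)) " (negatives clipped)" else ""))
  invisible(x)
}

#' Decompose a voltage-clamp sweep set into E and I conductances
#'
#' The main fitting function. Runs the whole decomposition on a raw sweep
#' set: background subtraction over the pre-stimulus baseline, averaging over
#' repetitions, the per-timepoint linear I/V regression across holding
#' potentials, and the split into excitatory and inhibitory conductances at
#' the given reversal potentials. Analysis is restricted to the post-stimulus
#' window (100 ms by default, on the sweep set's own grid — use [decimate()]
#' beforehand to reach the 0.1 ms analysis resolution).
#'
#' A quality statistic (median r2 of the I/V fit over the response window) is
#' compared with `qc_r2_min`: cells whose I/V relation is not linear should
#' not be decomposed, so fits with `qc_pass = FALSE` deserve scrutiny.
#'
#' @param ss an [ei_sweepset()] with >= 2 distinct holding potentials.
#' @param reversals a [reversal_potentials()].
#' @param baseline_ms pre-stimulus baseline window for background
#'   subtraction, `c(start, end)` with `end <= 0`.
#' @param window_ms post-stimulus analysis window (ms), default `c(0, 100)`.
#' @param clip_negative clip negative conductance estimates to 0?
#' @param qc_r2_min minimum acceptable median r2 over the response window.
#' @return An object of class `"ei_decomposition"` with the fitted
#'   [decompose_conductance()] trace, the underlying [fit_iv()] object, the
#'   processed (subtracted, averaged, windowed) sweep set and QC fields.
#'   Methods: `print`, `summary`, `coef`, `fitted`, `residuals`, `predict`,
#'   `plot`.
#' @examples
#' tb <- timebase(-100, 0.1, 2000)
#' k <- default_kernels("AiP")
#' ss <- simulate_voltage_clamp(kernel_waveform(k$exc, tb),
#'                              kernel_waveform(k$inh, tb),
#'                              timebase = tb, noise_sd_pA = 0, seed = 1)
#' fit <- ei_decompose(ss)
#' coef(fit)
#' @export
ei_decompose <- function(ss, reversals = reversal_potentials(),
                         baseline_ms = c(-100, 0), window_ms = c(0, 100),
                         clip_negative = FALSE, qc_r2_min = 0.9) {
  stopifnot(inherits(ss, "ei_sweepset"))
  if (length(ss$holding_potentials_mV) < 2L)
    stop("decomposition needs >= 2 distinct holding potentials", call. = FALSE)
  ## subtract over whatever part of the baseline window was recorded;
  ## sweeps starting at/after the stimulus are assumed pre-subtracted
  t <- tb_times(ss$timebase)
  bw <- c(max(baseline_ms[1], min(t)), baseline_ms[2])
  if (bw[1] < bw[2] - 1e-9 && min(t) < -1e-9)
    ss <- subtract_background(ss, bw)
  ss <- average_repeats(ss)
  iv_full <- fit_iv(ss)
  ct_full <- decompose_conductance(iv_full, reversals, clip_negative)
  win <- tb_window_idx(ss$timebase, window_ms, "analysis window")
  ## linearity screen: judge r2 only where a response is present (total
  ## conductance above 10% of its in-window peak) — response-free samples
  ## are pure noise and carry no information about I/V linearity
  a_win <- iv_full$a_nS[win]
  resp <- if (max(a_win) > 0) win[a_win > 0.1 * max(a_win)] else win
  qc_r2 <- stats::median(iv_full$r2[resp])
  structure(list(conductances = ct_full, iv = iv_full, sweepset = ss,
                 reversals = reversals, window_ms = window_ms,
                 window_idx = win, baseline_ms = baseline_ms,
                 clip_negative = clip_negative,
                 qc = list(median_r2 = qc_r2, r2_min = qc_r2_min,
                           qc_pass = qc_r2 >= qc_r2_min)),
            class = "ei_decomposition")
}

#' @export
print.ei_decomposition <- function(x, ...) {
  cf <- coef(x)
  cat(sprintf("Conductance decomposition (%s, %d holding potentials)\n",
              x$sweepset$condition, x$iv$n_potentials))
  cat(sprintf("  window [%g, %g] ms, E_exc = %g mV, E_inh = %g mV\n",
              x$window_ms[1], x$window_ms[2], x$reversals$E_exc_mV,
              x$reversals$E_inh_mV))
  cat(sprintf("  peak G_exc %.3g nS at %.1f ms; peak G_inh %.3g nS at %.1f ms\n",
              cf["peak_G_exc_nS"], cf["peak_time_exc_ms"],
              cf["peak_G_inh_nS"], cf["peak_time_inh_ms"]))
  cat(sprintf("  I/V linearity: median r2 = %.4f (QC %s at %.2f)\n",
              x$qc$median_r2, if (x$qc$qc_pass) "pass" else "FAIL",
              x$qc$r2_min))
  invisible(x)
}

#' @export
coef.ei_decomposition <- function(object, ...) {
  ct <- object$conductances
  t <- tb_times(ct$timebase)
  w <- object$window_idx
  ie <- w[which.max(ct$G_exc_nS[w])]
  ii <- w[which.max(ct$G_inh_nS[w])]
  c(peak_G_exc_nS = ct$G_exc_nS[ie], peak_time_exc_ms = t[ie],
    peak_G_inh_nS = ct$G_inh_nS[ii], peak_time_inh_ms = t[ii],
    median_r2 = object$qc$median_r2)
}

#' @export
summary.ei_decomposition <- function(object, ...) {
  out <- list(coef = coef(object), condition = object$sweepset$condition,
              n_potentials = object$iv$n_potentials,
              potentials_mV = object$iv$potentials_mV,
              qc = object$qc, window_ms = object$window_ms)
  class(out) <- "summary.ei_decomposition"
  out
}

#' @export
print.summary.ei_decomposition <- function(x, ...) {
  cat(sprintf("Decomposition of %s sweeps at V_h = {%s} mV\n", x$condition,
              paste(x$potentials_mV, collapse = ", ")))
  print(round(x$coef, 4))
  cat(sprintf("QC: median r2 %.4f (threshold %.2f): %s\n", x$qc$median_r2,
              x$qc$r2_min, if (x$qc$qc_pass) "pass" else "fail"))
  invisible(x)
}

#' Predict membrane currents implied by a decomposition
#'
#' Reconstructs `I(t) = G_exc(t) (V - E_exc) + G_inh(t) (V - E_inh)` at the
#' requested holding potentials.
#'
#' @param object an [ei_decompose()] fit.
#' @param potentials_mV holding potentials; default those of the fit.
#' @param ... unused.
#' @return Matrix (n_samples x n_potentials) of currents in pA.
#' @export
predict.ei_decomposition <- function(object,
                                     potentials_mV = object$iv$potentials_mV,
                                     ...) {
  ct <- object$conductances
  Ee <- object$reversals$E_exc_mV
  Ei <- object$reversals$E_inh_mV
  out <- vapply(potentials_mV,
                function(v) ct$G_exc_nS * (v - Ee) + ct$G_inh_nS * (v - Ei),
                numeric(ct$timebase$n_samples))
  colnames(out) <- sprintf("%gmV", potentials_mV)
  out
}

#' @export
fitted.ei_decomposition <- function(object, ...) predict(object)

#' @export
residuals.ei_decomposition <- function(object, ...) {
  sm <- sweep_matrix(object$sweepset)
  sm$values - predict(object, sm$potentials)
}

#' @export
plot.ei_decomposition <- function(x, ...) {
  ct <- x$conductances
  t <- tb_times(ct$timebase)[x$window_idx]
  graphics::matplot(t, cbind(ct$G_exc_nS[x$window_idx],
                             ct$G_inh_nS[x$window_idx]),
                    type = "l", lty = 1, col = c("firebrick", "navy"),
                    xlab = "time after stimulus (ms)",
                    ylab = "conductance (nS)", ...)
  graphics::legend("topright", c("G_exc", "G_inh"), lty = 1,
                   col = c("firebrick", "navy"), bty = "n")
  invisible(x)
}

#' Passive membrane conductance from a voltage step
#'
#' The leak conductance `G_m` is the inverse of the passive input resistance,
#' measured in voltage clamp as the steady-state current change produced by a
#' small voltage step: `G_m = dI_steady / dV`. Plateau and baseline means are
#' taken over configurable windows.
#'
#' @param step_sweep an [ei_sweep()] containing the step response; the step
#'   onset is at t = 0.
#' @param step_amplitude_mV the command step size (nonzero; e.g. -10).
#' @param baseline_ms pre-step window for the holding current.
#' @param plateau_ms window over which the response has reached steady state.
#' @return Leak conductance in nS.
#' @export
measure_gm <- function(step_sweep, step_amplitude_mV,
                       baseline_ms = c(-100, 0), plateau_ms = c(50, 100)) {
  stopifnot(inherits(step_sweep, "ei_sweep"))
  if (!is.finite(step_amplitude_mV) || step_amplitude_mV == 0)
    stop("'step_amplitude_mV' must be nonzero", call. = FALSE)
  i0 <- mean(step_sweep$values[tb_baseline_idx(step_sweep$timebase,
                                               baseline_ms)])
  i1 <- mean(step_sweep$values[tb_window_idx(step_sweep$timebase, plateau_ms,
                                             "plateau window")])
  (i1 - i0) / step_amplitude_mV
}

#' Excitability ratio trace
#'
#' The leak-regularised balance of excitation and inhibition,
#' `E_ratio(t) = (G_exc + G_m) / (G_inh + G_m)`; the membrane conductance
#' `G_m` in both numerator and denominator prevents division by zero outside
#' the response and anchors the ratio at 1 when no synaptic input is active.
#' Values above 1 indicate dominant excitation, below 1 dominant inhibition.
#'
#' @param ct a [decompose_conductance()] trace (or the `conductances` element
#'   of an [ei_decompose()] fit).
#' @param G_m_nS passive membrane conductance in nS (> 0), from
#'   [measure_gm()].
#' @return Object of class `"excitability_trace"`: `ratio`, `G_m_nS`,
#'   `timebase`.
#' @export
excitability_ratio <- function(ct, G_m_nS) {
  if (inherits(ct, "ei_decomposition")) ct <- ct$conductances
  stopifnot(inherits(ct, "conductance_trace"))
  if (!is.finite(G_m_nS) || G_m_nS <= 0)
    stop("'G_m_nS' must be a positive number", call. = FALSE)
  structure(list(ratio = (ct$G_exc_nS + G_m_nS) / (ct$G_inh_nS + G_m_nS),
                 G_m_nS = G_m_nS, timebase = ct$timebase),
            class = "excitability_trace")
}

#' @export
print.excitability_trace <- function(x, ...) {
  cat(sprintf("<excitability_trace> %s; range [%.3f, %.3f], G_m = %g nS\n",
              format(x$timebase), min(x$ratio), max(x$ratio), x$G_m_nS))
  invisible(x)
}
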