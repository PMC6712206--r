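#' Difference-of-exponentials synaptic conductance kernel
#'
#' Ground-truth waveform for the simulator: a monophasic conductance
#' transient starting at `latency_ms` with rise constant `tau_rise_ms`,
#' decay constant `tau_decay_ms`, normalised so its maximum equals
#' `peak_nS`.
#'
#' @param latency_ms onset latency after the stimulus (ms, >= 0).
#' @param tau_rise_ms rise time constant (ms, > 0).
#' @param tau_decay_ms decay time constant (ms, > `tau_rise_ms`).
#' @param peak_nS peak conductance (nS, >= 0).
#' @param kind `"exc"` or `"inh"`.
#' @return Object of class `"conductance_kernel"`.
#' @export
conductance_kernel <- function(latency_ms, tau_rise_ms, tau_decay_ms,
                               peak_nS, kind = c("exc", "inh")) {
  kind <- match.arg(kind)
  if (!is.finite(tau_rise_ms) || tau_rise_ms <= 0 ||
      !is.finite(tau_decay_ms) || tau_decay_ms <= tau_rise_ms)
    stop("need tau_decay_ms > tau_rise_ms > 0", call. = FALSE)
  if (!is.finite(peak_nS) || peak_nS < 0)
    stop("'peak_nS' must be >= 0", call. = FALSE)
  if (!is.finite(latency_ms) || latency_ms < 0)
    stop("'latency_ms' must be >= 0", call. = FALSE)
  structure(list(latency_ms = latency_ms, tau_rise_ms = tau_rise_ms,
                 tau_decay_ms = tau_decay_ms, peak_nS = peak_nS,
                 kind = kind),
            class = "conductance_kernel")
}

#' @export
print.conductance_kernel <- function(x, ...) {
  cat(sprintf(
    "<conductance_kernel> %s: peak %g nS, latency %g ms, tau %g/%g ms\n",
    x$kind, x$peak_nS, x$latency_ms, x$tau_rise_ms, x$tau_decay_ms))
  invisible(x)
}

#' Default excitatory/inhibitory kernels for each pathway
#'
#' Peak conductances and onset latencies follow the reported single-pathway
#' values: AiP excitation 2.94 nS at 5.95 ms and inhibition 8.89 nS at
#' 7.67 ms; LA excitation 0.75 nS at 5.55 ms and inhibition 3.22 nS at
#' 6.72 ms. Rise/decay kinetics (1 and 10 ms) are generator conventions,
#' not measured quantities.
#'
#' @param pathway `"AiP"` or `"LA"`.
#' @return List with elements `exc` and `inh` ([conductance_kernel()]s).
#' @export
default_kernels <- function(pathway = c("AiP", "LA")) {
  pathway <- match.arg(pathway)
  if (pathway == "AiP")
    list(exc = conductance_kernel(5.95, 1, 10, 2.94, "exc"),
         inh = conductance_kernel(7.67, 1, 10, 8.89, "inh"))
  else
    list(exc = conductance_kernel(5.55, 1, 10, 0.75, "exc"),
         inh = conductance_kernel(6.72, 1, 10, 3.22, "inh"))
}

#' Evaluate a kernel on a timebase
#'
#' `g(t) = peak * N * (exp(-(t-L)/tau_d) - exp(-(t-L)/tau_r))` for `t >= L`,
#' 0 before, with `N` the normalisation making `max g = peak`. The maximum
#' falls at `L + tau_r tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`.
#'
#' @param k a [conductance_kernel()].
#' @param tb a [timebase()].
#' @return Numeric conductance trace in nS.
#' @export
kernel_waveform <- function(k, tb) {
  stopifnot(inherits(k, "conductance_kernel"), inherits(tb, "timebase"))
  t <- tb_times(tb) - k$latency_ms
  tr <- k$tau_rise_ms; td <- k$tau_decay_ms
  tpk <- tr * td / (td - tr) * log(td / tr)
  norm <- exp(-tpk / td) - exp(-tpk / tr)
  g <- ifelse(t >= 0, (exp(-t / td) - exp(-t / tr)) / norm, 0)
  k$peak_nS * pmax(g, 0)
}

#' Passive membrane / integrate-and-fire parameters
#'
#' Defaults are the intrinsic properties of deep-layer principal neurons:
#' input resistance 111 MOhm, resting potential -62.8 mV, spike threshold
#' -37.3 mV, capacitance 21.4 pF. The reset potential defaults to threshold
#' minus the afterhyperpolarisation amplitude (8.3 mV -> -45.6 mV).
#' [membrane_model_pv()] gives the corresponding parvalbumin-interneuron
#' set (104 MOhm, -65.9 mV, -36.1 mV, 14.3 pF, AHP 31.1 mV).
#'
#' @param C_pF membrane capacitance (pF, > 0).
#' @param R_MOhm input resistance (MOhm, > 0); leak conductance is
#'   `G_m = 1000 / R_MOhm` nS.
#' @param E_rest_mV resting membrane potential (mV).
#' @param V_thresh_mV spike threshold (mV).
#' @param V_reset_mV post-spike reset (mV, < threshold).
#' @param refractory_ms absolute refractory period (ms).
#' @return Object of class `"membrane_model"`.
#' @export
membrane_model <- function(C_pF = 21.4, R_MOhm = 111, E_rest_mV = -62.8,
                           V_thresh_mV = -37.3, V_reset_mV = -45.6,
                           refractory_ms = 2) {
  if (C_pF <= 0 || R_MOhm <= 0) stop("C and R must be > 0", call. = FALSE)
  if (V_reset_mV >= V_thresh_mV)
    stop("V_reset_mV must be below V_thresh_mV", call. = FALSE)
  structure(list(C_pF = C_pF, R_MOhm = R_MOhm, E_rest_mV = E_rest_mV,
                 V_thresh_mV = V_thresh_mV, V_reset_mV = V_reset_mV,
                 refractory_ms = refractory_ms,
                 G_m_nS = 1000 / R_MOhm, tau_m_ms = R_MOhm * C_pF / 1000),
            class = "membrane_model")
}

#' @rdname membrane_model
#' @export
membrane_model_pv <- function() {
  membrane_model(C_pF = 14.3, R_MOhm = 104, E_rest_mV = -65.9,
                 V_thresh_mV = -36.1, V_reset_mV = -67.2)
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf(
    "<membrane_model> R %g MOhm (G_m %.3g nS), C %g pF (tau_m %.3g ms), rest %g, thresh %g, reset %g mV\n",
    x$R_MOhm, x$G_m_nS, x$C_pF, x$tau_m_ms, x$E_rest_mV, x$V_thresh_mV,
    x$V_reset_mV))
  invisible(x)
}

#' Simulate an ideal voltage-clamp sweep set
#'
#' Forward model of the decomposition equations under an ideal clamp
#' (`V_m = V_h` at all times): at each holding potential and repeat,
#' `I(t) = g_exc(t) (V_h - E_exc) + g_inh(t) (V_h - E_inh)
#' + G_m (V_h - E_rest) + noise`, with iid Gaussian current noise.
#' Repeats at the same potential differ only in the noise. The default
#' protocol uses the five holding potentials -90 to -50 mV in 10 mV steps
#' and three repetitions.
#'
#' @param gexc,ginh conductance traces (nS) on `timebase`, e.g. from
#'   [kernel_waveform()].
#' @param timebase a [timebase()].
#' @param membrane a [membrane_model()] (supplies leak `G_m` and `E_rest`).
#' @param potentials_mV holding potentials (>= 2 distinct values).
#' @param reversals a [reversal_potentials()].
#' @param noise_sd_pA recording noise SD in pA, default 10.
#' @param n_repeats repetitions per potential, default 3.
#' @param seed RNG seed (`NULL` leaves the RNG state alone).
#' @param condition condition label for the sweeps.
#' @return An [ei_sweepset()].
#' @export
simulate_voltage_clamp <- function(gexc, ginh, timebase,
                                   membrane = membrane_model(),
                                   potentials_mV = seq(-90, -50, by = 10),
                                   reversals = reversal_potentials(),
                                   noise_sd_pA = 10, n_repeats = 3,
                                   seed = NULL, condition = "AIP") {
  stopifnot(inherits(timebase, "timebase"), inherits(membrane,
                                                     "membrane_model"))
  potentials_mV <- unique(as.numeric(potentials_mV))
  if (length(potentials_mV) < 2L)
    stop("need >= 2 distinct holding potentials", call. = FALSE)
  if (length(gexc) != timebase$n_samples ||
      length(ginh) != timebase$n_samples)
    stop("conductance traces must match the timebase", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Ee <- reversals$E_exc_mV; Ei <- reversals$E_inh_mV
  sweeps <- list()
  for (v in potentials_mV) {
    clean <- gexc * (v - Ee) + ginh * (v - Ei) +
      membrane$G_m_nS * (v - membrane$E_rest_mV)
    for (r in seq_len(n_repeats)) {
      eps <- if (noise_sd_pA > 0)
        stats::rnorm(timebase$n_samples, 0, noise_sd_pA) else 0
      sweeps[[length(sweeps) + 1L]] <-
        ei_sweep(clean + eps, timebase, v, condition, r)
    }
  }
  ei_sweepset(sweeps)
}

#' Simulate a conductance-driven leaky integrate-and-fire neuron
#'
#' Forward-Euler integration of
#' `C dV/dt = -(V - E_rest)/R - g_exc (V - E_exc) - g_inh (V - E_inh)
#' + noise`; when `V` reaches threshold a spike is logged, a stylised spike
#' peak (+20 mV) is rendered into the returned voltage trace for detector
#' testing, and `V` is reset and held for the refractory period. The
#' integration step must satisfy `dt <= 0.1 tau_m` for stability; the
#' intended grid is `dt = 0.01` ms.
#'
#' @param gexc,ginh conductance traces (nS) on `timebase`.
#' @param timebase a [timebase()] whose `dt_ms` is the Euler step.
#' @param membrane a [membrane_model()].
#' @param reversals a [reversal_potentials()].
#' @param noise_sd_pA white current-noise SD in pA, default 0.
#' @param seed RNG seed.
#' @param spike_peak_mV rendered spike-peak voltage, default +20.
#' @return List: `voltage` (an [ei_sweep()] in mV) and `spikes` (the
#'   simulator's own [spike_train()], the ground truth for detector tests).
#' @export
simulate_current_clamp <- function(gexc, ginh, timebase,
                                   membrane = membrane_model(),
                                   reversals = reversal_potentials(),
                                   noise_sd_pA = 0, seed = NULL,
                                   spike_peak_mV = 20) {
  stopifnot(inherits(timebase, "timebase"), inherits(membrane,
                                                     "membrane_model"))
  dt <- timebase$dt_ms
  if (dt > 0.1 * membrane$tau_m_ms)
    stop(sprintf("dt = %g ms too large for stability (tau_m = %.3g ms)",
                 dt, membrane$tau_m_ms), call. = FALSE)
  n <- timebase$n_samples
  if (length(gexc) != n || length(ginh) != n)
    stop("conductance traces must match the timebase", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  eps <- if (noise_sd_pA > 0) stats::rnorm(n, 0, noise_sd_pA) else numeric(n)
  Gl <- membrane$G_m_nS; C <- membrane$C_pF
  Ee <- reversals$E_exc_mV; Ei <- reversals$E_inh_mV
  t <- tb_times(timebase)
  v <- numeric(n)
  v[1] <- membrane$E_rest_mV
  spike_idx <- integer(0)
  refr_until <- -Inf
  for (i in seq_len(n - 1L)) {
    if (t[i] < refr_until) {
      v[i + 1L] <- membrane$V_reset_mV
      next
    }
    ## pA / pF * ms = mV
    dv <- (-Gl * (v[i] - membrane$E_rest_mV) - gexc[i] * (v[i] - Ee) -
             ginh[i] * (v[i] - Ei) + eps[i]) / C * dt
    vn <- v[i] + dv
    if (vn >= membrane$V_thresh_mV) {
      spike_idx <- c(spike_idx, i + 1L)
      v[i + 1L] <- spike_peak_mV          # stylised spike peak
      refr_until <- t[i + 1L] + membrane$refractory_ms
    } else v[i + 1L] <- vn
  }
  ## samples right after a rendered peak sit at reset already (refractory)
  list(voltage = ei_sweep(v, timebase, NA_real_, "OTHER", 1L, units = "mV"),
       spikes = spike_train(t[spike_idx], rep(spike_peak_mV,
                                              length(spike_idx))))
}

#' Construct a simultaneous-stimulation (DUO) response
#'
#' Builds the ground-truth DUO trace from the two single-pathway traces and
#' a known summation factor, `duo = true_alpha * (aip + la)`, optionally
#' passing the result through a saturating distortion
#' `x -> sat * tanh(x / sat)` for robustness experiments.
#'
#' @param aip,la numeric traces (or lists of traces with matching names,
#'   e.g. `list(exc = ..., inh = ...)`; then each element is combined).
#' @param true_alpha the ground-truth scale factor.
#' @param saturation optional saturation level in the traces' own units;
#'   `NULL` (default) for none.
#' @return A trace (or list of traces) of the same shape as the inputs.
#' @export
make_duo <- function(aip, la, true_alpha = 1, saturation = NULL) {
  if (is.list(aip)) {
    stopifnot(is.list(la), identical(names(aip), names(la)))
    return(Map(make_duo, aip, la,
               MoreArgs = list(true_alpha = true_alpha,
                               saturation = saturation)))
  }
  out <- true_alpha * (aip + la)
  if (!is.null(saturation)) out <- saturation * tanh(out / saturation)
  out
}

## hexagonally packed diode coordinates, row by row around the origin
hex_coords <- function(n_diodes, pitch_um) {
  side <- ceiling(sqrt(n_diodes / 0.866))
  rows <- -side:side
  xs <- ys <- numeric(0)
  for (r in rows) {
    x <- (-side:side) * pitch_um + (r %% 2) * pitch_um / 2
    xs <- c(xs, x)
    ys <- c(ys, rep(r * pitch_um * sqrt(3) / 2, length(x)))
  }
  d <- xs^2 + ys^2
  ord <- order(d)[seq_len(n_diodes)]
  cbind(x = xs[ord], y = ys[ord])
}

#' Simulate a diode-array voltage-sensitive dye recording
#'
#' Emulates the 464-channel photodiode array sampled at 1 kHz: hexagonally
#' packed diode positions at ~150 um pitch, a propagation-free activation
#' wave with Gaussian spatial profile and difference-of-exponentials time
#' course of known fractional amplitude, per-diode `Amax` drawn uniformly,
#' and additive Gaussian noise. Frames are returned un-normalised
#' (`dA = fraction * Amax`) so that [vsd_normalize()] is exercised by the
#' analysis.
#'
#' @param n_diodes number of diodes, default 464.
#' @param pitch_um inter-diode distance, default 150.
#' @param amplitude_fraction peak `dA/Amax` at the wave centre, default
#'   0.0741.
#' @param center_um 2-vector, wave centre (um), default the array centre.
#' @param spread_um Gaussian spatial SD of the wave, default 900 (the
#'   activated region spans well over a millimetre, so the wave is broad
#'   relative to the 150 um spatial filter).
#' @param onset_ms,rise_ms,decay_ms temporal kernel parameters, defaults
#'   5, 5, 30 ms.
#' @param noise_sd_fraction noise SD on the `dA/Amax` scale, default 0.005.
#' @param n_repeats number of repeats generated, default 3.
#' @param timebase default 1 kHz with 100 ms pre-stimulus and 300 ms
#'   post-stimulus.
#' @param seed RNG seed.
#' @return List of `n_repeats` [diode_array()] recordings (raw `dA`).
#' @export
simulate_vsd <- function(n_diodes = 464, pitch_um = 150,
                         amplitude_fraction = 0.0741, center_um = c(0, 0),
                         spread_um = 900, onset_ms = 5, rise_ms = 5,
                         decay_ms = 30, noise_sd_fraction = 0.005,
                         n_repeats = 3, timebase = NULL, seed = NULL) {
  if (is.null(timebase)) timebase <- timebase(-100, 1, 400)
  if (amplitude_fraction < 0)
    stop("'amplitude_fraction' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  coords <- hex_coords(n_diodes, pitch_um)
  d2 <- (coords[, 1] - center_um[1])^2 + (coords[, 2] - center_um[2])^2
  spatial <- exp(-d2 / (2 * spread_um^2))
  tkern <- kernel_waveform(conductance_kernel(onset_ms, rise_ms, decay_ms,
                                              1, "exc"), timebase)
  amax <- stats::runif(n_diodes, 800, 1200)
  clean_frac <- amplitude_fraction * outer(spatial, tkern)
  lapply(seq_len(n_repeats), function(r) {
    noise <- if (noise_sd_fraction > 0)
      matrix(stats::rnorm(n_diodes * timebase$n_samples, 0,
                          noise_sd_fraction),
             n_diodes) else 0
    diode_array((clean_frac + noise) * amax, amax, coords, timebase,
                gain = 500)
  })
}

#' Simulate a population of cells with known summation factors
#'
#' Generates per-cell trace triplets (AiP, LA, DUO) for a chosen conductance
#' kind, with biological variability: kernel peaks jittered log-normally
#' (25% coefficient of variation), latencies jittered with Gaussian SD
#' 0.5 ms, and each cell's true scale factor drawn from
#' `N(alpha_mean, alpha_sd)` (truncated at 0). The ground-truth factors are
#' returned alongside the traces, so recovery by [fit_scale_factor()] can be
#' scored.
#'
#' @param n_cells number of cells (>= 2).
#' @param alpha_mean,alpha_sd distribution of the true scale factor;
#'   defaults 0.77 and 0.1786 (the excitatory-summation population).
#' @param kind `"exc"` or `"inh"` conductance traces.
#' @param timebase analysis grid, default 0.1 ms over -100..100 ms.
#' @param noise_sd_nS additive Gaussian noise on each trace (nS), default 0.
#' @param seed RNG seed.
#' @return List: `cells` (each `list(aip, la, duo)` numeric traces),
#'   `true_alpha` (numeric vector), `timebase`.
#' @export
population_scenario <- function(n_cells, alpha_mean = 0.77,
                                alpha_sd = 0.1786, kind = c("exc", "inh"),
                                timebase = NULL,
                                noise_sd_nS = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (is.null(timebase)) timebase <- timebase(-100, 0.1, 2000)
  if (n_cells < 2L) stop("need n_cells >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  base_aip <- default_kernels("AiP")[[kind]]
  base_la <- default_kernels("LA")[[kind]]
  jitter_kernel <- function(k) {
    conductance_kernel(max(0, k$latency_ms + stats::rnorm(1, 0, 0.5)),
                       k$tau_rise_ms, k$tau_decay_ms,
                       k$peak_nS * stats::rlnorm(1, -0.25^2 / 2, 0.25),
                       k$kind)
  }
  true_alpha <- pmax(0, stats::rnorm(n_cells, alpha_mean, alpha_sd))
  cells <- lapply(seq_len(n_cells), function(i) {
    aip <- kernel_waveform(jitter_kernel(base_aip), timebase)
    la <- kernel_waveform(jitter_kernel(base_la), timebase)
    duo <- make_duo(aip, la, true_alpha[i])
    if (noise_sd_nS > 0) {
      n <- timebase$n_samples
      aip <- aip + stats::rnorm(n, 0, noise_sd_nS)
      la <- la + stats::rnorm(n, 0, noise_sd_nS)
      duo <- duo + stats::rnorm(n, 0, noise_sd_nS)
    }
    list(aip = aip, la = la, duo = duo)
  })
  list(cells = cells, true_alpha = true_alpha, timebase = timebase)
}
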