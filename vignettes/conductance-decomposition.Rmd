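---
title: "Decomposing and summating stimulus-evoked synaptic conductances"
author: "eidecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing and summating stimulus-evoked synaptic conductances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eidecomp)
```

This vignette explains the models and procedures the package implements,
the assumptions behind them, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the methods literature leaves the design
open.

## The decomposition model

A neuron receiving a stimulus-evoked mixture of glutamatergic excitation
and GABA~A~ inhibition is voltage-clamped at several holding potentials
$V_h$ while the same (voltage-independent) synaptic conductance is evoked.
After subtraction of the stimulus-independent background current, the
membrane current at each instant is

$$I_m(t) = G_\mathrm{exc}(t)\,(V_m - E_\mathrm{exc}) +
           G_\mathrm{inh}(t)\,(V_m - E_\mathrm{inh})
         = a(t)\,V_m + b(t),$$

a linear I/V relation whose slope $a(t)$ is the total synaptic conductance
and whose intercept $b(t)$ encodes the balance of the two reversal
potentials. `fit_iv()` estimates $a(t)$, $b(t)$ by unweighted ordinary
least squares across holding potentials, independently at every timepoint;
`decompose_conductance()` then inverts

$$G_\mathrm{inh}(t) = \frac{b(t) + a(t) E_\mathrm{exc}}
                            {E_\mathrm{exc} - E_\mathrm{inh}}, \qquad
  G_\mathrm{exc}(t) = a(t) - G_\mathrm{inh}(t).$$

`ei_decompose()` wraps the chain (baseline subtraction, repeat averaging,
regression, inversion) into one fitting function returning a classed model
object with the usual `print`/`summary`/`coef`/`predict`/`residuals`/
`plot` methods.

Key assumptions, inherited from the experimental design:

* **Ideal clamp.** $V_m \equiv V_h$; series-resistance and space-clamp
  errors are not modelled (the generator makes the same idealisation).
* **Fixed reversals.** $E_\mathrm{exc} = 0$ mV, $E_\mathrm{inh} = -70$ mV
  (chloride), time-invariant. Both are configurable via
  `reversal_potentials()`.
* **Linearity.** The method is only valid for cells with a linear I/V
  relation. The fit records per-timepoint $r^2$ and a QC statistic: the
  median $r^2$ over response-carrying timepoints (those where the total
  conductance exceeds 10% of its in-window peak), compared with
  `qc_r2_min = 0.9`. The restriction matters: timepoints without a
  response contain only recording noise, whose $r^2$ says nothing about
  I/V linearity, and a median over the full 100 ms window would flag
  perfectly linear cells.

Units are fixed as mV, pA, nS and ms so that nS × mV = pA exactly and no
conversion constants appear in the arithmetic. Where currents are constant
across potentials the flat line fits perfectly and $r^2 = 1$ by
convention. Negative conductance estimates (possible under noise) are
reported as-is by default because clipping destroys the linearity of the
estimator; `clip_negative = TRUE` zeroes them and records a flag.

The excitability ratio
$E_\mathrm{ratio}(t) = (G_\mathrm{exc} + G_m)/(G_\mathrm{inh} + G_m)$
uses the leak conductance $G_m$ (from `measure_gm()`, the steady-state
current change per voltage step) in both numerator and denominator; this
prevents division by zero outside the response and anchors the ratio at 1
when no synaptic input is active. $E_\mathrm{ratio} > 1$ exactly where
$G_\mathrm{exc} > G_\mathrm{inh}$.

## The summation fit

`fit_scale_factor()` quantifies how two converging inputs combine: the
DUO response is fitted by $\alpha\,(\mathrm{AiP} + \mathrm{LA})$ with a
single non-negative coefficient,

$$\hat\alpha = \arg\min_{\alpha \ge 0}
  \sum_t w(t)^2 \left(d(t) - \alpha\, s(t)\right)^2,
  \qquad w(t) = e^{-t/\tau},\ \tau = 20\ \mathrm{ms},$$

which has the closed form
$\hat\alpha = \max\!\left(0, \sum w^2 s d \big/ \sum w^2 s^2\right)$ — the
one-dimensional non-negative least-squares solution, verified in the test
suite against a dense grid search. Design choices here were genuinely
open:

* **How the weight enters.** "Weighted by an exponential curve" admits
  $w$ on residuals or on squared residuals. The package uses standard
  weighted least squares (per-point weight $w$, i.e. $w^2$ on the squared
  residual). This is documented precisely so results are reproducible;
  for exact scalings the two conventions agree, and for the noise levels
  tested the difference is far below the reported precision.
* **Fit window.** Default `[0, 100]` ms — the full analysis window. The
  emphasis on the first 40 ms is produced by the exponential decay
  itself ($w(40) = e^{-2} \approx 0.14$), not by a hard cutoff; the
  window is configurable (e.g. `[0, 40]`) for sensitivity analyses.
* **Non-negativity.** The classic implementation routine is a
  non-negative solver, so `nonnegative = TRUE` is the default; the
  unconstrained solution is available for diagnostics.

`classify_summation()` maps $\alpha$ to sub-linear/linear/super-linear
with a zero tolerance by default; population-level judgements use the
one-sample Z test against 1 instead of a per-cell tolerance.
`population_scale_summary()` reports mean, SEM ($s/\sqrt n$, $n-1$
denominator), SD and Fisher–Pearson skewness.

## Detection

`detect_response()` implements the 8 × baseline-SD rule: the onset is the
first post-stimulus sample within 30 ms whose deviation from the baseline
mean exceeds `k_sd` baseline SDs, and the peak is the extremum in the
crossing polarity. Defaults resolve what the rule leaves open:

* **Polarity** is two-sided (`|deviation|`), covering inward currents at
  −70 mV (negative) and PSPs (positive); one-sided modes are available.
* **Stimulus artifact**: the first 0.5 ms after the stimulus are blanked.
* **Baseline window**: the 100 ms before the stimulus, half-open
  $[-100, 0)$ so the stimulus sample itself never contaminates the
  baseline.

`detect_spikes()` is a prominence-based local-maximum detector in the
style of the classic `peakdet` routine (default prominence 20 mV, minimum
peak −10 mV — sensible for rendered action potentials; the original
analysis names no delta parameter). `spike_density()` pools spike trains
into 1 ms bins.

## VSD processing

The diode-array chain (`vsd_process()`) applies, in order: normalisation
of each diode's ΔA(t) by its absolute light level Amax; averaging of at
least three artifact-free repeats; subtraction of the per-diode mean over
the 100 ms pre-stimulus window; spatial filtering; temporal filtering.
Every step is linear, so the chain is linear in the input frames — a
property the tests assert to 1e−10.

* **Spatial filter.** "Kernel width of one inter-diode distance
  (~150 µm)" is read as $\sigma = 150$ µm (not FWHM). The filter is a
  distance-based Gaussian kernel evaluated on the true (hexagonally
  packed, irregular) diode positions with weights normalised per target
  diode — this preserves spatially constant frames exactly and avoids
  the interpolation artifacts of resampling onto a grid.
* **Temporal filter.** 5 ms centred running average with truncated
  (shrinking) windows at the edges, preserving DC.
* **ROI quantification.** `roi_response()` averages the masked diodes and
  takes the peak of the *first positive deflection* after the stimulus;
  the undershoot that follows is excluded by construction. With noisy
  data, "first positive run" would latch onto sub-noise wiggles, so a
  run only counts as the response if its maximum exceeds `min_snr = 5`
  pre-stimulus SDs of the ROI trace (noise-free data fall back to the
  literal first run).
* The 0.2 Hz acquisition high-pass is treated as already applied to
  input data.

## The synthetic-data generator

The generator produces every input the pipeline consumes, under the study
conditions the analysis assumes:

* **Kernels** (`conductance_kernel()`, `default_kernels()`): monophasic
  difference-of-exponentials transients normalised to their peak. The
  default peaks and latencies are the reported single-pathway values
  (AiP: 2.94 nS at 5.95 ms excitatory, 8.89 nS at 7.67 ms inhibitory;
  LA: 0.75 nS at 5.55 ms, 3.22 nS at 6.72 ms). Rise/decay constants
  (1 / 10 ms) are generator conventions — the source reports no kinetics
  — and are stated as such.
* **Voltage clamp** (`simulate_voltage_clamp()`): the decomposition
  equations run forward under an ideal clamp, plus the leak current
  $G_m (V_h - E_\mathrm{rest})$ and iid Gaussian current noise
  (default 10 pA). Five potentials (−90…−50 mV), three repeats.
* **Membrane** (`membrane_model()`): passive parameters from the
  measured intrinsic properties (principal cells: 111 MΩ, −62.8 mV rest,
  −37.3 mV threshold, 21.4 pF; PV interneurons: 104 MΩ, −65.9 mV,
  −36.1 mV, 14.3 pF). The LIF reset potential is not reported; it is set
  to threshold minus the afterhyperpolarisation amplitude (−45.6 mV
  principal, −67.2 mV PV), with a 2 ms refractory period.
* **Current clamp** (`simulate_current_clamp()`): forward-Euler
  integration of the conductance-driven leaky integrate-and-fire
  equation at 0.01 ms (stability requires
  $\mathrm{d}t \le 0.1\,\tau_m$; $\tau_m \approx 2.4$ ms principal,
  1.5 ms PV). Spikes are logged internally (the ground truth for
  detector tests) and rendered as stylised +20 mV peaks in the returned
  trace. For the latency-shift scenario the PV cell is driven by
  excitatory kernels of 15 nS (AiP) and 5 nS (LA): the minimum sustained
  conductance that reaches threshold in the PV model is 7.9 nS, so the
  AiP input alone is supra-threshold and the LA input alone is not,
  matching the reported spike counts qualitatively. AiP and DUO runs
  share the noise seed, mirroring a within-cell comparison.
* **DUO construction** (`make_duo()`): $\alpha_0 (\mathrm{AiP} +
  \mathrm{LA})$ with a known ground-truth factor, optionally passed
  through a saturating `tanh` distortion for robustness experiments.
* **Diode array** (`simulate_vsd()`): 464 hexagonally packed diodes at
  150 µm pitch, 1 kHz sampling, a Gaussian-profile activation wave of
  known fractional amplitude (default 0.0741) with
  difference-of-exponentials time course, per-diode Amax drawn uniformly,
  frames returned un-normalised so the normalisation step is exercised.
  The wave's spatial SD defaults to 900 µm: the activated deep-layer
  region spans well over a millimetre, and a wave of SD $\sigma$ passed
  through the $\sigma_f = 150$ µm spatial filter retains the fraction
  $\sigma^2/(\sigma^2 + \sigma_f^2)$ of its centre amplitude — 97% at
  900 µm, so the full chain can recover the set amplitude faithfully.
* **Populations** (`population_scenario()`): per-cell kernel jitter
  (log-normal peaks, CV 25%; Gaussian latency jitter, SD 0.5 ms) and
  true $\alpha$ drawn from a stated normal distribution (defaults
  0.77 ± 0.1786, the excitatory-summation population), truncated at 0.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real recordings: series-resistance and
space-clamp errors, voltage-dependent (NMDA) conductances, synaptic
failures and trial-to-trial amplitude variability beyond additive
Gaussian noise, correlated (1/f) recording noise, dye bleaching, and
optical point spread. The recovery results bound estimator error under
the model's own assumptions, not instrument error.

## Statistics

`one_sample_z_test()` tests a summary-level mean against a null value
using the sample SD (that is what the printed "SD" denotes, consistent
with SEM × √n). Two caveats are deliberate:

* The test is asymptotic. With the sample SD plugged in, the exact null
  rejection rate at level 0.05 is $P(|t_{n-1}| > 1.96)$ — about 0.066 at
  $n = 18$ — so the package's calibration check runs at $n = 100$, where
  the normal approximation holds (0.053). Small-sample users should
  prefer `ei_t_test()`.
* `pearson_skewness()` defaults to the Fisher–Pearson moment coefficient
  $g_1 = m_3 / m_2^{3/2}$ (population moments); the printed coefficients
  are small and name no variant, so the median-based second coefficient
  is available via `type = "median"`.

`ei_t_test()` delegates to the classic Student forms (pooled variance for
two samples), with explicit conventions for degenerate input (identical
paired samples: $t = 0, p = 1$; constant nonzero difference: $p = 0$ with
a degenerate flag). `pointwise_comparison()` runs an uncorrected paired t
test per timepoint and returns the $p < 0.05$ mask, exactly as the figure
conventions it mirrors — users should treat the mask as descriptive, not
as a family-wise inference.

## Pipeline, sizes and reproducibility

`run_pipeline()` validates its configuration (including
$E_\mathrm{exc} \ne E_\mathrm{inh}$) before any stage runs, seeds all
randomness from one integer, and records an MD5 hash of the canonical
JSON form of the configuration in every artifact; identical configuration
and seed reproduce the bundle bit for bit.

Problem sizes used by the test suite and the acceptance script — chosen
as the package's own precision/runtime trade-off: decomposition recovery
uses 100 seeds of 2000-sample sweep sets (five potentials, three
repeats); scale-factor recovery 100 seeds per $\alpha$, and population
recovery the median over 20 populations of the study's cell counts
(18 or 28); the LIF comparison 100 paired runs; the detector
false-positive rate 1000 seeds; the Z-test calibration $10^4$ null
replicates. The whole suite runs in well under a minute on one core.

## Known limitations

* The decomposition inherits every limitation of the ideal-clamp,
  two-conductance, fixed-reversal model; cells failing the linearity QC
  should not be decomposed.
* The scale-factor model forces one coefficient for both pathways; a
  differential fit (separate AiP and LA coefficients) is out of scope.
* On-disk support covers the package's own CSV/HDF5 schemas, not vendor
  acquisition formats.
* The LIF neuron is a stand-in for spike-latency logic, not a
  biophysical model of PV interneurons.
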