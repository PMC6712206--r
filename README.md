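# eidecomp

Analysis of how converging synaptic inputs summate in cortical neurons,
built around whole-cell voltage-clamp conductance decomposition.

When two afferent pathways (here a neocortical and an amygdalar input onto
deep-layer perirhinal/entorhinal neurons) are stimulated individually and
then simultaneously ("DUO"), three questions recur:

1. How much excitation and inhibition does each input recruit over time?
2. Does the simultaneous response equal, exceed, or fall short of the sum
   of the individual responses?
3. Does the summed drive move spike output earlier?

`eidecomp` implements the full analysis chain for these questions —
conductance decomposition, scale-factor summation fitting, response/spike
detection, photodiode-array voltage-sensitive dye (VSD) processing, the
accompanying statistics — together with a seeded synthetic-data generator
that produces every input the chain consumes, so the whole pipeline is
testable end to end without raw recordings.

## The model

**Conductance decomposition.** With the membrane clamped at several holding
potentials `V_h` (−90 … −50 mV) while the same stimulus-evoked synaptic
conductance is elicited, the background-subtracted current at each instant
is linear in voltage:

    I_m(t) = G_exc(t) (V_m − E_exc) + G_inh(t) (V_m − E_inh)
           = a(t) V_m + b(t)

Ordinary least squares across holding potentials, independently at each
timepoint, gives the slope `a(t)` (total synaptic conductance) and
intercept `b(t)`, from which

    G_inh(t) = (b(t) + a(t) E_exc) / (E_exc − E_inh)
    G_exc(t) = a(t) − G_inh(t)

with `E_exc = 0 mV`, `E_inh = −70 mV`. The leak-regularised balance is the
excitability ratio `E_ratio(t) = (G_exc + G_m) / (G_inh + G_m)`, where
`G_m` is the passive membrane conductance (inverse input resistance).

**Summation scale factor.** The DUO response is fitted by the arithmetic
sum of the single-pathway responses with a single non-negative coefficient,

    DUO(t) ≈ α (AiP(t) + LA(t)),

minimising exponentially weighted squared residuals (`w(t) = e^(−t/20 ms)`,
so the first ~40 ms dominate). `α < 1` is sub-linear summation, `α = 1`
linear, `α > 1` super-linear. Populations of per-cell `α` are summarised as
mean ± SEM and tested against 1 with a one-sample Z test.

**Detection.** A response onset is the first post-stimulus crossing of
8 × the pre-stimulus SD within 30 ms; spikes are local maxima with a
prominence criterion, as in the classic `peakdet` routine.

**VSD processing.** Diode-array absorbance signals are normalised to the
per-diode light level (ΔA/Amax), offset-subtracted over 100 ms
pre-stimulus, filtered in space (2-D Gaussian on the true diode positions,
σ = 150 µm) and time (5 ms running average), averaged over ≥ 3 repeats and
quantified as the peak of the first positive deflection over a region of
interest.

## Worked example

Simulate an ideal voltage-clamp experiment from the default excitatory
(peak 2.94 nS, latency 5.95 ms) and inhibitory (8.89 nS, 7.67 ms) kernels
with 10 pA recording noise, three repeats, five holding potentials, and
decompose it:

```r
library(eidecomp)
tb <- timebase(-100, 0.1, 2000)          # 0.1 ms grid, stimulus at t = 0
k  <- default_kernels("AiP")
ss <- simulate_voltage_clamp(kernel_waveform(k$exc, tb),
                             kernel_waveform(k$inh, tb),
                             tb, noise_sd_pA = 10, n_repeats = 3, seed = 1)
fit <- ei_decompose(ss)
fit
#> Conductance decomposition (AIP, 5 holding potentials)
#>   window [0, 100] ms, E_exc = 0 mV, E_inh = -70 mV
#>   peak G_exc 2.97 nS at 8.9 ms; peak G_inh 9.05 nS at 10.3 ms
#>   I/V linearity: median r2 = 0.9949 (QC pass at 0.90)
```

The recovered peaks (2.97 / 9.05 nS) sit within noise of the generating
kernels (2.94 / 8.89 nS), and the near-unity r² confirms the linear I/V
relation the method assumes. Summation fitting on a DUO trace constructed
with a known factor of 0.77:

```r
a <- kernel_waveform(k$exc, tb)
l <- kernel_waveform(default_kernels("LA")$exc, tb)
fit_scale_factor(make_duo(a, l, 0.77), a, l, timebase = tb)
#> Summation fit: alpha = 0.7700 (sublinear), weighted RSS = 0, 1000 points, tau = 20 ms

one_sample_z_test(0.77, 0.1786, 18)      # population test against alpha = 1
#> one-sample Z test: statistic = -5.464, p = 4.665e-08 (n = 18)
```

`run_pipeline(pipeline_config(...))` chains everything — synthetic
population, decomposition, summation, detection, population statistics —
into a reproducible bundle with per-cell CSV/JSON artifacts and a
markdown report (`make_report()`).

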