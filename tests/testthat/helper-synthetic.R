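# shared fixtures built in code

tb_std <- function() timebase(-100, 0.1, 2000)   # -100..99.9 ms, 0.1 ms

aip_traces <- function(tb = tb_std()) {
  k <- default_kernels("AiP")
  list(exc = kernel_waveform(k$exc, tb), inh = kernel_waveform(k$inh, tb))
}

la_traces <- function(tb = tb_std()) {
  k <- default_kernels("LA")
  list(exc = kernel_waveform(k$exc, tb), inh = kernel_waveform(k$inh, tb))
}

# noise-free ideal-clamp sweepset from given conductance traces
clean_sweepset <- function(gexc, ginh, tb = tb_std(),
                           potentials = seq(-90, -50, by = 10), ...) {
  simulate_voltage_clamp(gexc, ginh, tb, potentials_mV = potentials,
                         noise_sd_pA = 0, n_repeats = 1, ...)
}
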