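test_that("kernel waveforms are normalised, causal and peak where predicted", {
  tb <- timebase(-20, 0.01, 20000)
  t <- tb_times(tb)
  zero <- kernel_waveform(conductance_kernel(5, 1, 10, 0, "exc"), tb)
  expect_equal(zero, rep(0, 20000))
  for (pars in list(c(5.95, 1, 10, 2.94), c(7.67, 1, 10, 8.89),
                    c(3, 0.5, 25, 1.7))) {
    k <- conductance_kernel(pars[1], pars[2], pars[3], pars[4], "exc")
    g <- kernel_waveform(k, tb)
    expect_lt(abs(max(g) - k$peak_nS), 1e-9 + 1e-6 * k$peak_nS)
    expect_true(all(g[t < k$latency_ms] == 0))
    # closed-form argmax of the difference of exponentials
    tpk <- k$latency_ms + pars[2] * pars[3] / (pars[3] - pars[2]) *
      log(pars[3] / pars[2])
    expect_lt(abs(t[which.max(g)] - tpk), tb$dt_ms)
  }
  expect_error(conductance_kernel(5, 10, 1, 2, "exc"), "tau")
  expect_error(conductance_kernel(5, 1, 10, -2, "exc"), "peak")
})

test_that("the ideal clamp produces the leak current and is seed-stable", {
  tb <- timebase(-100, 0.1, 2000)
  z <- rep(0, 2000)
  ss <- simulate_voltage_clamp(z, z, tb, potentials_mV = c(-70, -50),
                               noise_sd_pA = 0, n_repeats = 1)
  i70 <- ss$sweeps[[which(vapply(ss$sweeps, function(s)
    s$holding_potential_mV, numeric(1)) == -70)]]
  # G_m (V_h - E_rest) = 9.009 * (-7.2) = -64.86 pA at -70 mV
  expect_equal(i70$values, rep((1000 / 111) * (-70 + 62.8), 2000))
  g <- aip_traces(tb)
  s1 <- simulate_voltage_clamp(g$exc, g$inh, tb, seed = 77)
  s2 <- simulate_voltage_clamp(g$exc, g$inh, tb, seed = 77)
  for (i in seq_along(s1$sweeps))
    expect_identical(s1$sweeps[[i]]$values, s2$sweeps[[i]]$values)
  expect_error(simulate_voltage_clamp(g$exc, g$inh, tb,
                                      potentials_mV = -70), "2 distinct")
})

test_that("simulated sweep sets decompose back to the generating kernels", {
  tb <- tb_std()
  for (pw in c("AiP", "LA")) {
    k <- default_kernels(pw)
    ge <- kernel_waveform(k$exc, tb); gi <- kernel_waveform(k$inh, tb)
    fit <- ei_decompose(simulate_voltage_clamp(ge, gi, tb,
                                               noise_sd_pA = 0,
                                               n_repeats = 1))
    expect_lt(max(abs(fit$conductances$G_exc_nS - ge)), 1e-9)
    expect_lt(max(abs(fit$conductances$G_inh_nS - gi)), 1e-9)
  }
})

test_that("the LIF neuron rests, spikes above threshold, and is stable", {
  tb <- timebase(-10, 0.01, 6000)          # -10..49.99 ms
  n <- tb$n_samples
  m <- membrane_model()
  quiet <- simulate_current_clamp(numeric(n), numeric(n), tb, membrane = m)
  expect_equal(quiet$voltage$values, rep(m$E_rest_mV, n))
  expect_equal(quiet$spikes$count, 0L)
  # sustained g_exc with steady state above threshold must spike:
  # V_inf = G_m E_rest / (G_m + g) (E_exc = 0); threshold crossing needs
  # g > G_m (E_rest - V_thresh) / V_thresh
  g_crit <- m$G_m_nS * (m$E_rest_mV - m$V_thresh_mV) / m$V_thresh_mV
  g_on <- rep(1.5 * g_crit, n)
  sup <- simulate_current_clamp(g_on, numeric(n), tb, membrane = m)
  expect_gte(sup$spikes$count, 1L)
  sub <- simulate_current_clamp(rep(0.5 * g_crit, n), numeric(n), tb,
                                membrane = m)
  expect_equal(sub$spikes$count, 0L)
  # too-coarse integration grid is refused
  tbc <- timebase(0, 1, 100)
  expect_error(simulate_current_clamp(numeric(100), numeric(100), tbc,
                                      membrane = m), "stability")
})

test_that("DUO construction and recovery of the true scale factor", {
  tb <- tb_std()
  a <- aip_traces(tb); l <- la_traces(tb)
  duo1 <- make_duo(a$exc, l$exc, 1)
  expect_equal(duo1, a$exc + l$exc)
  expect_equal(make_duo(a$exc, l$exc, 0), rep(0, 2000))
  # list form combines element-wise
  duoL <- make_duo(a, l, 0.77)
  expect_equal(duoL$inh, 0.77 * (a$inh + l$inh))
  # noise-free recovery of the generating alpha
  for (al in c(0.5, 0.77, 0.94, 1.0, 1.2)) {
    f <- fit_scale_factor(make_duo(a$exc, l$exc, al), a$exc, l$exc,
                          timebase = tb)
    expect_lt(abs(f$alpha - al), 0.01)
  }
  # saturating distortion compresses large responses
  sat <- make_duo(a$inh, l$inh, 1, saturation = 5)
  expect_lt(max(sat), max(a$inh + l$inh))
})

test_that("summed drive never delays the first LIF spike", {
  tb <- timebase(-10, 0.01, 6000)
  n <- tb$n_samples
  m <- membrane_model_pv()
  g_aip <- kernel_waveform(conductance_kernel(5.95, 1, 10, 15, "exc"), tb)
  g_la <- kernel_waveform(conductance_kernel(5.55, 1, 10, 5, "exc"), tb)
  for (s in 1:20) {
    aip <- simulate_current_clamp(g_aip, numeric(n), tb, membrane = m,
                                  noise_sd_pA = 20, seed = s)
    duo <- simulate_current_clamp(g_aip + g_la, numeric(n), tb,
                                  membrane = m, noise_sd_pA = 20, seed = s)
    expect_gte(aip$spikes$count, 1L)
    expect_lte(first_spike_latency(duo$spikes),
               first_spike_latency(aip$spikes))
  }
  # scaling both kernels up can only advance the first spike
  base <- simulate_current_clamp(g_aip, numeric(n), tb, membrane = m)
  for (c_scale in c(1.2, 1.5, 2)) {
    up <- simulate_current_clamp(c_scale * g_aip, numeric(n), tb,
                                 membrane = m)
    expect_lte(first_spike_latency(up$spikes),
               first_spike_latency(base$spikes))
  }
})

test_that("the diode-array generator is seeded and zero-amplitude is noise", {
  r1 <- simulate_vsd(n_diodes = 40, n_repeats = 2, seed = 5)
  r2 <- simulate_vsd(n_diodes = 40, n_repeats = 2, seed = 5)
  expect_identical(r1[[1]]$frames, r2[[1]]$frames)
  expect_identical(r1[[2]]$frames, r2[[2]]$frames)
  expect_false(identical(r1[[1]]$frames, r1[[2]]$frames))
  r0 <- simulate_vsd(n_diodes = 40, amplitude_fraction = 0,
                     noise_sd_fraction = 0.01, n_repeats = 1, seed = 5)
  expect_lt(abs(mean(r0[[1]]$frames / r0[[1]]$amax)), 1e-3)
  # geometry: hexagonal packing at the requested pitch
  d <- as.matrix(dist(r1[[1]]$coords_um))
  diag(d) <- Inf
  expect_equal(min(d), 150, tolerance = 1e-9)
})

test_that("population scenarios return recoverable ground truth", {
  sc <- population_scenario(6, alpha_mean = 0.8, alpha_sd = 0, seed = 31)
  sc2 <- population_scenario(6, alpha_mean = 0.8, alpha_sd = 0, seed = 31)
  expect_identical(sc$true_alpha, sc2$true_alpha)
  expect_identical(sc$cells[[3]]$duo, sc2$cells[[3]]$duo)
  expect_true(all(sc$true_alpha == 0.8))
  alphas <- vapply(seq_along(sc$cells), function(i)
    fit_scale_factor(sc$cells[[i]]$duo, sc$cells[[i]]$aip,
                     sc$cells[[i]]$la, timebase = sc$timebase)$alpha,
    numeric(1))
  s <- population_scale_summary(alphas)
  expect_lt(s$sem, 1e-9)                  # noise-free, sd = 0 scenario
  expect_equal(s$mean, 0.8, tolerance = 1e-9)
})
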