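test_that("the per-timepoint I/V regression recovers hand-computed slopes", {
  # G_exc = 2 nS, G_inh = 8 nS, E_exc = 0, E_inh = -70:
  # I(-90) = 2*(-90) + 8*(-20) = -340 pA; I(-50) = 2*(-50) + 8*20 = 60 pA
  # => a = 400/40 = 10 nS, b = 60 - 10*(-50) = 560 pA
  tb <- timebase(0, 1, 10)
  ss <- ei_sweepset(list(ei_sweep(rep(-340, 10), tb, -90, "AIP"),
                         ei_sweep(rep(60, 10), tb, -50, "AIP")))
  iv <- fit_iv(ss)
  expect_equal(iv$a_nS, rep(10, 10))
  expect_equal(iv$b_pA, rep(560, 10))
  ct <- decompose_conductance(iv)
  expect_equal(ct$G_inh_nS, rep(8, 10))    # 560/70
  expect_equal(ct$G_exc_nS, rep(2, 10))
  # any >= 2 of 5 exact potentials give the identical line, r2 = 1
  ss5 <- ei_sweepset(lapply(seq(-90, -50, 10), function(v)
    ei_sweep(rep(2 * v + 8 * (v + 70), 10), tb, v, "AIP")))
  iv5 <- fit_iv(ss5)
  expect_equal(iv5$a_nS, rep(10, 10))
  expect_equal(iv5$b_pA, rep(560, 10))
  expect_equal(iv5$r2, rep(1, 10))
})

test_that("null input gives a zero fit and zero conductances", {
  tb <- timebase(0, 1, 50)
  ss <- ei_sweepset(lapply(c(-90, -70, -50), function(v)
    ei_sweep(rep(0, 50), tb, v, "AIP")))
  iv <- fit_iv(ss)
  expect_equal(iv$a_nS, rep(0, 50))
  expect_equal(iv$b_pA, rep(0, 50))
  expect_equal(iv$r2, rep(1, 50))          # flat-line convention
  ct <- decompose_conductance(iv)
  expect_equal(ct$G_exc_nS, rep(0, 50))
  expect_equal(ct$G_inh_nS, rep(0, 50))
})

test_that("vectorized I/V regression matches lm() per timepoint", {
  tb <- timebase(0, 0.1, 30)
  set.seed(5)
  V <- seq(-90, -50, 10)
  I <- matrix(rnorm(30 * 5, sd = 50), 30, 5)
  ss <- ei_sweepset(lapply(seq_along(V), function(j)
    ei_sweep(I[, j], tb, V[j], "AIP")))
  iv <- fit_iv(ss)
  for (k in c(1, 13, 30)) {
    ref <- lm(I[k, ] ~ V)
    expect_equal(iv$a_nS[k], unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(iv$b_pA[k], unname(coef(ref)[1]), tolerance = 1e-10)
    expect_equal(iv$r2[k], summary(ref)$r.squared, tolerance = 1e-10)
  }
})

test_that("noise-free decomposition is exact for every >= 2-potential subset", {
  tb <- tb_std()
  g <- aip_traces(tb)
  pots <- seq(-90, -50, 10)
  subsets <- c(utils::combn(pots, 2, simplify = FALSE),
               utils::combn(pots, 3, simplify = FALSE),
               list(pots))
  for (p in subsets) {
    fit <- ei_decompose(clean_sweepset(g$exc, g$inh, tb, potentials = p))
    expect_lt(max(abs(fit$conductances$G_exc_nS - g$exc)), 1e-9)
    expect_lt(max(abs(fit$conductances$G_inh_nS - g$inh)), 1e-9)
  }
})

test_that("decomposition is linear and a(t) = G_exc + G_inh holds", {
  tb <- tb_std()
  a <- aip_traces(tb); l <- la_traces(tb)
  dec <- function(e, i) {
    f <- ei_decompose(clean_sweepset(e, i, tb))
    f$conductances
  }
  f1 <- dec(a$exc, a$inh); f2 <- dec(l$exc, l$inh)
  fsum <- dec(a$exc + l$exc, a$inh + l$inh)
  expect_equal(fsum$G_exc_nS, f1$G_exc_nS + f2$G_exc_nS, tolerance = 1e-9)
  expect_equal(fsum$G_inh_nS, f1$G_inh_nS + f2$G_inh_nS, tolerance = 1e-9)
  iv <- fit_iv(average_repeats(subtract_background(
    clean_sweepset(a$exc, a$inh, tb))))
  ct <- decompose_conductance(iv)
  expect_equal(iv$a_nS, ct$G_exc_nS + ct$G_inh_nS, tolerance = 1e-12)
})

test_that("clipping reports the flag and never yields negative conductances", {
  tb <- timebase(0, 1, 20)
  iv <- fit_iv(ei_sweepset(list(ei_sweep(rep(100, 20), tb, -90, "AIP"),
                                ei_sweep(rep(-100, 20), tb, -50, "AIP"))))
  ct <- decompose_conductance(iv, clip_negative = TRUE)
  expect_true(ct$clipped)
  expect_true(all(ct$G_exc_nS >= 0) && all(ct$G_inh_nS >= 0))
})

test_that("decomposition errors on bad inputs", {
  tb <- timebase(0, 1, 10)
  one <- ei_sweepset(list(ei_sweep(rep(1, 10), tb, -70, "AIP")))
  expect_error(fit_iv(one), "2 distinct")
  expect_error(ei_decompose(one), "2 distinct")
  expect_error(reversal_potentials(-70, -70), "differ")
})

test_that("measure_gm converts a voltage step to the leak conductance", {
  # R_m = 111 MOhm => G_m = 1000/111 = 9.009 nS; -10 mV step settles to
  # delta-I = G_m * (-10) pA with tau_m kinetics
  tb <- timebase(-100, 0.1, 2000)
  t <- tb_times(tb)
  for (R in c(111, 104)) {
    gm_true <- 1000 / R
    tau <- R * 21.4 / 1000
    dI <- gm_true * (-10) * (1 - exp(-pmax(t, 0) / tau)) * (t >= 0)
    s <- ei_sweep(-64.8 + dI, tb, -70, "STEP")
    expect_lt(abs(measure_gm(s, -10) - gm_true) / gm_true, 0.01)
  }
  flat <- ei_sweep(rep(-64.8, 2000), tb, -70, "STEP")
  expect_equal(measure_gm(flat, -10), 0)
  expect_error(measure_gm(flat, 0), "nonzero")
})

test_that("excitability ratio behaves as the leak-regularised E/I balance", {
  tb <- timebase(0, 1, 10)
  ct <- structure(list(G_exc_nS = rep(2, 10), G_inh_nS = rep(8, 10),
                       r2 = rep(1, 10), timebase = tb, clipped = FALSE),
                  class = "conductance_trace")
  er <- excitability_ratio(ct, 9)
  expect_equal(er$ratio, rep(11 / 17, 10))
  ct0 <- ct; ct0$G_exc_nS <- ct0$G_inh_nS <- rep(0, 10)
  expect_equal(excitability_ratio(ct0, 9)$ratio, rep(1, 10))
  ct1 <- ct; ct1$G_exc_nS <- ct1$G_inh_nS <- rep(5, 10)
  expect_equal(excitability_ratio(ct1, 9)$ratio, rep(1, 10))
  expect_error(excitability_ratio(ct, 0), "positive")
  # E_ratio > 1 exactly where G_exc > G_inh
  tb2 <- tb_std()
  g <- aip_traces(tb2)
  fit <- ei_decompose(clean_sweepset(g$exc, g$inh, tb2))
  er2 <- excitability_ratio(fit$conductances, 9)
  expect_equal(er2$ratio > 1 + 1e-12,
               fit$conductances$G_exc_nS > fit$conductances$G_inh_nS + 1e-12)
})

test_that("model methods are coherent: predict, fitted, residuals, coef", {
  tb <- tb_std()
  g <- aip_traces(tb)
  fit <- ei_decompose(clean_sweepset(g$exc, g$inh, tb))
  expect_lt(max(abs(residuals(fit))), 1e-9)     # noise-free: exact fit
  cf <- coef(fit)
  expect_equal(unname(cf["peak_G_exc_nS"]), 2.94, tolerance = 1e-4)
  expect_equal(unname(cf["peak_G_inh_nS"]), 8.89, tolerance = 1e-4)
  pr <- predict(fit, -70)
  # at E_inh the inhibitory term vanishes: current is -70 * G_exc
  expect_equal(as.numeric(pr), -70 * fit$conductances$G_exc_nS,
               tolerance = 1e-9)
  expect_output(print(fit), "peak G_exc")
  expect_output(print(summary(fit)), "QC")
})
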