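small_array <- function(n_diodes = 16, n_samples = 250, seed = 1,
                        frames = NULL) {
  set.seed(seed)
  tb <- timebase(-100, 1, n_samples)
  coords <- as.matrix(expand.grid(x = (0:3) * 150, y = (0:3) * 150))
  coords <- coords[seq_len(n_diodes), , drop = FALSE]
  amax <- runif(n_diodes, 800, 1200)
  if (is.null(frames)) frames <- matrix(rnorm(n_diodes * n_samples),
                                        n_diodes)
  diode_array(frames, amax, coords, tb)
}

test_that("normalisation divides each diode by its own Amax", {
  rec <- small_array(frames = matrix(0, 16, 250))
  expect_true(all(vsd_normalize(rec)$frames == 0))
  rec2 <- small_array()
  rec2$frames <- matrix(rec2$amax, 16, 250)   # dA == Amax per diode
  expect_equal(vsd_normalize(rec2)$frames, matrix(1, 16, 250))
  expect_error(diode_array(matrix(0, 2, 10), c(1, -1),
                           cbind(1:2, 0), timebase(0, 1, 10)),
               "positive")
})

test_that("offset subtraction zeroes the pre-stimulus mean and is linear", {
  rec <- small_array(frames = matrix(5, 16, 250))
  out <- vsd_subtract_offset(rec)
  expect_equal(out$frames, matrix(0, 16, 250))
  # already-centred input is unchanged
  f <- matrix(rnorm(16 * 250), 16)
  f <- f - rowMeans(f[, 1:100])
  recc <- small_array(frames = f)
  expect_equal(vsd_subtract_offset(recc)$frames, f, tolerance = 1e-12)
  # linearity
  fa <- matrix(rnorm(16 * 250), 16); fb <- matrix(rnorm(16 * 250), 16)
  g <- function(fr) vsd_subtract_offset(small_array(frames = fr))$frames
  expect_equal(g(fa + fb), g(fa) + g(fb), tolerance = 1e-10)
})

test_that("the spatial Gaussian filter preserves DC and matches the kernel", {
  rec <- small_array(frames = matrix(3.7, 16, 250))
  out <- vsd_spatial_filter(rec, 150)
  expect_equal(out$frames, matrix(3.7, 16, 250), tolerance = 1e-10)
  # single-diode impulse spreads with weights prop. to the Gaussian of
  # inter-diode distance, normalised per target diode (direct oracle)
  imp <- matrix(0, 16, 250); imp[5, 10] <- 1
  reci <- small_array(frames = imp)
  outi <- vsd_spatial_filter(reci, 150)
  d2 <- as.matrix(dist(reci$coords_um))^2
  W <- exp(-d2 / (2 * 150^2)); W <- W / rowSums(W)
  expect_equal(outi$frames[, 10], unname(W[, 5]), tolerance = 1e-12)
  # sigma -> 0 approaches the identity
  out0 <- vsd_spatial_filter(reci, 1e-3)
  expect_equal(out0$frames[5, 10], 1, tolerance = 1e-12)
  expect_error(vsd_spatial_filter(rec, 0), "sigma")
})

test_that("the running average is a truncated boxcar preserving DC", {
  rec <- small_array(frames = matrix(2.5, 16, 250))
  expect_equal(vsd_temporal_filter(rec, 5)$frames, matrix(2.5, 16, 250),
               tolerance = 1e-12)
  # interior unit impulse with a 5-sample window -> five samples of 0.2
  x <- rep(0, 101); x[51] <- 1
  y <- vsd_temporal_filter(x, window_ms = 5, dt_ms = 1)
  expect_equal(y[49:53], rep(0.2, 5))
  expect_equal(sum(y), 1)                     # mean/DC conservation
  # Nyquist alternation is attenuated by an odd window
  z <- rep(c(1, -1), 50)
  zf <- vsd_temporal_filter(z, window_ms = 5, dt_ms = 1)
  expect_lt(max(abs(zf[10:90])), 1)
})

test_that("ROI averaging and first-positive-deflection peak behave", {
  rec <- small_array(frames = matrix(rep(sin(seq(-1, 3, length.out = 250)),
                                         each = 16), 16))
  r_all <- roi_response(rec, 1:16)
  expect_equal(r_all$trace, rec$frames[1, ])   # identical diodes
  r_one <- roi_response(rec, 7)
  expect_equal(r_one$trace, rec$frames[7, ])
  # diode ordering is irrelevant
  r_perm <- roi_response(rec, c(9, 3, 1, 12))
  expect_equal(r_perm$trace, r_all$trace)
  expect_error(roi_response(rec, integer(0)), "empty")
  expect_error(roi_response(rec, c(1, 1)), "unique")
  # the peak is taken from the first positive deflection only
  tb <- timebase(-100, 1, 300)
  t <- tb_times(tb)
  w1 <- ifelse(t >= 5 & t < 60, sin(pi * (t - 5) / 55) * 0.07, 0)
  under <- ifelse(t >= 60 & t < 150, -0.02 * sin(pi * (t - 60) / 90), 0)
  late <- ifelse(t >= 150, 0.2 * sin(pi * (t - 150) / 100), 0)
  fr <- matrix(rep(w1 + under + late, each = 4), 4)
  rec2 <- diode_array(fr, rep(1000, 4), cbind(1:4 * 150, 0), tb)
  resp <- roi_response(rec2, 1:4)
  expect_equal(resp$peak_amplitude, max(w1), tolerance = 1e-12)
  expect_lt(resp$peak_time_ms, 60)             # not the late deflection
})

test_that("the full processing chain is linear and recovers amplitude", {
  mk <- function(amp, seed) simulate_vsd(n_diodes = 60, pitch_um = 150,
                                         amplitude_fraction = amp,
                                         noise_sd_fraction = 0,
                                         n_repeats = 3, seed = seed)
  ra <- mk(0.04, 1); rb <- mk(0.03, 1)   # same seed: same amax and layout
  chain <- function(recs) vsd_process(recs)$frames
  sum_ab <- ra
  for (i in 1:3) sum_ab[[i]]$frames <- ra[[i]]$frames + rb[[i]]$frames
  expect_equal(chain(sum_ab), chain(ra) + chain(rb), tolerance = 1e-10)
  # noise-free amplitude recovery through the whole chain
  recs <- mk(0.0741, 3)
  proc <- vsd_process(recs)
  ctr <- which.min(rowSums(proc$coords_um^2))
  resp <- roi_response(proc, ctr)
  # the spatial (sigma 150 um on a 900 um wave) and temporal (5 ms boxcar)
  # filters attenuate the true amplitude by ~3%; recovery contract is 5%
  expect_equal(resp$peak_amplitude, 0.0741, tolerance = 0.05)
  expect_error(vsd_average_repeats(recs[1:2]), ">= 3")
})
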