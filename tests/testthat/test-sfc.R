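test_that("MSC and imaginary coherence follow their closed forms", {
  C <- new_coherency_spectrum(c(1, 2, 3),
                              c(1 + 0i, 0.8 * exp(1i * 0.7), 0.5 * exp(1i * pi / 4)))
  expect_equal(msc(C)$value, c(1, 0.64, 0.25), tolerance = 1e-12)
  ic <- imaginary_coherence(C)$value
  expect_equal(ic[1], 0)
  expect_equal(ic[3], 0.5 * sin(pi / 4), tolerance = 1e-12)
  Ci <- new_coherency_spectrum(1, 1i)
  expect_equal(imaginary_coherence(Ci)$value, 1)

  # identical-signal pair end-to-end: msc = 1 wherever there is power
  set.seed(41)
  x <- rnorm(3000)
  m <- msc(complex_coherency(cross_spectra(x, x, fs = 100)))
  expect_equal(max(m$value), 1, tolerance = 1e-9)
  expect_equal(min(m$value), 1, tolerance = 1e-6)
})

test_that("wPLI arithmetic, the 0/0 convention and the lag regimes", {
  seg <- make_segments(matrix(c(3i, -1i), nrow = 1))
  expect_equal(wpli(seg)$value, 0.5)

  # zero-lag copies: all imaginary parts vanish -> defined as 0
  g0 <- gen_coupled_pair(fs = 250, duration = 30, seed = 42, freq = 10,
                         phase_lag = 0, snr = Inf)
  w0 <- wpli(cross_spectra(g0$x, g0$y, 250))
  expect_equal(w0$value[w0$freq == 10], 0)

  # consistent quarter-cycle lag: |wPLI| ~ 1 at the oscillation frequency
  g <- gen_coupled_pair(fs = 250, duration = 101, seed = 43, freq = 10,
                        phase_lag = pi / 2, snr = 10)
  seg2 <- cross_spectra(g$x, g$y, 250)
  expect_gte(seg2$n_segments, 200)
  w <- wpli(seg2)
  expect_gte(abs(w$value[w$freq == 10]), 0.9)
  expect_error(wpli(make_segments(matrix(1i, 1, 1))), "2 segments")
})

test_that("PSI sign follows the constructed delay and flips with roles", {
  g <- gen_coupled_pair(fs = 250, duration = 60, seed = 44,
                        band = c(8, 30), delay = 0.02, snr = 10)
  Cxy <- complex_coherency(cross_spectra(g$x, g$y, 250))
  p_xy <- psi(Cxy, c(8, 30))
  expect_gt(p_xy$value, 0)             # x precedes y
  Cyx <- complex_coherency(cross_spectra(g$y, g$x, 250))
  p_yx <- psi(Cyx, c(8, 30))
  expect_lt(p_yx$value, 0)
  expect_equal(p_yx$raw, -p_xy$raw, tolerance = 1e-10)

  expect_error(psi(Cxy, c(8, 8.5)), "fewer than 3")
  few <- complex_coherency(cross_spectra(g$x[1:500], g$y[1:500], 250,
                                         nperseg = 250, noverlap = 100))
  expect_error(psi(few, c(8, 30)), "at least 4 segments")
})

test_that("normalized PSI behaves like a z-score under the null", {
  inside <- 0L
  n_rep <- 100L
  for (s in seq_len(n_rep)) {
    set.seed(500 + s)
    n <- 100 * 101 / 2 + 50
    a <- rnorm(n)
    b <- rnorm(n)
    C <- complex_coherency(cross_spectra(a, b, fs = 100, nperseg = 100))
    v <- psi(C, c(8, 30))$value
    if (abs(v) <= 2) inside <- inside + 1L
  }
  expect_gte(inside / n_rep, 0.95)
})

test_that("DAC is signed band-mean coherency with a volume-conduction flag", {
  g <- gen_coupled_pair(fs = 250, duration = 60, seed = 45,
                        band = c(8, 30), delay = 0.02, snr = 10)
  d <- dac(g$x, 0.5 * g$y, 250, c(8, 30))
  expect_gt(d$value, 0)
  expect_equal(abs(d$value), d$mean_coh, tolerance = 0.1)
  expect_lte(abs(d$value), 1)
  expect_false(d$volume_conduction)

  # both sensors see one common source at zero lag
  set.seed(46)
  src <- apply_fir(rnorm(250 * 40), "bandpass", c(8, 30), 4, fs = 250)
  dz <- dac(src + rnorm(length(src), sd = 0.01),
            src + rnorm(length(src), sd = 0.01), 250, c(8, 30))
  expect_true(dz$volume_conduction)
  expect_lte(abs(dz$value), 1)
})

test_that("metric bounds and symmetries hold on randomized inputs", {
  for (s in 1:15) {
    set.seed(600 + s)
    n <- 4000
    x <- cumsum(rnorm(n))
    y <- 0.3 * x + cumsum(rnorm(n))
    seg <- cross_spectra(x, y, fs = 100, nperseg = 100)
    C <- complex_coherency(seg)
    expect_lte(max(msc(C)$value), 1 + 1e-9)
    expect_lte(max(abs(wpli(seg)$value)), 1 + 1e-12)
    expect_lte(max(abs(imaginary_coherence(C)$value)), 1 + 1e-9)
    d <- dac(x, y, 100, c(10, 30))
    expect_lte(abs(d$value), 1)
  }
  # wpli antisymmetric, msc symmetric, both scale-invariant
  set.seed(47)
  x <- rnorm(3000); y <- 0.4 * x + rnorm(3000)
  sxy <- cross_spectra(x, y, 100)
  syx <- cross_spectra(y, x, 100)
  expect_equal(wpli(syx)$value, -wpli(sxy)$value, tolerance = 1e-12)
  expect_equal(msc(complex_coherency(syx))$value,
               msc(complex_coherency(sxy))$value, tolerance = 1e-12)
  scl <- cross_spectra(5 * x, 0.1 * y, 100)
  expect_equal(wpli(scl)$value, wpli(sxy)$value, tolerance = 1e-9)
})

test_that("the sfc dispatcher routes and validates", {
  set.seed(48)
  x <- rnorm(2000); y <- rnorm(2000)
  expect_named(sfc_metric(x, y, 100, "msc"), c("freq", "metric", "value"))
  expect_equal(sfc_metric(x, y, 100, "wpli"),
               wpli(cross_spectra(x, y, 100)))
  expect_error(sfc_metric(x, y, 100, "psi"), "band")
  expect_equal(sfc_metric(x, y, 100, "dac", band = c(8, 30))$metric, "dac")
})
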