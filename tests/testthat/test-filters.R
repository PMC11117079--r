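test_that("FIR design: odd symmetric taps with the Hamming tap-count rule", {
  spec <- fir_spec("bandpass", c(8, 12), 2, fs = 250)
  cf <- design_fir(spec)
  n <- length(cf$taps)
  expect_true(n %% 2 == 1)
  expect_gte(n, 3.3 * 250 / 2)
  expect_equal(cf$taps, rev(cf$taps))          # linear phase
  expect_lt(abs(sum(cf$taps)), 1e-3)           # bandpass DC gain ~ 0

  lp <- design_fir(fir_spec("lowpass", 30, 5, fs = 250))
  expect_equal(sum(lp$taps), 1, tolerance = 1e-3)  # unit DC gain
  expect_equal(lp$taps, rev(lp$taps))
})

test_that("FIR magnitude response meets pass/stop specs", {
  cf <- design_fir(fir_spec("bandpass", c(8, 12), 2, fs = 250))
  resp <- fir_response(cf, c(10, 6, 14, 50))
  expect_gte(resp$gain[1], 0.99)       # band center
  expect_lte(resp$gain[1], 1.01)
  expect_lte(resp$gain[2], 0.01)       # one transition below the low edge
  expect_lte(resp$gain[3], 0.01)       # one transition above the high edge
  expect_lte(resp$gain[4], 0.01)

  lp <- design_fir(fir_spec("lowpass", 30, 5, fs = 250))
  expect_equal(fir_response(lp, 0)$gain, 1, tolerance = 1e-3)
  expect_gte(fir_response(lp, 15)$gain, 0.99)
  expect_lte(fir_response(lp, 40)$gain, 0.01)

  hp <- design_fir(fir_spec("highpass", 1, 0.5, fs = 100))
  expect_lte(fir_response(hp, 0)$gain, 1e-3)
  expect_gte(fir_response(hp, 10)$gain, 0.99)

  bs <- design_fir(fir_spec("bandstop", c(48, 52), 2, fs = 250))
  expect_lte(fir_response(bs, 50)$gain, 0.01)
  expect_gte(fir_response(bs, 20)$gain, 0.99)
})

test_that("invalid filter specs name the violated bound", {
  expect_error(fir_spec("lowpass", 0, 2, 100), "edge > 0")
  expect_error(fir_spec("lowpass", 60, 2, 100), "fs/2")
  expect_error(fir_spec("bandpass", c(12, 8), 2, 250), "increasing")
  expect_error(fir_spec("bandpass", c(1, 10), 2, 250), "> 0 Hz")
  expect_error(fir_spec("lowpass", 48, 5, 100), "fs/2")
  expect_error(fir_spec("bandpass", 8, 2, 250), "2 edge")
})

test_that("overlap-add equals direct convolution (the central oracle)", {
  cf <- design_fir(fir_spec("bandpass", c(8, 12), 2, fs = 250))
  set.seed(42)
  x <- rnorm(10000)
  ola <- apply_overlap_add(x, cf, mode = "precise")
  expect_length(ola, length(x))
  expect_lt(max(abs(ola - direct_filter(x, cf$taps))), 1e-9 * max(abs(x)))

  # a unit impulse reproduces the taps centered at the impulse
  imp <- numeric(2001)
  imp[1001] <- 1
  out <- apply_overlap_add(imp, cf, mode = "precise")
  m <- (length(cf$taps) - 1L) / 2L
  expect_equal(out[(1001 - m):(1001 + m)], cf$taps, tolerance = 1e-12)

  # short signals (shorter than one FFT block) still match
  xs <- rnorm(50)
  expect_equal(apply_overlap_add(xs, cf), direct_filter(xs, cf$taps),
               tolerance = 1e-9)
  expect_error(apply_overlap_add(numeric(0), cf), "empty")
})

test_that("fast mode tracks precise mode to single precision", {
  cf <- design_fir(fir_spec("lowpass", 30, 5, fs = 250))
  set.seed(7)
  x <- rnorm(10000)
  prec <- apply_overlap_add(x, cf, mode = "precise")
  fast <- apply_overlap_add(x, cf, mode = "fast")
  expect_lt(max(abs(fast - prec)) / max(abs(prec)), 1e-4)
})

test_that("the FIR filter is linear and time-invariant", {
  cf <- design_fir(fir_spec("lowpass", 20, 5, fs = 100))
  set.seed(8)
  x <- rnorm(2000)
  y <- rnorm(2000)
  lhs <- apply_overlap_add(2.5 * x - 1.3 * y, cf)
  rhs <- 2.5 * apply_overlap_add(x, cf) - 1.3 * apply_overlap_add(y, cf)
  expect_equal(lhs, rhs, tolerance = 1e-10)

  k <- 37L
  shifted <- c(numeric(k), x)[seq_along(x)]
  fx <- apply_overlap_add(x, cf)
  fs_ <- apply_overlap_add(shifted, cf)
  interior <- (k + 200):(length(x) - 200)
  expect_equal(fs_[interior], fx[interior - k], tolerance = 1e-9)
})

test_that("IIR filtering is zero-phase with expected band behavior", {
  fs <- 250
  t <- (0:(10 * fs - 1)) / fs
  in_band <- sin(2 * pi * 10 * t)
  out <- apply_iir(in_band, "bandpass", c(8, 12), order = 4, fs = fs)
  mid <- (fs + 1):(9 * fs)
  ratio <- sqrt(mean(out[mid]^2) / mean(in_band[mid]^2))
  expect_equal(ratio, 1, tolerance = 0.05)

  stop_band <- sin(2 * pi * 50 * t)
  out2 <- apply_iir(stop_band, "bandpass", c(8, 12), order = 4, fs = fs)
  expect_lt(sqrt(mean(out2[mid]^2) / mean(stop_band[mid]^2)), 0.05)

  n <- 20 * fs
  dc <- rep(3, n)
  hp <- apply_iir(dc + rnorm(n, sd = 1e-6), "highpass", 1, 4, fs)
  interior <- (2 * fs):(n - 2 * fs)       # outside filtfilt edge transients
  expect_lt(abs(mean(hp[interior])), 1e-3 * 3)
})
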