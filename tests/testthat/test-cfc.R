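test_that("analytic signal recovers amplitude and phase of a cosine", {
  fs <- 250
  t <- (0:(fs * 4 - 1)) / fs
  pa <- analytic_phase_amp(cos(2 * pi * 10 * t))
  interior <- 100:(length(t) - 100)
  expect_equal(pa$amplitude[interior], rep(1, length(interior)),
               tolerance = 0.01)
  dphi <- diff(pa$phase[interior]) %% (2 * pi)
  expect_equal(dphi, rep(2 * pi * 10 / fs, length(dphi)), tolerance = 0.01)

  pa3 <- analytic_phase_amp(3.2 * cos(2 * pi * 10 * t))
  expect_equal(mean(pa3$amplitude[interior]), 3.2, tolerance = 0.01)
  expect_error(analytic_phase_amp(rep(1, 100)), "constant")
})

test_that("the envelope tracks an amplitude modulator", {
  fs <- 500
  t <- (0:(fs * 10 - 1)) / fs
  modu <- 1 + 0.5 * cos(2 * pi * 6 * t)
  x <- modu * cos(2 * pi * 60 * t)
  env <- analytic_phase_amp(x)$amplitude
  interior <- 250:(length(t) - 250)
  expect_gte(cor(env[interior], modu[interior]), 0.95)
})

test_that("phase-amplitude histogram bins correctly", {
  n_bins <- 18L
  # uniform phase grid, constant amplitude -> flat histogram
  ph <- seq(-pi + 1e-6, pi, length.out = 1800)
  h <- phase_amp_histogram(ph, rep(2, 1800), n_bins)
  expect_equal(h$mean_amp, rep(2, n_bins))
  expect_equal(sum(h$counts), 1800L)

  # all phases in one bin
  h2 <- suppressWarnings(phase_amp_histogram(rep(0.1, 50), 1:50, n_bins))
  expect_equal(sum(h2$mean_amp > 0), 1L)
  expect_equal(max(h2$mean_amp), mean(1:50))
  expect_warning(phase_amp_histogram(rep(0.1, 50), 1:50, n_bins), "empty")

  # closed-form bin means for amplitude = 1 + sin(phase)
  dense <- seq(-pi + 1e-9, pi, length.out = 2e5)
  h3 <- phase_amp_histogram(dense, 1 + sin(dense), n_bins)
  expect_equal(h3$mean_amp, 1 + sin(h3$bin_center), tolerance = 0.02)

  expect_error(phase_amp_histogram(1:10, 1:10, n_bins = 1), "at least 2")
  expect_error(phase_amp_histogram(1:5, 1:4), "equal length")
})

test_that("modulation index matches its entropy closed forms", {
  one_hot <- c(1, rep(0, 17))
  expect_equal(modulation_index(one_hot)$value, 1)
  expect_equal(modulation_index(rep(3, 18))$value, 0)
  expect_equal(modulation_index(rep(c(1, 0), each = 9))$value,
               log(2) / log(18), tolerance = 1e-12)
  expect_error(modulation_index(rep(0, 18)), "all-zero")
})

test_that("direct modulation index scores sinusoidal modulation", {
  centers <- seq(-pi, pi, length.out = 19)[-1] - pi / 18
  exact <- 0.5 + 0.5 * sin(centers)
  expect_equal(direct_modulation_index(exact)$value, 1, tolerance = 1e-9)
  expect_equal(direct_modulation_index(rep(0.7, 18))$value, 0)
  expect_error(direct_modulation_index(c(1, 2, 3)), "4 non-empty")

  # generator ground truth: deeper modulation scores higher
  score <- function(depth) {
    g <- gen_pac_signal(fs = 250, duration = 30, seed = 55, depth = depth)
    low <- apply_fir(g$composite, "bandpass", c(4, 8), 2, fs = 250)
    high <- apply_fir(g$composite, "bandpass", c(50, 70), 4, fs = 250)
    cfc_metric(low, high, "dmi")$value
  }
  expect_gt(score(1), score(0))
})

test_that("PAC phase-locking value matches the von Mises resultant", {
  n <- 2048
  psi_env <- 2 * pi * 32 * (0:(n - 1)) / n        # 32 envelope cycles
  env <- 1 + 0.9 * cos(psi_env)
  # perfectly locked: phase difference identically 0
  expect_equal(pac_plv(psi_env, env)$value, 1, tolerance = 0.01)
  # uniform phase difference over full cycles -> 0
  delta_u <- 2 * pi * 7 * (0:(n - 1)) / n
  expect_equal(pac_plv(psi_env + delta_u, env)$value, 0, tolerance = 0.02)
  # von Mises(kappa = 2) phase jitter -> resultant I1(2)/I0(2)
  set.seed(56)
  n2 <- 10000
  psi2 <- 2 * pi * 100 * (0:(n2 - 1)) / n2
  env2 <- 1 + 0.9 * cos(psi2)
  delta <- rvonmises(n2, 2)
  v <- pac_plv(psi2 + delta, env2)$value
  expect_equal(v, besselI(2, 1) / besselI(2, 0), tolerance = 0.05)
  expect_error(pac_plv(psi_env, rep(1, n)), "constant")
})

test_that("mean vector length matches its closed forms", {
  n <- 3600
  ph <- seq(-pi, pi, length.out = n + 1)[-1]
  expect_equal(mean_vector_length(ph, rep(1, n))$value, 0, tolerance = 1e-6)
  expect_equal(mean_vector_length(ph, 1 + cos(ph))$value, 0.5,
               tolerance = 1e-3)
  expect_equal(mean_vector_length(rep(0.7, 100), rep(1, 100))$value, 1)
  expect_error(mean_vector_length(numeric(0), numeric(0)), "empty")
  # linear in amplitude gain
  set.seed(57)
  a <- abs(rnorm(500)); p <- runif(500, -pi, pi)
  expect_equal(mean_vector_length(p, 4 * a)$value,
               4 * mean_vector_length(p, a)$value, tolerance = 1e-12)
})

test_that("MI and DMI are invariant to circular histogram rotation", {
  set.seed(58)
  h <- abs(rnorm(18)) + 0.1
  for (k in c(3, 9, 14)) {
    rot <- c(h[-seq_len(k)], h[seq_len(k)])
    expect_equal(modulation_index(rot)$value, modulation_index(h)$value,
                 tolerance = 1e-12)
    expect_equal(direct_modulation_index(rot)$value,
                 direct_modulation_index(h)$value, tolerance = 1e-6)
  }
})

test_that("PAC scores stay in [0, 1] on randomized inputs", {
  for (s in 1:10) {
    set.seed(700 + s)
    ph <- runif(1000, -pi, pi)
    amp <- abs(rnorm(1000)) + 1e-3
    h <- suppressWarnings(phase_amp_histogram(ph, amp))
    expect_true(modulation_index(h)$value >= 0 &&
                  modulation_index(h)$value <= 1)
    expect_true(direct_modulation_index(h)$value >= 0 &&
                  direct_modulation_index(h)$value <= 1)
    expect_true(pac_plv(ph, amp)$value <= 1)
  }
})
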