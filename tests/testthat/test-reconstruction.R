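test_that("baseline subtraction recovers offset-free signals", {
  expect_equal(background_subtract(rep(3.5, 100), 10), rep(0, 100))
  set.seed(1)
  sig <- c(numeric(64), sin(seq(0, 6 * pi, length.out = 64)))
  expect_equal(background_subtract(sig + 5, 64), sig)
  # zero-mean baseline leaves the signal essentially unchanged
  noise <- rnorm(64, sd = 1e-3)
  noisy <- c(noise, sig[65:128])
  expect_equal(background_subtract(noisy, 64), noisy - mean(noise))
  expect_error(background_subtract(sig, 128), "shorter")
})

test_that("Hilbert envelope matches closed forms", {
  n <- 1024
  t <- seq_len(n) - 1
  x <- 2.5 * cos(2 * pi * 50 * t / n)
  env <- hilbert_envelope(x)
  interior <- 100:(n - 100)
  expect_equal(env[interior], rep(2.5, length(interior)), tolerance = 1e-6)

  expect_equal(hilbert_envelope(numeric(64)), numeric(64))
  expect_equal(hilbert_envelope(-x), hilbert_envelope(x))

  # Gaussian-modulated tone: envelope is the Gaussian, within 1% inside
  t2 <- (t - n / 2)
  gauss <- exp(-t2^2 / (2 * 40^2))
  tone <- gauss * cos(2 * pi * 100 * t / n)
  env2 <- hilbert_envelope(tone)
  core <- which(gauss > 0.05)
  expect_lt(max(abs(env2[core] - gauss[core]) / gauss[core]), 0.01)
})

test_that("trapezoidal AUC is exact on polygonal envelopes", {
  n <- 101
  dt <- 1 / (n - 1)
  expect_equal(auc(rep(1, n), dt, 0, 1), 1.0)
  expect_equal(auc(numeric(n), dt), 0)

  # triangle of base 1, height 2: area 1 (trapezoid exact on piecewise linear)
  tri <- c(seq(0, 2, length.out = 51), seq(2, 0, length.out = 51)[-1])
  expect_equal(auc(tri, dt), 1, tolerance = 1e-9)

  # positive homogeneity
  expect_equal(auc(3.7 * tri, dt), 3.7 * auc(tri, dt))
  expect_error(auc(tri, dt, 0.5, 0.2), "t0")
  expect_error(auc(tri, dt, 0, 2), "outside")
})

test_that("spectral stacks reflect composite absorption ratios", {
  energies <- c(1, 0.8, 1.3, 0.6)
  acq <- acquisition_spec(samples_per_aline = 1024L, noise_sigma = 0,
                          energy_jitter = 0, pulse_energies_uJ = energies,
                          seed = 3L)
  ph <- make_phantom("mixture_10", grid = c(6L, 6L))
  fs <- simulate_frameset(ph, acq)
  lib <- spectral_library()
  A <- build_extinction_matrix(lib, acq$wavelengths, c("collagen", "melanin"))
  mu <- as.numeric(unclass(A) %*% c(0.9, 0.1))

  raw <- build_spectral_stack(fs, compensation = "none")
  raw_means <- apply(raw$auc, 3L, mean)
  expect_equal(raw_means / raw_means[1],
               (mu * energies) / (mu[1] * energies[1]), tolerance = 1e-9)

  comp <- build_spectral_stack(fs)
  comp_means <- apply(comp$auc, 3L, mean)
  expect_equal(comp_means / comp_means[1], mu / mu[1], tolerance = 1e-9)

  # homogeneous phantom at zero noise: each wavelength image is constant
  for (l in 1:4) {
    img <- comp$auc[, , l]
    expect_lt(diff(range(img)) / mean(img), 1e-9)
  }
})

test_that("energy compensation cancels pulse-energy differences exactly", {
  mkstack <- function(energies) {
    acq <- acquisition_spec(samples_per_aline = 1024L, noise_sigma = 0,
                            energy_jitter = 0, pulse_energies_uJ = energies,
                            seed = 8L)
    build_spectral_stack(simulate_frameset(make_phantom("mixture_5",
                                                        grid = c(6L, 6L)), acq))
  }
  s1 <- mkstack(c(1, 1, 1, 1))
  s2 <- mkstack(c(2.5, 0.4, 1.7, 0.9))
  expect_equal(s1$auc, s2$auc, tolerance = 1e-9)
})

test_that("equal pulse energies make compensation a global rescale", {
  acq <- acquisition_spec(samples_per_aline = 1024L, noise_sigma = 0,
                          energy_jitter = 0, pulse_energies_uJ = rep(2, 4),
                          seed = 3L)
  fs <- simulate_frameset(make_phantom("mixture_5", grid = c(5L, 5L)), acq)
  comp <- build_spectral_stack(fs)
  raw <- build_spectral_stack(fs, compensation = "none")
  expect_equal(comp$auc, raw$auc / 2, tolerance = 1e-12)
  expect_true(comp$compensated)
  expect_false(raw$compensated)
})
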