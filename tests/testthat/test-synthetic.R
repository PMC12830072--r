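test_that("named mixture scenarios carry the stated compositions", {
  ph <- make_phantom("mixture_1")
  comp <- ph$regions[[1]]$composition
  expect_equal(comp[["melanin"]], 0.01)
  expect_equal(comp[["collagen"]], 0.99)
  comp20 <- make_phantom("mixture_20")$regions[[1]]$composition
  expect_equal(comp20[["melanin"]], 0.20)
  expect_equal(comp20[["collagen"]], 0.80)
  expect_error(make_phantom("mixture_42"), "unknown scenario")
})

test_that("phantom validation enforces composition and geometry invariants", {
  expect_error(phantom_spec(regions = list(
    list(type = "background", composition = c(collagen = 0.5, melanin = 0.4),
         depth_um = 6000))), "sum to 1")
  expect_error(phantom_spec(regions = list(
    list(type = "background", composition = c(collagen = 1.2, melanin = -0.2),
         depth_um = 6000))), "non-negative")
  expect_error(phantom_spec(regions = list(
    list(type = "vessel", centerline = cbind(c(5, 5), c(1, 200)),
         radius_um = 60, so2 = 0.9, depth_um = 6000))), "within the grid")
  expect_error(phantom_spec(regions = list(
    list(type = "vessel", centerline = cbind(c(5, 5), c(1, 20)),
         radius_um = -1, so2 = 0.9, depth_um = 6000))), "radius")
})

test_that("vessel_demo has an arteriole-like and a venule-like tube", {
  ph <- make_phantom("vessel_demo")
  vessels <- Filter(function(r) identical(r$type, "vessel"), ph$regions)
  expect_gte(length(vessels), 2L)
  so2s <- sort(vapply(vessels, `[[`, numeric(1), "so2"))
  expect_gt(so2s[length(so2s)], 0.9)  # arteriole-like
  expect_lt(so2s[1], 0.8)             # venule-like
})

test_that("single A-line follows the closed-form bandlimited pulse model", {
  acq <- acquisition_spec(samples_per_aline = 1024L, noise_sigma = 0, seed = 1L)
  expect_identical(simulate_aline(0, 6000, acq), rep(0, 1024L))

  x1 <- simulate_aline(1, 6000, acq)
  x2 <- simulate_aline(2, 6000, acq)
  expect_equal(x2, 2 * x1)

  # direct sample-by-sample evaluation of the documented closed form
  t <- (0:1023) * 10e-9
  t0 <- 6000e-6 / 1500
  tau <- sqrt(2 * log(2)) / (pi * 0.66 * 2.25e6)
  oracle <- exp(-(t - t0)^2 / (2 * tau^2)) * cos(2 * pi * 2.25e6 * (t - t0))
  expect_equal(x1, oracle, tolerance = 1e-12)

  expect_error(simulate_aline(1, 6e7, acq), "outside")
})

test_that("frame sets are homogeneous, contrast-ordered and reproducible", {
  acq <- acquisition_spec(samples_per_aline = 1024L, noise_sigma = 0,
                          energy_jitter = 0, seed = 4L)
  ph <- make_phantom("mixture_1", grid = c(8L, 8L))
  fs <- simulate_frameset(ph, acq)
  for (l in 1:4) {
    X <- fs$alines[[l]]
    expect_equal(max(abs(sweep(X, 1L, X[, 1]))), 0)  # all pixels identical
  }

  demo <- make_phantom("vessel_demo", grid = c(24L, 24L))
  fs2 <- simulate_frameset(demo, acq)
  peak <- apply(abs(fs2$alines[[1]]), 2L, max)  # 532 nm
  vessel_pix <- !is.na(fs2$truth$so2)
  expect_gt(min(peak[vessel_pix]), max(peak[!vessel_pix]))

  fs3 <- simulate_frameset(demo, acq)
  expect_identical(fs2$alines, fs3$alines)

  acq_n <- acquisition_spec(samples_per_aline = 1024L, noise_sigma = 0.05, seed = 9L)
  n1 <- simulate_frameset(ph, acq_n)
  n2 <- simulate_frameset(ph, acq_n)
  expect_identical(n1$alines, n2$alines)
})

test_that("frame sets record post-jitter pulse energies", {
  acq <- acquisition_spec(samples_per_aline = 1024L, noise_sigma = 0,
                          energy_jitter = 0.05, seed = 12L)
  ph <- make_phantom("mixture_5", grid = c(8L, 8L))
  fs <- simulate_frameset(ph, acq)
  expect_gt(stats::sd(fs$energies), 0)
  # amplitudes scale with the recorded energies: compensating per shot must
  # flatten the image exactly at zero noise
  stack <- build_spectral_stack(fs, compensation = "per_shot")
  for (l in 1:4) {
    img <- stack$auc[, , l]
    expect_lt(diff(range(img)) / mean(img), 1e-9)
  }
})

test_that("training pairs have the averaged-reference noise structure", {
  acq0 <- acquisition_spec(samples_per_aline = 512L, noise_sigma = 0, seed = 2L)
  p0 <- make_training_pairs("mixture_1", acq0, n_pairs = 4L, n_average = 10L)
  expect_identical(p0$noisy, p0$reference)

  acq <- acquisition_spec(samples_per_aline = 512L, noise_sigma = 0.05, seed = 2L)
  pr <- make_training_pairs("mixture_1", acq, n_pairs = 120L, n_average = 150L)
  v_noisy <- mean((pr$noisy - pr$clean)^2)
  v_ref <- mean((pr$reference - pr$clean)^2)
  expect_equal(v_ref / v_noisy, 1 / 150, tolerance = 0.25)

  p1 <- make_training_pairs("mixture_1", acq, n_pairs = 10L, n_average = 1L)
  # n_average = 1: the reference is an independent single realization
  expect_false(identical(p1$noisy, p1$reference))
  expect_equal(mean((p1$reference - p1$clean)^2),
               mean((p1$noisy - p1$clean)^2), tolerance = 0.2)

  expect_error(make_training_pairs("mixture_1", acq, n_pairs = 5L,
                                   n_average = 0L), "n_average")
})

test_that("mid-rise quantization is idempotent and level-limited", {
  set.seed(6)
  x <- rnorm(4096)
  q1 <- quantize_bits(x, 8L)
  q2 <- quantize_bits(q1, 8L)  # reuses the stored full scale
  expect_identical(unclass(q1), unclass(q2))
  expect_lte(length(unique(as.vector(q1))), 2^8)

  acq <- acquisition_spec(samples_per_aline = 512L, noise_sigma = 0.01,
                          bit_depth = 16L, seed = 5L)
  fs <- simulate_frameset(make_phantom("mixture_1", grid = c(6L, 6L)), acq)
  lv <- unique(as.vector(fs$alines[[1]]))
  expect_lte(length(lv), 2^16)
})
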