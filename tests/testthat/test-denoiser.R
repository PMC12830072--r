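small_config <- function(seed = 7L) {
  denoiser_config(input_size = 128L, encoder_sizes = c(128L, 64L, 16L),
                  decoder_sizes = c(16L, 64L, 128L), seed = seed)
}

small_train_config <- function(...) {
  training_config(stft_scales = c(32L), batch_size = 16L, ...)
}

test_that("attention gate matches hand-computed tanh/softmax/product", {
  m <- 4L
  z <- c(0.5, -1, 2, 0.25)
  Wa <- matrix(c(0.1, -0.2, 0.3, 0, 0.5, 0.1, -0.1, 0.2,
                 0, 0.4, -0.3, 0.1, 0.2, 0, 0.1, -0.5), m, m)
  Ws <- diag(m) * 0.7
  out <- attention_forward(z, list(Wa = Wa, Ws = Ws))
  # independent scalar arithmetic
  u <- tanh(as.numeric(Wa %*% z))
  s <- 0.7 * u
  a <- exp(s) / sum(exp(s))
  expect_equal(out$u, u)
  expect_equal(out$alpha, a)
  expect_equal(out$c, a * z)
  expect_equal(sum(out$alpha), 1)

  # zero attention weights: uniform alpha, c = z / m
  out0 <- attention_forward(z, list(Wa = matrix(0, m, m), Ws = matrix(0, m, m)))
  expect_equal(out0$alpha, rep(1 / m, m))
  expect_equal(out0$c, z / m)

  # zero embedding passes through to zero
  outz <- attention_forward(numeric(m), list(Wa = Wa, Ws = Ws))
  expect_equal(outz$c, numeric(m))

  expect_error(attention_forward(z, list(Wa = matrix(0, 3, 3), Ws = Ws)),
               "shapes")
})

test_that("attention weights are a probability vector for random inputs", {
  set.seed(14)
  m <- 16L
  W <- list(Wa = matrix(rnorm(m * m), m), Ws = matrix(rnorm(m * m), m))
  Z <- matrix(rnorm(m * 20, sd = 3), m)
  out <- attention_forward(Z, W)
  expect_true(all(out$alpha >= 0))
  expect_equal(unname(colSums(out$alpha)), rep(1, 20), tolerance = 1e-6)
})

test_that("composite loss is a weighted L1 plus multi-scale STFT magnitude L1", {
  cfg <- training_config(stft_scales = c(8L))
  x <- sin(seq(0, 8 * pi, length.out = 32)) * exp(-(1:32) / 20)
  expect_equal(composite_loss(x, x, cfg), 0)

  y <- x + c(rep(0.2, 16), rep(-0.1, 16))
  cfg_l1 <- training_config(lambda1 = 1, lambda2 = 0, stft_scales = c(8L))
  expect_equal(composite_loss(y, x, cfg_l1), mean(abs(y - x)))

  # independent naive-DFT oracle for the spectral term
  Mp <- stft_mag_naive(y, 8L)
  Mr <- stft_mag_naive(x, 8L)
  expected <- 0.6 * mean(abs(y - x)) + 0.4 * mean(abs(Mp - Mr))
  expect_equal(composite_loss(y, x, cfg), expected, tolerance = 1e-12)

  expect_gt(composite_loss(y, x, cfg), 0)
  expect_error(composite_loss(y, x[1:10], cfg), "shapes")
})

test_that("analytic training gradient agrees with finite differences", {
  cfg <- small_config()
  params <- paunmix:::init_denoiser_params(cfg)
  tc <- small_train_config()
  set.seed(3)
  X <- matrix(rnorm(128 * 4), 128, 4)
  Y <- matrix(rnorm(128 * 4), 128, 4)
  cache <- paunmix:::denoiser_forward(params, X, keep = TRUE)
  lg <- paunmix:::composite_loss_impl(cache$out, Y, tc, grad = TRUE)
  g <- paunmix:::denoiser_backward(params, cache, lg$grad)

  loss_at <- function() {
    paunmix:::composite_loss_impl(paunmix:::denoiser_forward(params, X), Y, tc)$loss
  }
  eps <- 1e-6
  for (probe in list(c("Wa", 5), c("Ws", 17), c("p", 3))) {
    nm <- probe[1]; i <- as.integer(probe[2])
    p0 <- params[[nm]][i]
    params[[nm]][i] <- p0 + eps; lp <- loss_at()
    params[[nm]][i] <- p0 - eps; lm <- loss_at()
    params[[nm]][i] <- p0
    expect_equal(g[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
  for (probe in list(list("enc", 1L, "W", 11L), list("dec", 2L, "b", 7L))) {
    p0 <- params[[probe[[1]]]][[probe[[2]]]][[probe[[3]]]][probe[[4]]]
    params[[probe[[1]]]][[probe[[2]]]][[probe[[3]]]][probe[[4]]] <- p0 + eps
    lp <- loss_at()
    params[[probe[[1]]]][[probe[[2]]]][[probe[[3]]]][probe[[4]]] <- p0 - eps
    lm <- loss_at()
    params[[probe[[1]]]][[probe[[2]]]][[probe[[3]]]][probe[[4]]] <- p0
    expect_equal(g[[probe[[1]]]][[probe[[2]]]][[probe[[3]]]][probe[[4]]],
                 (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("reduced training lowers the loss and is reproducible", {
  acq <- acquisition_spec(samples_per_aline = 128L, noise_sigma = 0.05,
                          sampling_interval_ns = 40, seed = 2L)
  ph <- make_phantom("vessel_demo", grid = c(12L, 12L), depth_um = 4000)
  pairs <- make_training_pairs(ph, acq, n_pairs = 64L, n_average = 20L)
  tc <- small_train_config(learning_rate = 1e-3, epochs = 6L, seed = 9L)
  m1 <- train_denoiser(pairs, small_config(), tc)
  expect_length(m1$history, 6L)
  expect_lt(m1$history[6], m1$history[1])

  m2 <- train_denoiser(pairs, small_config(), tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$Wa, m2$params$Wa)

  out <- denoise(m1, pairs$noisy[, 1])
  expect_length(out, 128L)
  expect_true(all(is.finite(out)))
  expect_true(all(is.finite(denoise(m1, numeric(128L)))))
  expect_error(denoise(m1, numeric(64L)), "input size")

  # denoising is optional in the pipeline: reconstruction without a model
  # must leave the stack untouched by any denoiser state
  fs <- simulate_frameset(make_phantom("mixture_1", grid = c(4L, 4L)),
                          acquisition_spec(samples_per_aline = 512L,
                                           noise_sigma = 0, seed = 1L))
  s_plain <- build_spectral_stack(fs)
  expect_s3_class(s_plain, "spectral_stack")
})

test_that("training configuration validates the printed protocol constraints", {
  tc <- training_config()
  expect_equal(tc$learning_rate, 1e-4)
  expect_equal(tc$batch_size, 32L)
  expect_equal(tc$epochs, 120L)
  expect_equal(tc$lambda1 + tc$lambda2, 1)
  expect_error(training_config(lambda1 = 0.5, lambda2 = 0.4), "equal 1")
  expect_error(denoiser_config(input_size = 100L), "encoder size")
})
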