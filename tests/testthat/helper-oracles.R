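# Independent oracles used across the suite. These deliberately avoid the
# package's own computation paths: brute-force grids, naive O(n^2) DFTs,
# shift-based dilation, closed forms.

# Exhaustive search over a non-negative grid for min ||A x - b|| (2 variables).
grid_nnls <- function(A, b, upper, step) {
  xs <- seq(0, upper, by = step)
  best <- list(x = c(0, 0), residual = Inf)
  for (x1 in xs) {
    # vectorize over x2 for speed
    r1 <- b - A[, 1] * x1
    res2 <- sapply(xs, function(x2) sqrt(sum((r1 - A[, 2] * x2)^2)))
    j <- which.min(res2)
    if (res2[j] < best$residual) best <- list(x = c(x1, xs[j]), residual = res2[j])
  }
  best
}

# Same, for the Tikhonov objective ||A x - b||^2 + lambda^2 ||x||^2.
grid_tikhonov <- function(A, b, lambda, upper, step) {
  xs <- seq(0, upper, by = step)
  best <- list(x = c(0, 0), objective = Inf)
  for (x1 in xs) {
    r1 <- b - A[, 1] * x1
    obj2 <- sapply(xs, function(x2) {
      sum((r1 - A[, 2] * x2)^2) + lambda^2 * (x1^2 + x2^2)
    })
    j <- which.min(obj2)
    if (obj2[j] < best$objective) best <- list(x = c(x1, xs[j]), objective = obj2[j])
  }
  best
}

# Naive O(n^2) DFT.
dft_naive <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  sapply(k, function(kk) sum(x * exp(-2i * pi * kk * k / n)))
}

# Naive STFT magnitudes with a periodic Hann window, hop = window / 4.
stft_mag_naive <- function(x, w) {
  hop <- max(1L, w %/% 4L)
  win <- 0.5 * (1 - cos(2 * pi * (0:(w - 1)) / w))
  starts <- seq.int(1L, length(x) - w + 1L, by = hop)
  sapply(starts, function(s) Mod(dft_naive(x[s:(s + w - 1L)] * win)))
}

# Brute-force binary dilation: OR of the mask shifted over all (dy, dx)
# with dy^2 + dx^2 <= r^2.
dilate_shift_oracle <- function(mask, r) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  for (dy in -r:r) for (dx in -r:r) {
    if (dy^2 + dx^2 > r^2) next
    ys <- pmin(pmax(seq_len(H) - dy, 1L), H)
    valid_y <- (seq_len(H) - dy) >= 1 & (seq_len(H) - dy) <= H
    xs <- pmin(pmax(seq_len(W) - dx, 1L), W)
    valid_x <- (seq_len(W) - dx) >= 1 & (seq_len(W) - dx) <= W
    shifted <- matrix(FALSE, H, W)
    shifted[valid_y, valid_x] <- mask[(seq_len(H) - dy)[valid_y],
                                      (seq_len(W) - dx)[valid_x]]
    out <- out | shifted
  }
  out
}

# Small noiseless vessel-demo stack shared by masking/unmixing tests,
# built once per test run.
demo_env <- new.env()
demo_stack <- function() {
  if (is.null(demo_env$stack)) {
    ph <- make_phantom("vessel_demo", grid = c(32L, 32L))
    acq <- acquisition_spec(samples_per_aline = 1024L, noise_sigma = 0,
                            energy_jitter = 0, seed = 7L)
    frames <- simulate_frameset(ph, acq)
    demo_env$frames <- frames
    demo_env$stack <- build_spectral_stack(frames)
    demo_env$phantom <- ph
    demo_env$truth <- frames$truth
  }
  demo_env
}
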