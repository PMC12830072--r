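#' Bandlimited transducer pulse (closed form)
#'
#' The detected waveform for a point absorber is modeled as a
#' Gaussian-envelope sinusoid at the transducer center frequency: the
#' envelope's spectral FWHM equals the fractional bandwidth times the
#' center frequency, so
#' `tau = sqrt(2 log 2) / (pi * B * f0)` and the pulse is
#' `exp(-(t - t0)^2 / (2 tau^2)) * cos(2 pi f0 (t - t0))`.
#' This stands in for a full acoustic wave solver: region-partitioned
#' unmixing depends only on relative spectral amplitudes, which this model
#' preserves exactly.
#'
#' @param t Sample times, seconds.
#' @param t0 Arrival time (time of flight), seconds.
#' @param f0 Center frequency, Hz.
#' @param fractional_bandwidth Fractional bandwidth (e.g. 0.66).
#' @return Waveform samples of unit peak amplitude.
#' @export
transducer_pulse <- function(t, t0, f0, fractional_bandwidth) {
  tau <- sqrt(2 * log(2)) / (pi * fractional_bandwidth * f0)
  exp(-(t - t0)^2 / (2 * tau^2)) * cos(2 * pi * f0 * (t - t0))
}

#' Simulate a single A-line
#'
#' Clean signal: `mu_a * pulse_energy` times the unit [transducer_pulse()]
#' centered at time-of-flight `depth / c` (the Grueneisen coefficient and
#' optical fluence are folded into a unit calibration constant, i.e. the
#' photoacoustic amplitude is assumed to scale with absorption). Additive
#' Gaussian noise with standard deviation `noise_sigma * max |clean|`
#' (or `noise_sigma * reference_amplitude` when supplied) is then applied,
#' followed by optional uniform mid-rise quantization.
#'
#' @param mu_a Absorption coefficient, mm^-1 (>= 0).
#' @param depth_um Acoustic path length, um.
#' @param acq An [acquisition_spec()].
#' @param wavelength_index Index into `acq$wavelengths` selecting the pulse
#'   energy.
#' @param pulse_energy Actual pulse energy in uJ; defaults to the nominal
#'   energy of the selected wavelength (no jitter).
#' @param reference_amplitude Amplitude scale that `noise_sigma` is relative
#'   to; defaults to this A-line's own maximum clean amplitude.
#' @return Numeric vector of `acq$samples_per_aline` samples.
#' @export
simulate_aline <- function(mu_a, depth_um, acq, wavelength_index = 1L,
                           pulse_energy = NULL, reference_amplitude = NULL) {
  stopifnot(inherits(acq, "acquisition_spec"), mu_a >= 0, depth_um > 0)
  n <- acq$samples_per_aline
  dt <- acq$sampling_interval_ns * 1e-9
  t <- (seq_len(n) - 1L) * dt
  t0 <- depth_um * 1e-6 / acq$speed_of_sound
  if (t0 >= t[n]) {
    stop("time of flight (", format(t0 * 1e6), " us) falls outside the ",
         format(t[n] * 1e6), " us recording window")
  }
  energy <- pulse_energy %||% acq$pulse_energies_uJ[wavelength_index]
  amp <- mu_a * energy
  clean <- amp * transducer_pulse(t, t0, acq$transducer_center_freq_mhz * 1e6,
                                  acq$fractional_bandwidth_pct / 100)
  x <- clean
  if (acq$noise_sigma > 0) {
    ref <- reference_amplitude %||% max(abs(clean))
    x <- x + stats::rnorm(n, sd = acq$noise_sigma * ref)
  }
  if (!is.null(acq$bit_depth)) {
    x <- quantize_bits(x, acq$bit_depth)
  }
  x
}

#' Uniform mid-rise quantization
#'
#' Quantizes samples to `2^bits` levels spanning `[-full_scale, full_scale]`.
#' Re-applying with the same `full_scale` is an identity (idempotence), so
#' quantized frame sets record the full scale used.
#'
#' @param x Numeric vector, matrix or array.
#' @param bits Bit depth (e.g. 16).
#' @param full_scale Positive scalar; defaults to `max(abs(x))`.
#' @return Quantized object of the same shape, with attribute `full_scale`.
#' @export
quantize_bits <- function(x, bits, full_scale = NULL) {
  stopifnot(bits >= 2, bits <= 32)
  fs <- full_scale %||% attr(x, "full_scale") %||% max(abs(x))
  if (fs == 0) return(structure(x, full_scale = 0))
  q <- 2 * fs / 2^bits
  lev <- floor(unclass(x) / q)
  half <- 2^(bits - 1)
  lev <- pmin(pmax(lev, -half), half - 1)
  out <- (lev + 0.5) * q
  attributes(out) <- attributes(x)
  attr(out, "full_scale") <- fs
  out
}

#' Simulate a raw multispectral frame set
#'
#' For every pixel and wavelength the composite absorption coefficient is
#' the composition-weighted sum of the library spectra; the clean A-line is
#' that absorption times the (possibly jittered) pulse energy times the
#' unit bandlimited pulse at the pixel's time of flight. Noise is relative
#' to the maximum clean amplitude across the whole frame set, and
#' per-shot pulse energies actually applied are recorded so downstream
#' energy compensation can be exact. Deterministic given `acq$seed`.
#'
#' @param phantom A [phantom_spec()] or scenario name.
#' @param acq An [acquisition_spec()].
#' @param library Spectral library (defaults to the packaged one).
#' @return A `raw_frameset`: list with `alines` (per-wavelength list of
#'   T x (H*W) matrices, column-major over the H x W grid), `energies`
#'   (H x W x wavelength array of applied pulse energies, uJ), `spec`,
#'   `phantom`, and `truth` (see [rasterize_phantom()]).
#' @export
simulate_frameset <- function(phantom, acq = acquisition_spec(),
                              library = spectral_library()) {
  phantom <- make_phantom(phantom)
  stopifnot(inherits(acq, "acquisition_spec"))
  set.seed(acq$seed)
  truth <- rasterize_phantom(phantom)
  H <- phantom$grid[1]; W <- phantom$grid[2]
  npix <- H * W
  n <- acq$samples_per_aline
  dt <- acq$sampling_interval_ns * 1e-9
  t <- (seq_len(n) - 1L) * dt
  chroms <- dimnames(truth$fractions)[[3]]
  A <- build_extinction_matrix(library, acq$wavelengths, chroms)
  fr <- matrix(truth$fractions, nrow = npix)  # npix x chroms
  mu <- fr %*% t(unclass(A))                  # npix x wavelengths

  depths <- unique(as.vector(truth$depth_um))
  pulses <- lapply(depths, function(d) {
    t0 <- d * 1e-6 / acq$speed_of_sound
    if (t0 >= t[n]) {
      stop("time of flight for depth ", d, " um falls outside the recording window")
    }
    transducer_pulse(t, t0, acq$transducer_center_freq_mhz * 1e6,
                     acq$fractional_bandwidth_pct / 100)
  })
  depth_idx <- match(as.vector(truth$depth_um), depths)

  nlam <- length(acq$wavelengths)
  energies <- array(NA_real_, dim = c(H, W, nlam))
  for (l in seq_len(nlam)) {
    e <- acq$pulse_energies_uJ[l]
    jit <- if (acq$energy_jitter > 0) {
      pmax(1 + stats::rnorm(npix, sd = acq$energy_jitter), .Machine$double.eps)
    } else rep(1, npix)
    energies[, , l] <- matrix(e * jit, H, W)
  }

  # max clean amplitude across the frame set (unit-peak pulse => amplitude map)
  amp_max <- 0
  for (l in seq_len(nlam)) {
    amp_max <- max(amp_max, max(mu[, l] * as.vector(energies[, , l])))
  }

  alines <- vector("list", nlam)
  for (l in seq_len(nlam)) {
    amps <- mu[, l] * as.vector(energies[, , l])
    X <- matrix(0, n, npix)
    for (di in seq_along(depths)) {
      sel <- which(depth_idx == di)
      if (length(sel)) X[, sel] <- outer(pulses[[di]], amps[sel])
    }
    if (acq$noise_sigma > 0 && amp_max > 0) {
      X <- X + matrix(stats::rnorm(n * npix, sd = acq$noise_sigma * amp_max),
                      n, npix)
    }
    alines[[l]] <- X
  }

  fs <- NULL
  if (!is.null(acq$bit_depth)) {
    fs <- max(vapply(alines, function(X) max(abs(X)), numeric(1)))
    alines <- lapply(alines, quantize_bits, bits = acq$bit_depth,
                     full_scale = fs)
  }
  structure(list(alines = alines, energies = energies, spec = acq,
                 phantom = phantom, truth = truth, dim = c(H, W),
                 quant_full_scale = fs),
            class = "raw_frameset")
}

#' @export
print.raw_frameset <- function(x, ...) {
  cat("raw_frameset:", x$dim[1], "x", x$dim[2], "pixels,",
      length(x$spec$wavelengths), "wavelengths (",
      paste(x$spec$wavelengths, collapse = "/"), "nm ),",
      x$spec$samples_per_aline, "samples/A-line\n")
  invisible(x)
}

#' Generate paired noisy/reference A-lines for denoiser training
#'
#' Each pair consists of one noisy single-shot realization and a reference
#' obtained by averaging `n_average` independent noisy realizations of the
#' same clean signal (emulating high-SNR references acquired by 150x
#' averaging). Pixels, wavelengths and per-shot pulse energies are drawn at
#' random from the phantom so amplitudes vary across pairs; pixels are
#' sampled with probability proportional to their signal amplitude, so the
#' pairs carry detectable waveforms the way training pairs acquired over
#' real structures do (an A-line with no signal above the noise floor
#' teaches only suppression).
#'
#' @param phantom A [phantom_spec()] or scenario name.
#' @param acq An [acquisition_spec()]; its `noise_sigma` sets the single-shot
#'   noise level and its `seed` the randomness.
#' @param n_pairs Number of pairs (> 0).
#' @param n_average Number of averaged realizations for the reference
#'   (default 150; >= 1).
#' @param library Spectral library.
#' @return A `training_pairs` list with `noisy` and `reference`
#'   (T x n_pairs matrices), `clean`, and `meta`.
#' @export
make_training_pairs <- function(phantom, acq = acquisition_spec(),
                                n_pairs = 500L, n_average = 150L,
                                library = spectral_library()) {
  stopifnot(n_pairs > 0)
  if (n_average < 1) stop("n_average must be >= 1")
  phantom <- make_phantom(phantom)
  set.seed(acq$seed + 1L)
  truth <- rasterize_phantom(phantom)
  H <- phantom$grid[1]; W <- phantom$grid[2]
  n <- acq$samples_per_aline
  dt <- acq$sampling_interval_ns * 1e-9
  t <- (seq_len(n) - 1L) * dt
  chroms <- dimnames(truth$fractions)[[3]]
  A <- build_extinction_matrix(library, acq$wavelengths, chroms)
  fr <- matrix(truth$fractions, nrow = H * W)
  mu <- fr %*% t(unclass(A))

  amp_weight <- apply(mu, 1L, max)
  pix <- sample.int(H * W, n_pairs, replace = TRUE, prob = amp_weight)
  lam <- sample.int(length(acq$wavelengths), n_pairs, replace = TRUE)
  jit <- if (acq$energy_jitter > 0) {
    pmax(1 + stats::rnorm(n_pairs, sd = acq$energy_jitter), .Machine$double.eps)
  } else rep(1, n_pairs)
  energy <- acq$pulse_energies_uJ[lam] * jit
  amps <- mu[cbind(pix, lam)] * energy

  depth <- as.vector(truth$depth_um)[pix]
  clean <- matrix(0, n, n_pairs)
  f0 <- acq$transducer_center_freq_mhz * 1e6
  bw <- acq$fractional_bandwidth_pct / 100
  for (d in unique(depth)) {
    sel <- which(depth == d)
    pulse <- transducer_pulse(t, d * 1e-6 / acq$speed_of_sound, f0, bw)
    clean[, sel] <- outer(pulse, amps[sel])
  }
  sd0 <- acq$noise_sigma * max(abs(clean))
  noisy <- clean
  reference <- clean
  if (sd0 > 0) {
    noisy <- clean + matrix(stats::rnorm(n * n_pairs, sd = sd0), n, n_pairs)
    for (j in seq_len(n_pairs)) {
      reps <- matrix(stats::rnorm(n * n_average, sd = sd0), n, n_average)
      reference[, j] <- clean[, j] + rowMeans(reps)
    }
  }
  structure(list(noisy = noisy, reference = reference, clean = clean,
                 meta = list(pixel = pix, wavelength_index = lam,
                             pulse_energy = energy, noise_sd = sd0,
                             n_average = n_average, acq = acq)),
            class = "training_pairs")
}
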