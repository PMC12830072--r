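#' Subtract the pre-arrival baseline from A-lines
#'
#' Estimates the DC background of each A-line as the mean of its first
#' `window` samples (before any acoustic arrival) and subtracts it.
#'
#' @param x Numeric vector, or matrix with one A-line per column.
#' @param window Number of leading samples used for the baseline estimate;
#'   must be smaller than the A-line length.
#' @return Object of the same shape.
#' @export
background_subtract <- function(x, window = 256L) {
  v <- is.null(dim(x))
  X <- if (v) matrix(x, ncol = 1L) else x
  if (window >= nrow(X)) stop("baseline window must be shorter than the A-line")
  if (window < 1) stop("baseline window must be >= 1")
  bg <- colMeans(X[seq_len(window), , drop = FALSE])
  out <- sweep(X, 2L, bg)
  if (v) drop(out) else out
}

#' Hilbert envelope of A-lines
#'
#' Magnitude of the analytic signal, computed in the frequency domain
#' (positive frequencies doubled, negative frequencies zeroed).
#'
#' @param x Numeric vector, or matrix with one A-line per column.
#' @return Non-negative envelope of the same shape.
#' @export
hilbert_envelope <- function(x) {
  v <- is.null(dim(x))
  X <- if (v) matrix(x, ncol = 1L) else x
  n <- nrow(X)
  if (n < 2L) stop("A-line must have at least 2 samples")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2L)] <- 2
  }
  Xf <- stats::mvfft(X) * h
  env <- Mod(stats::mvfft(Xf, inverse = TRUE)) / n
  if (v) drop(env) else env
}

#' Trapezoidal area under an envelope
#'
#' Integrates the envelope over the time window `[t0, t1]` (inclusive
#' sample range) with the trapezoidal rule. Times are in the same unit as
#' `dt`; the result carries units of amplitude x time.
#'
#' @param envelope Numeric vector, or matrix with one envelope per column.
#' @param dt Sampling interval (any time unit).
#' @param t0,t1 Integration limits in the same unit, measured from the first
#'   sample at time 0. Default: the full record.
#' @return Scalar AUC (or one AUC per column).
#' @export
auc <- function(envelope, dt = 1, t0 = NULL, t1 = NULL) {
  v <- is.null(dim(envelope))
  E <- if (v) matrix(envelope, ncol = 1L) else envelope
  n <- nrow(E)
  tmax <- (n - 1L) * dt
  t0 <- t0 %||% 0
  t1 <- t1 %||% tmax
  if (t0 >= t1) stop("t0 must be < t1")
  if (t0 < 0 || t1 > tmax + 1e-9 * dt) stop("integration window outside the record")
  i0 <- round(t0 / dt) + 1L
  i1 <- round(t1 / dt) + 1L
  E <- E[i0:i1, , drop = FALSE]
  out <- dt * (colSums(E) - 0.5 * (E[1L, ] + E[nrow(E), ]))
  if (v) unname(out[1L]) else out
}

#' Build energy-compensated per-wavelength AUC images
#'
#' Per pixel and wavelength: (optionally denoise the raw A-line, then)
#' subtract the pre-arrival baseline, take the Hilbert envelope, subtract
#' each A-line's envelope noise floor (its mean envelope over the baseline
#' window), and integrate with the trapezoidal rule over the signal gate.
#' Each wavelength's AUC image is then divided by that wavelength's mean
#' applied pulse energy (`compensation = "mean"`), by each shot's own
#' recorded energy (`"per_shot"`), or left uncompensated (`"none"`). Only
#' compensated stacks should be passed to spectral unmixing.
#'
#' The signal gate matters: the detected pulse occupies a small fraction of
#' the record, so integrating the rectified envelope over everything would
#' accumulate a noise pedestal that can exceed the signal of weak (dermal)
#' absorbers. By default (`gate = "auto"`) the gate is found from the
#' pixel-mean envelope: the samples above 10 percent of its peak, widened
#' by four pulse widths, shared by all wavelengths. `gate = "full"`
#' integrates the whole post-baseline record; explicit `t0_us`/`t1_us`
#' override both.
#'
#' @param frames A `raw_frameset` from [simulate_frameset()].
#' @param background_window Leading samples for baseline and noise-floor
#'   estimation.
#' @param t0_us,t1_us Explicit integration window in microseconds from the
#'   record start (overrides `gate`).
#' @param gate `"auto"` (signal-adaptive window, default) or `"full"`.
#' @param envelope_floor Subtract the per-A-line envelope noise floor
#'   before integration (default `TRUE`; the AUC is clipped at zero).
#' @param denoiser Optional `trained_denoiser` applied to raw A-lines.
#' @param compensation One of `"mean"`, `"per_shot"`, `"none"`.
#' @return A `spectral_stack`: list with `auc` (H x W x wavelength array),
#'   `wavelengths`, `compensated`, `compensation`, `mean_energies_uJ`,
#'   and the integration window used (`t0_us`, `t1_us`).
#' @export
build_spectral_stack <- function(frames, background_window = 256L,
                                 t0_us = NULL, t1_us = NULL,
                                 gate = c("auto", "full"),
                                 envelope_floor = TRUE,
                                 denoiser = NULL,
                                 compensation = c("mean", "per_shot", "none")) {
  stopifnot(inherits(frames, "raw_frameset"))
  compensation <- match.arg(compensation)
  gate <- match.arg(gate)
  if (compensation != "none" && is.null(frames$energies)) {
    stop("frame set carries no pulse energies; cannot compensate")
  }
  H <- frames$dim[1]; W <- frames$dim[2]
  nlam <- length(frames$spec$wavelengths)
  dt_us <- frames$spec$sampling_interval_ns / 1000
  n <- frames$spec$samples_per_aline
  bgw <- background_window
  aucs <- array(NA_real_, dim = c(H, W, nlam))
  mean_e <- numeric(nlam)
  gate_t0 <- t0_us; gate_t1 <- t1_us
  for (l in seq_len(nlam)) {
    X <- frames$alines[[l]]
    if (!is.null(denoiser)) X <- denoise(denoiser, X)
    X <- background_subtract(X, bgw)
    env <- hilbert_envelope(X)
    if (envelope_floor) {
      floor_est <- colMeans(env[seq_len(bgw), , drop = FALSE])
      env <- sweep(env, 2L, floor_est)
    }
    if (is.null(gate_t0) || is.null(gate_t1)) {
      if (gate == "auto") {
        # signal support of the pixel-mean envelope, widened by 4 pulse
        # widths; the arrival geometry is wavelength-independent, so the
        # first wavelength's gate is shared by all
        menv <- rowMeans(env)
        peak <- max(menv[(bgw + 1L):n])
        if (peak > 0) {
          sup <- range(which(menv > 0.1 * peak))
          tau_us <- sqrt(2 * log(2)) /
            (pi * frames$spec$fractional_bandwidth_pct / 100 *
               frames$spec$transducer_center_freq_mhz)  # MHz -> us
          gate_t0 <- max(bgw * dt_us, (sup[1] - 1L) * dt_us - 4 * tau_us)
          gate_t1 <- min((n - 1L) * dt_us, (sup[2] - 1L) * dt_us + 4 * tau_us)
        }
      }
      if (is.null(gate_t0)) gate_t0 <- bgw * dt_us
      if (is.null(gate_t1)) gate_t1 <- (n - 1L) * dt_us
    }
    a <- pmax(auc(env, dt = dt_us, t0 = gate_t0, t1 = gate_t1), 0)
    img <- matrix(a, H, W)
    mean_e[l] <- mean(frames$energies[, , l])
    img <- switch(compensation,
                  mean = img / mean_e[l],
                  per_shot = img / frames$energies[, , l],
                  none = img)
    aucs[, , l] <- img
  }
  structure(list(auc = aucs, wavelengths = frames$spec$wavelengths,
                 compensated = compensation != "none",
                 compensation = compensation,
                 mean_energies_uJ = mean_e,
                 t0_us = gate_t0, t1_us = gate_t1,
                 pixel_pitch_um = frames$phantom$pixel_pitch_um %||% NA_real_),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  d <- dim(x$auc)
  cat("spectral_stack:", d[1], "x", d[2], "pixels at",
      paste(x$wavelengths, collapse = "/"), "nm;",
      if (x$compensated) paste0("energy-compensated (", x$compensation, ")")
      else "uncompensated", "\n")
  invisible(x)
}
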