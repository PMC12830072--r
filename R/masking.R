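#' Masking configuration
#'
#' @param frangi_scales Gaussian scales (sigma, pixels) for the vesselness
#'   filter. The defaults 1-3 px match vessel radii of roughly 60-180 um at
#'   60 um pixel pitch.
#' @param frangi_threshold Threshold in (0, 1) applied to the min-max
#'   normalized vesselness map (default 0.1).
#' @param buffer_um Width of the safety buffer dilated around vessels, um
#'   (default 160, chosen to exceed the ~150 um range over which strong
#'   vascular absorption contaminates dermal photoacoustic signal).
#' @param pixel_pitch_um Pixel pitch, um.
#' @param reference_wavelength Wavelength (nm) of the image used for vessel
#'   detection; 545 nm is a hemoglobin isosbestic point, giving vessel
#'   contrast independent of oxygenation.
#' @return A `masking_config`.
#' @export
masking_config <- function(frangi_scales = c(1, 2, 3), frangi_threshold = 0.1,
                           buffer_um = 160, pixel_pitch_um = 60,
                           reference_wavelength = 545) {
  if (frangi_threshold <= 0 || frangi_threshold >= 1) {
    stop("frangi_threshold must lie in (0, 1)")
  }
  stopifnot(buffer_um >= 0, pixel_pitch_um > 0, all(frangi_scales > 0))
  structure(list(frangi_scales = frangi_scales,
                 frangi_threshold = frangi_threshold,
                 buffer_um = buffer_um, pixel_pitch_um = pixel_pitch_um,
                 reference_wavelength = reference_wavelength),
            class = "masking_config")
}

# Separable Gaussian smoothing with replicate padding.
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(M) {
    n <- nrow(M)
    P <- rbind(M[rep(1L, r), , drop = FALSE], M, M[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(M))
    for (i in seq_along(k)) {
      out <- out + k[i] * P[i:(i + n - 1L), , drop = FALSE]
    }
    out
  }
  t(smooth_axis(t(smooth_axis(img))))
}

#' Frangi vesselness of a 2-D image
#'
#' Hessian-eigenvalue vesselness for bright tubular structures on a dark
#' background. At each scale sigma the image is Gaussian-smoothed, the
#' scale-normalized Hessian (sigma^2 times second differences) is
#' eigen-decomposed, and pixels with `|lambda1| << |lambda2|`, `lambda2 < 0`
#' score highly:
#' `V = exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))`
#' with blobness `Rb = |lambda1| / |lambda2|` and structureness
#' `S = sqrt(lambda1^2 + lambda2^2)`. The response is maximized over scales
#' and min-max normalized to `[0, 1]`.
#'
#' @param img Numeric matrix.
#' @param scales Gaussian sigmas in pixels.
#' @param beta Blobness sensitivity (default 0.5).
#' @param c Structureness sensitivity; default half the maximum `S` at each
#'   scale.
#' @return Vesselness matrix in `[0, 1]` (all zeros for a constant image).
#' @export
frangi_vesselness <- function(img, scales = c(1, 2, 3), beta = 0.5, c = NULL) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  H <- nrow(img); W <- ncol(img)
  best <- matrix(0, H, W)
  for (s in scales) {
    G <- gaussian_blur(img, s)
    # replicate-padded central second differences
    up <- G[c(1L, seq_len(H - 1L)), ]; dn <- G[c(seq_len(H - 1L) + 1L, H), ]
    lf <- G[, c(1L, seq_len(W - 1L))]; rt <- G[, c(seq_len(W - 1L) + 1L, W)]
    Dxx <- s^2 * (up + dn - 2 * G)
    Dyy <- s^2 * (lf + rt - 2 * G)
    ul <- G[c(1L, seq_len(H - 1L)), c(1L, seq_len(W - 1L))]
    ur <- G[c(1L, seq_len(H - 1L)), c(seq_len(W - 1L) + 1L, W)]
    dl <- G[c(seq_len(H - 1L) + 1L, H), c(1L, seq_len(W - 1L))]
    dr <- G[c(seq_len(H - 1L) + 1L, H), c(seq_len(W - 1L) + 1L, W)]
    Dxy <- s^2 * (ul + dr - ur - dl) / 4
    tmp <- sqrt((Dxx - Dyy)^2 + 4 * Dxy^2)
    l1 <- (Dxx + Dyy + tmp) / 2
    l2 <- (Dxx + Dyy - tmp) / 2
    swap <- abs(l1) > abs(l2)
    h <- l1[swap]; l1[swap] <- l2[swap]; l2[swap] <- h
    Rb2 <- ifelse(l2 == 0, 0, (l1 / l2)^2)
    S2 <- l1^2 + l2^2
    cs <- c %||% (sqrt(max(S2)) / 2)
    V <- if (cs == 0) matrix(0, H, W) else {
      exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * cs^2)))
    }
    V[l2 > 0] <- 0
    best <- pmax(best, V)
  }
  rng <- range(best)
  if (rng[2] > rng[1]) (best - rng[1]) / (rng[2] - rng[1]) else best * 0
}

#' Compute a binary vessel mask from a spectral stack
#'
#' Applies the Frangi filter to the min-max normalized reference-wavelength
#' AUC image and thresholds the normalized vesselness map (strictly above
#' the threshold, so lowering the threshold never shrinks the mask).
#'
#' @param stack A `spectral_stack`.
#' @param config A [masking_config()].
#' @return Logical H x W matrix.
#' @export
compute_vessel_mask <- function(stack, config = masking_config()) {
  stopifnot(inherits(stack, "spectral_stack"), inherits(config, "masking_config"))
  l <- match(config$reference_wavelength, stack$wavelengths)
  if (is.na(l)) {
    stop("reference wavelength ", config$reference_wavelength,
         " nm not present in the stack")
  }
  img <- stack$auc[, , l]
  rng <- range(img)
  if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  v <- frangi_vesselness(img, scales = config$frangi_scales)
  v > config$frangi_threshold
}

# Euclidean disc structuring element of pixel radius r.
disc_kernel <- function(r) {
  d <- -r:r
  outer(d^2, d^2, `+`) <= r^2
}

#' Dilate a binary mask by a physical buffer width
#'
#' Morphological dilation with a Euclidean disc whose pixel radius is
#' `ceiling(buffer_um / pixel_pitch_um)` -- rounded up so the buffer is
#' never narrower than requested.
#'
#' @param mask Logical matrix.
#' @param buffer_um Buffer width, um.
#' @param pixel_pitch_um Pixel pitch, um.
#' @return Dilated logical matrix (a superset of `mask`).
#' @export
dilate_buffer <- function(mask, buffer_um, pixel_pitch_um) {
  stopifnot(is.matrix(mask), pixel_pitch_um > 0, buffer_um >= 0)
  mask <- mask != 0
  r <- ceiling(buffer_um / pixel_pitch_um)
  if (r == 0 || !any(mask)) return(mask)
  kern <- disc_kernel(r) + 0
  out <- EBImage::dilate(mask + 0, kern)
  matrix(out > 0.5, nrow(mask), ncol(mask))
}

#' Partition pixels into vessel, buffer and dermal regions
#'
#' The vessel core keeps the input mask; the buffer is the dilation minus
#' the core; the dermis is everything outside the dilated mask. Hemoglobin
#' is unmixed only in the core, collagen/melanin only in the dermis, and
#' buffer pixels are excluded from both models. The three masks are
#' pairwise disjoint and cover the grid (asserted on every call).
#'
#' @param vessel_mask Logical matrix.
#' @param config A [masking_config()] supplying `buffer_um` and
#'   `pixel_pitch_um`.
#' @return A `region_partition` list with logical matrices `vessel`,
#'   `buffer`, `dermal`.
#' @export
partition_regions <- function(vessel_mask, config = masking_config()) {
  stopifnot(is.matrix(vessel_mask))
  vessel <- vessel_mask != 0
  dilated <- dilate_buffer(vessel, config$buffer_um, config$pixel_pitch_um)
  buffer <- dilated & !vessel
  dermal <- !dilated
  stopifnot(!any(vessel & buffer), !any(vessel & dermal), !any(buffer & dermal),
            all(vessel | buffer | dermal))
  structure(list(vessel = vessel, buffer = buffer, dermal = dermal),
            class = "region_partition")
}
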