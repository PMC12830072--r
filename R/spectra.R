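#' Load the bundled chromophore spectral library
#'
#' The library tabulates absorption coefficients (and, where available,
#' scattering coefficients) of the six skin chromophores relevant to visible
#' photoacoustic microscopy -- oxyhemoglobin (`HbO2`), deoxyhemoglobin
#' (`Hb`), `collagen`, `melanin`, `lipid` and `water` -- at the four
#' excitation wavelengths 532, 545, 558 and 571 nm.
#'
#' The tabulation is a synthetic compilation: the 532 nm absorption values
#' and the collagen/melanin scattering columns are standard whole-tissue
#' literature values, while the remaining wavelengths follow standard
#' spectral shapes (near-isosbestic hemoglobin crossing at 545 nm, the Hb
#' absorption peak near 558 nm, the HbO2 alpha-band rise toward 571 nm, and
#' power-law melanin/collagen decay) calibrated so that the extinction-matrix
#' conditioning diagnostics of the two-chromophore unmixing models are
#' reproducible from the packaged file. See the methods vignette for the
#' construction.
#'
#' @param path Path to a library CSV with columns `chromophore`,
#'   `wavelength_nm`, `mu_a_mm_inv`, `mu_s_mm_inv`. Defaults to the
#'   packaged file.
#' @return A `spectral_library` data frame.
#' @export
#' @examples
#' lib <- spectral_library()
#' subset(lib, wavelength_nm == 532)
spectral_library <- function(path = system.file("extdata", "spectral_library.csv",
                                                package = "paunmix")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("spectral library file not found: ", path)
  }
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chromophore", "wavelength_nm", "mu_a_mm_inv", "mu_s_mm_inv")
  if (!all(need %in% names(lib))) {
    stop("spectral library must have columns: ", paste(need, collapse = ", "))
  }
  class(lib) <- c("spectral_library", "data.frame")
  lib
}

#' Extract one chromophore's spectrum from a library
#'
#' @param library A `spectral_library` (see [spectral_library()]).
#' @param name Chromophore identifier, e.g. `"Hb"`.
#' @return A `chromophore_spectrum` list with fields `name`, `wavelengths`
#'   (nm, strictly increasing), `mu_a` (mm^-1, strictly positive) and
#'   `mu_s` (mm^-1 or `NA` where untabulated).
#' @export
chromophore_spectrum <- function(library, name) {
  stopifnot(inherits(library, "spectral_library"), is.character(name),
            length(name) == 1L)
  rows <- library[library$chromophore == name, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("unknown chromophore: '", name, "'")
  }
  rows <- rows[order(rows$wavelength_nm), , drop = FALSE]
  spec <- structure(
    list(name = name,
         wavelengths = rows$wavelength_nm,
         mu_a = rows$mu_a_mm_inv,
         mu_s = rows$mu_s_mm_inv),
    class = "chromophore_spectrum")
  validate_chromophore_spectrum(spec)
  spec
}

validate_chromophore_spectrum <- function(spec) {
  if (length(spec$mu_a) != length(spec$wavelengths)) {
    stop("mu_a and wavelengths must have equal length")
  }
  if (any(diff(spec$wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (any(!is.finite(spec$mu_a)) || any(spec$mu_a <= 0)) {
    stop("mu_a values must be strictly positive")
  }
  invisible(spec)
}

#' Build an extinction matrix from the spectral library
#'
#' Arranges absorption coefficients into the wavelengths-by-chromophores
#' matrix `A` used by the per-pixel unmixing model `A x ~ b`. Entry (i, j)
#' is the absorption coefficient (mm^-1) of chromophore j at wavelength i.
#' No interpolation is performed: a wavelength absent from the library for
#' any requested chromophore is an error.
#'
#' @param library A `spectral_library`.
#' @param wavelengths Wavelengths in nm (matrix rows, in this order).
#' @param chromophores Chromophore names (matrix columns, in this order).
#' @return An `extinction_matrix`: a numeric matrix with `dimnames`
#'   recording the wavelengths and the chromophore order.
#' @export
#' @examples
#' lib <- spectral_library()
#' build_extinction_matrix(lib, c(532, 545, 558, 571), c("HbO2", "Hb"))
build_extinction_matrix <- function(library, wavelengths, chromophores) {
  stopifnot(inherits(library, "spectral_library"))
  if (length(chromophores) == 0L) stop("at least one chromophore is required")
  if (length(wavelengths) == 0L) stop("at least one wavelength is required")
  A <- matrix(NA_real_, nrow = length(wavelengths), ncol = length(chromophores),
              dimnames = list(as.character(wavelengths), chromophores))
  for (j in seq_along(chromophores)) {
    spec <- chromophore_spectrum(library, chromophores[j])
    idx <- match(wavelengths, spec$wavelengths)
    if (anyNA(idx)) {
      stop("wavelength(s) ", paste(wavelengths[is.na(idx)], collapse = ", "),
           " nm not tabulated for chromophore '", chromophores[j],
           "' (no interpolation is performed)")
    }
    A[, j] <- spec$mu_a[idx]
  }
  structure(A, class = c("extinction_matrix", class(A)))
}

#' 2-norm condition number of a matrix
#'
#' Ratio of the largest to the smallest singular value. Large values mean
#' measurement noise is strongly amplified when the matrix is inverted
#' during spectral unmixing; values above ~1000 are generally considered
#' problematic for stable inversion. A numerically rank-deficient matrix
#' returns `Inf` (not an error) so that feasibility reports can rank
#' candidate chromophore sets without exception handling.
#'
#' @param A A numeric matrix or `extinction_matrix`.
#' @return A scalar `>= 1`, or `Inf` for rank-deficient input.
#' @export
#' @examples
#' condition_number(diag(2)) # 1
condition_number <- function(A) {
  A <- unclass(A)
  stopifnot(is.matrix(A), length(A) > 0, all(is.finite(A)))
  s <- svd(A, nu = 0, nv = 0)$d
  tol <- max(dim(A)) * .Machine$double.eps * s[1]
  smin <- s[length(s)]
  if (s[1] == 0 || smin <= tol) return(Inf)
  s[1] / smin
}

#' Specify a Raman fiber for threshold calculation
#'
#' @param A_eff Effective mode area, m^2.
#' @param k_p Polarization factor, dimensionless in `[0.5, 1]`.
#' @param L_eff Effective fiber length, m.
#' @param g_R Raman gain coefficient, m/W.
#' @return A `raman_fiber_spec` list.
#' @export
raman_fiber_spec <- function(A_eff, k_p, L_eff, g_R) {
  vals <- c(A_eff = A_eff, k_p = k_p, L_eff = L_eff, g_R = g_R)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all fiber parameters must be strictly positive and finite")
  }
  if (k_p < 0.5 || k_p > 1) stop("k_p must lie in [0.5, 1]")
  structure(as.list(vals), class = "raman_fiber_spec")
}

#' Minimum peak power for stimulated Raman scattering in a fiber
#'
#' Closed-form single-mode-fiber threshold `P_th = 16 A_eff / (k_p L_eff g_R)`,
#' the standard analytic approximation in which the Stokes wave grows from
#' spontaneous Raman scattering with negligible pump depletion.
#'
#' @param spec A [raman_fiber_spec()].
#' @return Threshold peak power in W.
#' @export
raman_threshold <- function(spec) {
  stopifnot(inherits(spec, "raman_fiber_spec"))
  16 * spec$A_eff / (spec$k_p * spec$L_eff * spec$g_R)
}
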