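#' Specify a tissue phantom
#'
#' A phantom is a pixel grid covered by composition regions: a dermal
#' background and optional vessel tubes. Each region carries a chromophore
#' composition (fractions summing to 1) and an acoustic depth; vessels also
#' carry a true oxygen-saturation fraction used to split hemoglobin into
#' HbO2 and Hb.
#'
#' @param grid Integer vector `c(H, W)` in pixels.
#' @param pixel_pitch_um Pixel pitch in micrometres. The default 60 um
#'   corresponds to a 6 x 6 mm field scanned at 100 x 100 points.
#' @param regions List of region specs. A background region is
#'   `list(type = "background", composition = c(...), depth_um = ...)`;
#'   a vessel is `list(type = "vessel", centerline = 2-column matrix of
#'   (row, col) pixel endpoints, radius_um = ..., so2 = fraction in [0, 1],
#'   depth_um = ...)`. Vessel composition defaults to hemoglobin split by
#'   `so2`.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(64L, 64L), pixel_pitch_um = 60,
                         regions = list()) {
  stopifnot(length(grid) == 2L, all(grid >= 1), pixel_pitch_um > 0,
            length(regions) >= 1L)
  for (rg in regions) {
    type <- rg$type %||% "background"
    comp <- region_composition(rg)
    if (any(comp < 0)) stop("region composition fractions must be non-negative")
    if (abs(sum(comp) - 1) > 1e-8) {
      stop("region composition fractions must sum to 1 (got ",
           format(sum(comp)), ")")
    }
    if (type == "vessel") {
      if (is.null(rg$radius_um) || rg$radius_um <= 0) {
        stop("vessel radius_um must be > 0")
      }
      if (is.null(rg$so2) || rg$so2 < 0 || rg$so2 > 1) {
        stop("vessel so2 must be a fraction in [0, 1]")
      }
      cl <- rg$centerline
      if (is.null(cl) || ncol(cl) != 2L || nrow(cl) < 2L) {
        stop("vessel centerline must be a >=2-row matrix of (row, col) points")
      }
      if (any(cl < 1) || any(cl[, 1] > grid[1]) || any(cl[, 2] > grid[2])) {
        stop("vessel centerline must lie within the grid")
      }
    }
    if (is.null(rg$depth_um) || rg$depth_um <= 0) {
      stop("every region needs a positive depth_um")
    }
  }
  structure(list(grid = as.integer(grid), pixel_pitch_um = pixel_pitch_um,
                 regions = regions),
            class = "phantom_spec")
}

region_composition <- function(rg) {
  if (!is.null(rg$composition)) return(rg$composition)
  if (identical(rg$type, "vessel")) {
    return(c(HbO2 = rg$so2, Hb = 1 - rg$so2))
  }
  stop("region has no composition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a named phantom scenario
#'
#' `mixture_1`, `mixture_5`, `mixture_10` and `mixture_20` are uniform
#' dermal phantoms with melanin fractions of 1, 5, 10 and 20 percent
#' (collagen making up the remainder) -- the controlled collagen:melanin
#' compositions (99:1), (95:5), (90:10) and (80:20) used to validate the
#' dermal unmixing model. `vessel_demo` is a vascular scene with an
#' arteriole-like high-sO2 tube and a venule-like lower-sO2 tube over a
#' collagen-dominant dermis.
#'
#' @param scenario Scenario name, or an explicit [phantom_spec()] which is
#'   validated and returned unchanged.
#' @param grid Grid size for named scenarios (default 64 x 64 at 60 um
#'   pitch, i.e. a reduced-scale version of the full 6 x 6 mm field).
#' @param pixel_pitch_um Pixel pitch in um.
#' @param depth_um Acoustic path length from transducer to the absorbing
#'   layer (default 6 mm, a typical transducer standoff).
#' @return A `phantom_spec`.
#' @export
#' @examples
#' ph <- make_phantom("mixture_1")
#' ph$regions[[1]]$composition
make_phantom <- function(scenario, grid = c(64L, 64L), pixel_pitch_um = 60,
                         depth_um = 6000) {
  if (inherits(scenario, "phantom_spec")) return(scenario)
  stopifnot(is.character(scenario), length(scenario) == 1L)
  mixtures <- c(mixture_1 = 0.01, mixture_5 = 0.05,
                mixture_10 = 0.10, mixture_20 = 0.20)
  if (scenario %in% names(mixtures)) {
    mel <- unname(mixtures[scenario])
    return(phantom_spec(
      grid = grid, pixel_pitch_um = pixel_pitch_um,
      regions = list(list(type = "background",
                          composition = c(collagen = 1 - mel, melanin = mel),
                          depth_um = depth_um))))
  }
  if (scenario == "vessel_demo") {
    H <- grid[1]; W <- grid[2]
    r1 <- max(2L, round(H * 0.30)); r2 <- max(3L, round(H * 0.70))
    return(phantom_spec(
      grid = grid, pixel_pitch_um = pixel_pitch_um,
      regions = list(
        list(type = "background",
             composition = c(collagen = 0.99, melanin = 0.01),
             depth_um = depth_um),
        # arteriole-like: high sO2
        list(type = "vessel",
             centerline = cbind(c(r1, r1), c(2, W - 1L)),
             radius_um = 1.6 * pixel_pitch_um, so2 = 0.97,
             depth_um = depth_um),
        # venule-like: lower sO2
        list(type = "vessel",
             centerline = cbind(c(r2, r2), c(2, W - 1L)),
             radius_um = 2.1 * pixel_pitch_um, so2 = 0.70,
             depth_um = depth_um))))
  }
  stop("unknown scenario '", scenario, "'; expected one of mixture_1, ",
       "mixture_5, mixture_10, mixture_20, vessel_demo, or a phantom_spec")
}

#' Rasterize a phantom into per-pixel ground-truth maps
#'
#' Later regions overwrite earlier ones (vessels paint over the dermal
#' background). Vessel membership is decided by the Euclidean distance from
#' the pixel center to the centerline polyline, in micrometres.
#'
#' @param phantom A `phantom_spec`.
#' @return List with `fractions` (H x W x chromophore array), `depth_um`
#'   (H x W), `region` (H x W integer index into `phantom$regions`) and
#'   `so2` (H x W, `NA` outside vessels).
#' @export
rasterize_phantom <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_spec"))
  H <- phantom$grid[1]; W <- phantom$grid[2]
  chroms <- unique(unlist(lapply(phantom$regions,
                                 function(r) names(region_composition(r)))))
  frac <- array(0, dim = c(H, W, length(chroms)),
                dimnames = list(NULL, NULL, chroms))
  depth <- matrix(NA_real_, H, W)
  region <- matrix(NA_integer_, H, W)
  so2 <- matrix(NA_real_, H, W)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (i in seq_along(phantom$regions)) {
    rg <- phantom$regions[[i]]
    type <- rg$type %||% "background"
    inside <- if (type == "vessel") {
      d <- segment_distance(rows, cols, rg$centerline)
      d * phantom$pixel_pitch_um <= rg$radius_um
    } else {
      matrix(TRUE, H, W)
    }
    comp <- region_composition(rg)
    for (ch in chroms) frac[, , ch][inside] <- 0
    for (ch in names(comp)) frac[, , ch][inside] <- comp[[ch]]
    depth[inside] <- rg$depth_um
    region[inside] <- i
    so2[inside] <- if (type == "vessel") rg$so2 else NA_real_
  }
  list(fractions = frac, depth_um = depth, region = region, so2 = so2)
}

# Min distance (pixels) from each pixel center to a polyline of (row, col) points.
segment_distance <- function(rows, cols, centerline) {
  d <- matrix(Inf, nrow(rows), ncol(rows))
  for (k in seq_len(nrow(centerline) - 1L)) {
    p <- centerline[k, ]; q <- centerline[k + 1L, ]
    v <- q - p
    len2 <- sum(v^2)
    if (len2 == 0) {
      dk <- sqrt((rows - p[1])^2 + (cols - p[2])^2)
    } else {
      t <- ((rows - p[1]) * v[1] + (cols - p[2]) * v[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      dk <- sqrt((rows - (p[1] + t * v[1]))^2 + (cols - (p[2] + t * v[2]))^2)
    }
    d <- pmin(d, dk)
  }
  d
}

#' Specify acquisition parameters for the forward simulator
#'
#' Defaults mirror the imaging system being emulated: four excitation
#' wavelengths at 532/545/558/571 nm, 4096 samples per A-line, a 2.25 MHz
#' center-frequency transducer with 66 percent fractional bandwidth, and a
#' 1500 m/s speed of sound. The 10 ns sampling interval gives a 40.96 us
#' record covering several centimetres of acoustic path.
#'
#' @param wavelengths Excitation wavelengths, nm.
#' @param samples_per_aline Samples per A-line.
#' @param sampling_interval_ns Digitizer sampling interval, ns.
#' @param pulse_energies_uJ Nominal pulse energy per wavelength, uJ.
#' @param energy_jitter Relative pulse-to-pulse energy jitter (multiplicative
#'   Gaussian sigma; default 2 percent).
#' @param transducer_center_freq_mhz Transducer center frequency, MHz.
#' @param fractional_bandwidth_pct Transducer fractional bandwidth (FWHM of
#'   the magnitude spectrum as a percent of the center frequency).
#' @param speed_of_sound Speed of sound, m/s.
#' @param noise_sigma Additive Gaussian noise sigma, relative to the maximum
#'   clean amplitude of the simulated record. The default 1e-4 models a
#'   noise floor of a few LSB of a 16-bit digitizer: dermal absorbers sit roughly
#'   three orders of magnitude below blood, so a noise floor much above
#'   this leaves no single-shot dermal signal to analyze.
#' @param bit_depth `NULL` for continuous amplitudes, or an integer (e.g.
#'   16) for uniform mid-rise quantization.
#' @param seed Integer seed driving all randomness in the simulator.
#' @return An `acquisition_spec`.
#' @export
acquisition_spec <- function(wavelengths = c(532, 545, 558, 571),
                             samples_per_aline = 4096L,
                             sampling_interval_ns = 10,
                             pulse_energies_uJ = rep(1, length(wavelengths)),
                             energy_jitter = 0.02,
                             transducer_center_freq_mhz = 2.25,
                             fractional_bandwidth_pct = 66,
                             speed_of_sound = 1500,
                             noise_sigma = 1e-4,
                             bit_depth = NULL,
                             seed = 1L) {
  stopifnot(samples_per_aline > 0, sampling_interval_ns > 0,
            length(pulse_energies_uJ) == length(wavelengths),
            all(pulse_energies_uJ > 0), energy_jitter >= 0,
            transducer_center_freq_mhz > 0, speed_of_sound > 0,
            noise_sigma >= 0)
  if (fractional_bandwidth_pct <= 0 || fractional_bandwidth_pct >= 200) {
    stop("fractional bandwidth must lie in (0, 200) percent")
  }
  if (!is.null(bit_depth)) {
    stopifnot(bit_depth >= 2, bit_depth <= 32)
    bit_depth <- as.integer(bit_depth)
  }
  structure(list(wavelengths = wavelengths,
                 samples_per_aline = as.integer(samples_per_aline),
                 sampling_interval_ns = sampling_interval_ns,
                 pulse_energies_uJ = pulse_energies_uJ,
                 energy_jitter = energy_jitter,
                 transducer_center_freq_mhz = transducer_center_freq_mhz,
                 fractional_bandwidth_pct = fractional_bandwidth_pct,
                 speed_of_sound = speed_of_sound,
                 noise_sigma = noise_sigma,
                 bit_depth = bit_depth,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}
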