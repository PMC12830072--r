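#' Default pipeline configuration
#'
#' Nested configuration for the end-to-end pipeline. Section defaults
#' carry the standard acquisition and analysis parameters: wavelengths
#' 532/545/558/571 nm, 4096-sample A-lines, 2.25 MHz / 66 percent
#' transducer, Frangi threshold 0.1, 160 um vessel buffer, loss weights
#' 0.6/0.4, learning rate 1e-4 and batch size 32 for the full denoiser
#' protocol.
#'
#' @return A `pipeline_config` (nested named list).
#' @export
pipeline_config <- function() {
  structure(list(
    seed = 1L,
    output_dir = "paunmix_run",
    log_level = "info",
    phantom = list(scenario = "vessel_demo", grid = c(64L, 64L),
                   pixel_pitch_um = 60),
    acquisition = list(wavelengths = c(532, 545, 558, 571),
                       samples_per_aline = 4096L,
                       sampling_interval_ns = 10,
                       pulse_energies_uJ = c(1, 1, 1, 1),
                       energy_jitter = 0.02,
                       transducer_center_freq_mhz = 2.25,
                       fractional_bandwidth_pct = 66,
                       speed_of_sound = 1500,
                       noise_sigma = 1e-4,
                       bit_depth = "none"),
    denoiser = list(enabled = FALSE, n_pairs = 500L, n_average = 150L,
                    epochs = 15L, learning_rate = 1e-3),
    reconstruction = list(background_window = 256L, compensation = "mean"),
    masking = list(frangi_scales = c(1, 2, 3), frangi_threshold = 0.1,
                   buffer_um = 160, reference_wavelength = 545),
    regularization = list(selection = "l_curve", lambda = 0,
                          per_pixel = FALSE),
    validation = list(melanin_pct = c(1, 5, 10, 20), noise_sigma = 0,
                      bit_depth = "none")),
    class = "pipeline_config")
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", here)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        stop("configuration section '", here, "' must be a mapping")
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], here)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  m <- cfg$masking
  if (m$frangi_threshold <= 0 || m$frangi_threshold >= 1) {
    stop("masking.frangi_threshold must lie in (0, 1)")
  }
  if (m$buffer_um < 0) stop("masking.buffer_um must be >= 0")
  a <- cfg$acquisition
  if (length(a$pulse_energies_uJ) != length(a$wavelengths)) {
    stop("acquisition.pulse_energies_uJ must match acquisition.wavelengths")
  }
  if (!cfg$regularization$selection %in% c("l_curve", "fixed")) {
    stop("regularization.selection must be 'l_curve' or 'fixed'")
  }
  required <- c("phantom", "acquisition", "reconstruction", "masking",
                "regularization")
  missing <- required[!required %in% names(cfg)]
  if (length(missing)) {
    stop("configuration is missing section(s): ", paste(missing, collapse = ", "))
  }
  invisible(cfg)
}

#' Parse a pipeline configuration file
#'
#' Reads a YAML file, fills unset keys with the defaults of
#' [pipeline_config()], rejects unknown keys (with the offending path),
#' and validates parameter ranges. An empty file yields the all-defaults
#' configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated `pipeline_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  if (!is.null(user)) {
    if (!is.list(user)) stop("configuration must be a YAML mapping")
    cfg <- merge_config(unclass(cfg), user)
    class(cfg) <- "pipeline_config"
  }
  validate_config(cfg)
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' Round-trips losslessly through [parse_config()].
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Deterministic per-stage child seeds so that toggling one stage does not
# perturb another stage's randomness.
child_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, pairs = 211L, train = 307L, mask = 401L,
            unmix = 503L)
  as.integer((as.numeric(seed) * 48271 + offs[[stage]]) %% 2147483647)
}

# "none" is the YAML-safe spelling of a missing bit depth (NULL entries do
# not survive a YAML round trip).
bits_from_config <- function(b) {
  if (is.null(b) || identical(b, "none")) NULL else as.integer(b)
}

acq_from_config <- function(cfg, seed) {
  a <- cfg$acquisition
  acquisition_spec(wavelengths = a$wavelengths,
                   samples_per_aline = a$samples_per_aline,
                   sampling_interval_ns = a$sampling_interval_ns,
                   pulse_energies_uJ = a$pulse_energies_uJ,
                   energy_jitter = a$energy_jitter,
                   transducer_center_freq_mhz = a$transducer_center_freq_mhz,
                   fractional_bandwidth_pct = a$fractional_bandwidth_pct,
                   speed_of_sound = a$speed_of_sound,
                   noise_sigma = a$noise_sigma,
                   bit_depth = bits_from_config(a$bit_depth),
                   seed = seed)
}

#' Write image planes as a float TIFF with a YAML sidecar
#'
#' Each plane is affinely rescaled to `[0, 1]` for storage (the TIFF
#' writer's defined range) and the original `(min, max)` per plane is
#' recorded in the sidecar so [read_image_stack()] restores the values.
#' `NA` pixels are stored as the plane minimum and their positions recorded.
#'
#' @param planes Named list of numeric matrices.
#' @param path Output TIFF path; the sidecar is `<path>.yml`.
#' @param meta Extra metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(planes, path, meta = list()) {
  ranges <- list()
  pages <- vector("list", length(planes))
  for (i in seq_along(planes)) {
    m <- planes[[i]]
    na_idx <- which(is.na(m))
    vals <- m[is.finite(m)]
    lo <- if (length(vals)) min(vals) else 0
    hi <- if (length(vals)) max(vals) else 0
    m[na_idx] <- lo
    pages[[i]] <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
    ranges[[i]] <- list(name = names(planes)[i] %||% paste0("plane", i),
                        min = lo, max = hi, na = as.integer(na_idx))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(c(list(planes = ranges), meta), paste0(path, ".yml"))
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path (sidecar `<path>.yml` must be present).
#' @return Named list of numeric matrices.
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- yaml::read_yaml(paste0(path, ".yml"))
  out <- list()
  for (i in seq_along(pages)) {
    r <- side$planes[[i]]
    m <- pages[[i]] * (r$max - r$min) + r$min
    if (length(r$na)) m[r$na] <- NA_real_
    out[[r$name]] <- m
  }
  out
}

#' Run the full analysis pipeline
#'
#' Simulate (or reuse) a raw frame set, optionally train and apply the
#' denoiser, reconstruct the energy-compensated spectral stack, compute
#' the vessel mask and region partition, unmix, and derive the functional
#' maps. Writes `stack.tif`, `masks.tif`, `maps.tif` (each with a YAML
#' sidecar), `manifest.yml` and `log.txt` into the configured output
#' directory. Identical configuration and seed give identical numeric
#' outputs.
#'
#' @param config A `pipeline_config` (see [pipeline_config()] /
#'   [parse_config()]).
#' @param frames Optional pre-simulated `raw_frameset` (skips simulation).
#' @return Invisible list with `frames`, `stack`, `partition`, `maps`,
#'   `so2`, `relative`, `manifest`, `output_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), frames = NULL) {
  validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$output_dir, "log.txt")
  t_all <- Sys.time()
  timings <- list()
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    if (config$log_level != "quiet") message(msg)
    cat(msg, "\n", file = logfile, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    log_line("stage ", name, " done in ", sprintf("%.2f s", timings[[name]]))
    out
  }

  if (is.null(frames)) {
    frames <- stage("simulate", {
      phantom <- make_phantom(config$phantom$scenario,
                              grid = config$phantom$grid,
                              pixel_pitch_um = config$phantom$pixel_pitch_um)
      simulate_frameset(phantom,
                        acq_from_config(config, child_seed(config$seed, "simulate")))
    })
  }

  model <- NULL
  if (isTRUE(config$denoiser$enabled)) {
    model <- stage("denoise_train", {
      dcfg <- config$denoiser
      acq <- acq_from_config(config, child_seed(config$seed, "pairs"))
      pairs <- make_training_pairs(frames$phantom, acq,
                                   n_pairs = dcfg$n_pairs,
                                   n_average = dcfg$n_average)
      train_denoiser(pairs,
                     denoiser_config(input_size = acq$samples_per_aline),
                     reduced_training_config(
                       epochs = dcfg$epochs,
                       learning_rate = dcfg$learning_rate,
                       seed = child_seed(config$seed, "train")))
    })
  }

  stack <- stage("reconstruct", {
    build_spectral_stack(frames,
                         background_window = config$reconstruction$background_window,
                         denoiser = model,
                         compensation = config$reconstruction$compensation)
  })

  partition <- stage("mask", {
    mcfg <- masking_config(frangi_scales = config$masking$frangi_scales,
                           frangi_threshold = config$masking$frangi_threshold,
                           buffer_um = config$masking$buffer_um,
                           pixel_pitch_um = config$phantom$pixel_pitch_um,
                           reference_wavelength = config$masking$reference_wavelength)
    partition_regions(compute_vessel_mask(stack, mcfg), mcfg)
  })

  maps <- stage("unmix", {
    reg <- regularization_config(selection = config$regularization$selection,
                                 lambda = config$regularization$lambda,
                                 per_pixel = config$regularization$per_pixel)
    split_unmix(stack, partition, reg = reg)
  })

  so2 <- compute_so2(maps)
  rel <- compute_relative(maps)

  stage("write", {
    nlam <- length(stack$wavelengths)
    stack_planes <- lapply(seq_len(nlam), function(l) stack$auc[, , l])
    names(stack_planes) <- paste0("auc_", stack$wavelengths, "nm")
    write_image_stack(stack_planes, file.path(config$output_dir, "stack.tif"),
                      meta = list(wavelengths_nm = stack$wavelengths,
                                  mean_energies_uJ = stack$mean_energies_uJ,
                                  compensation = stack$compensation))
    # 0/1/2 region coding: vessel / buffer / dermal
    region_code <- partition$buffer * 1 + partition$dermal * 2
    write_image_stack(list(region = region_code),
                      file.path(config$output_dir, "masks.tif"),
                      meta = list(coding = "0=vessel, 1=buffer, 2=dermal"))
    write_image_stack(list(HbO2 = maps$HbO2, Hb = maps$Hb,
                           collagen = maps$collagen, melanin = maps$melanin,
                           so2_pct = so2,
                           collagen_rel_pct = rel$collagen_rel,
                           melanin_rel_pct = rel$melanin_rel),
                      file.path(config$output_dir, "maps.tif"))
    TRUE
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("paunmix")),
    seed = config$seed,
    config = unclass(config),
    stage_seconds = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t_all, units = "secs")))
  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yml"))
  log_line("pipeline finished in ", sprintf("%.2f s", manifest$total_seconds))

  invisible(list(frames = frames, stack = stack, partition = partition,
                 maps = maps, so2 = so2, relative = rel,
                 manifest = manifest, output_dir = config$output_dir))
}
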