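#' Write a stack as multi-page TIFF plus sidecar JSON
#'
#' One TIFF page per plane. Because TIFF stores normalised samples here,
#' the data are scaled before writing -- by 65535 for `"uint16"` stacks and
#' by a power of two (recorded in the sidecar, so the float32 round trip is
#' exact) for `"float32"` stacks. The sidecar JSON (`<path>.json`) is
#' authoritative for spacing, origin, frame tag, dtype, scale and
#' acquisition geometry; pixel data alone cannot carry the scan mode.
#'
#' @param stack A [volume_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "volume_stack"))
  d <- dim(stack$data)
  if (stack$dtype == "uint16") {
    vals <- round(pmin(pmax(stack$data, 0), 65535))
    scale <- 65535
    bits <- 16L
  } else {
    scale <- 2^max(0, ceiling(log2(max(abs(stack$data), 1e-12))))
    vals <- stack$data
    bits <- 32L
  }
  pages <- lapply(seq_len(d[1]), function(k)
    matrix(vals[k, , ] / scale, nrow = d[2], ncol = d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  meta <- list(
    format_version = 1L,
    tool = "mesodeskew",
    tool_version = as.character(utils::packageVersion("mesodeskew")),
    dim = d, spacing_um = stack$spacing_um, origin_um = stack$origin_um,
    frame = stack$frame, dtype = stack$dtype, scale = scale,
    geometry = if (!is.null(stack$geometry)) unclass(stack$geometry) else NULL)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' Restores voxel data, spacing, origin, frame tag and geometry. Without a
#' sidecar JSON the voxel spacing must be supplied; colour (RGB) TIFFs are
#' rejected.
#'
#' @param path TIFF path.
#' @param spacing_um Voxel spacing override / fallback when no sidecar
#'   exists.
#' @return A [volume_stack()].
#' @export
read_stack <- function(path, spacing_um = NULL) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else NULL
  if (is.null(meta) && is.null(spacing_um))
    stop("no sidecar JSON found for ", path,
         "; voxel spacing must be supplied")
  dtype <- meta$dtype %||% "float32"
  pages <- tiff::readTIFF(path, all = TRUE, as.is = (dtype == "uint16"))
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) > 2L)
    stop("multi-channel (RGB) TIFF not supported; expected grayscale pages")
  scale <- meta$scale %||% 1
  d <- c(length(pages), dim(pages[[1]]))
  arr <- array(0, d)
  for (k in seq_along(pages))
    arr[k, , ] <- if (dtype == "uint16") pages[[k]] else pages[[k]] * scale
  geom <- NULL
  if (!is.null(meta$geometry)) {
    g <- meta$geometry
    geom <- acquisition_geometry(g$theta_deg, g$z_step_um, g$pixel_pitch_um,
                                 g$scan_mode, g$scan_sign,
                                 g$n_frames %||% NA_integer_)
  }
  volume_stack(arr,
               spacing_um = spacing_um %||% meta$spacing_um,
               origin_um = meta$origin_um %||% c(0, 0, 0),
               frame = meta$frame %||% "lab_raw",
               geometry = geom, dtype = dtype)
}

run_config_known_keys <- c("geometry", "optics", "phantom", "psf", "noise",
                           "analysis", "output", "seed")

#' Read and validate a pipeline configuration
#'
#' YAML (or JSON) configuration with blocks `geometry`, `optics`, `phantom`,
#' `psf`, `noise`, `analysis`, `output` and a mandatory top-level `seed`.
#' Unknown top-level keys are rejected. The blocks are converted to the
#' package's typed objects, so invalid values fail here rather than
#' mid-pipeline.
#'
#' @param path Path to a YAML file, or a pre-parsed list.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), run_config_known_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("configuration must set a seed")
  if (is.null(cfg$geometry)) stop("configuration must contain a geometry block")
  g <- cfg$geometry
  make_geom <- function(mode) acquisition_geometry(
    g$theta_deg %||% 45, g$z_step_um %||% 1, g$pixel_pitch_um %||% 1.31,
    mode, g$scan_sign %||% 1L, g$n_frames %||% NA_integer_)
  modes <- g$scan_mode %||% c("standard_shear", "oblique_comp")
  ph <- cfg$phantom %||% list()
  ps <- cfg$psf %||% list()
  no <- cfg$noise
  an <- cfg$analysis %||% list()
  list(
    seed = as.integer(cfg$seed),
    geometries = lapply(modes, make_geom),
    optics = do.call(optics_spec, cfg$optics %||% list()),
    phantom = phantom_spec(
      kind = ph$kind %||% "beads",
      n_objects = ph$n_objects %||% 100L,
      bounds_um = unlist(ph$bounds_um %||% c(150, 100, 40)),
      bead_diameter_um = ph$bead_diameter_um %||% 1,
      nuclei_fwhm_range_um = unlist(ph$nuclei_fwhm_range_um %||% c(5, 15)),
      orientation = ph$orientation %||% "aligned",
      intensity = ph$intensity %||% 1000,
      seed = ph$seed %||% cfg$seed),
    psf = psf_model(
      sigma_x_um = ps$sigma_x_um %||% 2,
      sigma_y_um = ps$sigma_y_um %||% 2.4,
      sigma_z_um = ps$sigma_z_um %||% 3.7,
      astigmatism_delta = ps$astigmatism_delta %||% 1,
      mode_axial_inflation = ps$mode_axial_inflation %||% 1),
    noise = if (!is.null(no)) noise_model(
      photon_scale = no$photon_scale %||% Inf,
      read_sigma = no$read_sigma %||% 0,
      offset = no$offset %||% 0,
      seed = no$seed %||% (cfg$seed + 1L)) else NULL,
    analysis = list(
      r2_threshold = an$r2_threshold %||% 0.95,
      min_separation_um = an$min_separation_um %||% 10,
      window_factor = an$window_factor %||% 6,
      intensity_threshold = an$intensity_threshold %||% NULL,
      axial_limit_standard_um = an$axial_limit_standard_um %||% 13.15,
      axial_limit_oblique_um = an$axial_limit_oblique_um %||% 8.72),
    output = cfg$output %||% list()
  )
}

#' Run the demonstration pipeline
#'
#' End-to-end run driven by a single configuration: phantom generation,
#' simulated acquisition under each configured scan mode, reconstruction,
#' bead detection / FWHM measurement / cohort summary, and the overhead
#' report. Every artifact is stamped with the configuration hash and the
#' package version; the run is deterministic for a fixed seed.
#'
#' @param config A `run_config` from [read_run_config()] (or a path / list
#'   accepted by it).
#' @param out_dir Output directory for artifacts (created if needed); when
#'   `NULL`, nothing is written and results are only returned.
#' @return A list per mode with the raw stack, reconstruction, bead fits,
#'   summary and overhead report, plus the artifact manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!is.list(config) || is.null(config$geometries))
    config <- read_run_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(config[c("seed", "analysis")],
                               auto_unbox = TRUE, force = TRUE)
  stamp <- list(
    tool = "mesodeskew",
    tool_version = as.character(utils::packageVersion("mesodeskew")),
    config_hash = config_hash(config),
    seed = config$seed)
  phantom <- make_phantom(config$phantom)
  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  note("phantom: %d %s objects", nrow(phantom), config$phantom$kind)
  results <- list()
  for (geom in config$geometries) {
    mode <- geom$scan_mode
    raw <- acquire(phantom, config$psf, geom, noise = config$noise)
    rec <- if (mode == "standard_shear") deskew_standard(raw)
           else reconstruct_oblique(raw)
    note("%s: raw %s -> reconstructed %s", mode,
         paste(dim(raw$data), collapse = "x"),
         paste(dim(rec$volume$data), collapse = "x"))
    an <- config$analysis
    thr <- an$intensity_threshold %||% (0.2 * max(rec$volume$data))
    centers <- detect_beads(rec$volume, an$min_separation_um, thr)
    exp_fwhm <- fwhm_from_sigma(c(config$psf$sigma_z_um, config$psf$sigma_y_um,
                                  config$psf$sigma_x_um))
    fits <- measure_beads(rec$volume, centers,
                          window_um = an$window_factor * exp_fwhm,
                          r2_threshold = an$r2_threshold)
    summ <- if (!is.null(fits) && any(fits$accepted))
      summarize_fwhm(fits) else NULL
    crop_n <- if (!is.null(rec$crop)) diff(rec$crop$col) + 1L else NULL
    ov <- predict_shapes(geom, dim(raw$data), crop_cols = crop_n,
                         origin_um = if (!is.null(crop_n))
                           raw$origin_um +
                             c(0, 0, rec$crop$col[1] * raw$spacing_um[3])
                         else raw$origin_um,
                         bytes_voxel = bytes_per_voxel(raw$dtype))
    note("%s: %d beads detected, %d accepted; size factor %.3f", mode,
         nrow(centers), if (is.null(fits)) 0L else sum(fits$accepted),
         ov$size_factor)
    if (!is.null(out_dir)) {
      tag <- sub("_.*", "", mode)
      write_stack(raw, file.path(out_dir, paste0("raw_", tag, ".tif")))
      write_stack(rec$volume,
                  file.path(out_dir, paste0("sample_", tag, ".tif")))
      if (!is.null(fits))
        utils::write.csv(cbind(fits, mode = mode, stamp["config_hash"]),
                         file.path(out_dir, paste0("fits_", tag, ".csv")),
                         row.names = FALSE)
      report <- c(stamp, list(mode = mode,
                              raw_bytes = ov$raw_bytes,
                              final_bytes = ov$final_bytes,
                              size_factor = ov$size_factor,
                              padding_fraction = ov$padding_fraction))
      jsonlite::write_json(report,
                           file.path(out_dir, paste0("overhead_", tag, ".json")),
                           auto_unbox = TRUE, digits = NA)
      if (!is.null(summ))
        jsonlite::write_json(c(stamp, list(
          mode = mode, per_dimension = summ$per_dimension,
          anisotropy = summ$anisotropy)),
          file.path(out_dir, paste0("summary_", tag, ".json")),
          auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    results[[mode]] <- list(raw = raw, reconstruction = rec,
                            detections = centers, fits = fits,
                            summary = summ, overhead = ov)
  }
  if (!is.null(out_dir)) {
    utils::write.csv(phantom, file.path(out_dir, "phantom_truth.csv"),
                     row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  c(results, list(phantom = phantom, stamp = stamp, log = log_lines))
}

# Stable hash of the configuration: md5 of its canonical JSON serialisation.
config_hash <- function(config) {
  keep <- config[setdiff(names(config), "output")]
  js <- jsonlite::toJSON(keep, auto_unbox = TRUE, force = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(js, f)
  unname(tools::md5sum(f))
}
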