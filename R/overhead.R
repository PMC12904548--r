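#' Predict reconstruction shapes and data-size overhead
#'
#' Closed-form accounting of raw versus reconstructed data sizes for either
#' scan mode, decoupled from actual resampling but guaranteed to agree with
#' it: shapes come from the same [build_affine()] bounding-box computation
#' the reconstruction pipelines use. The standard-shear path transforms the
#' full, uncroppable raw stack (the skewed acquisition leaves non-trivial
#' empty wedges that only the affine step untangles); the oblique path may
#' crop content-free camera-x columns first.
#'
#' @param geom An [acquisition_geometry()]; its `scan_mode` selects the path.
#' @param raw_shape Integer triple (frames, rows, cols) of the raw stack.
#' @param crop_cols Optional number of camera-x columns retained before the
#'   affine step (oblique mode only). A value in (0, 1] is interpreted as a
#'   fraction of the raw column count.
#' @param origin_um Raw-stack origin (see [raw_index_to_sample()]); pass the
#'   origin of the *cropped* stack when matching an actual cropped
#'   reconstruction.
#' @param bytes_voxel Bytes per voxel (default 2, 16-bit).
#' @param out_pitch_um Output pitch override, see [build_affine()].
#' @return An `overhead_report`: `mode`, `raw_bytes`, `final_bytes`,
#'   `size_factor` (final / raw), `padding_fraction`, a per-step
#'   `shape_trace`, and for the standard path `padded_bytes_after_shear_step`
#'   (the intermediate stack size once the per-frame drift has been padded
#'   out, before rotation).
#' @export
predict_shapes <- function(geom, raw_shape, crop_cols = NULL,
                           origin_um = c(0, 0, 0), bytes_voxel = 2,
                           out_pitch_um = NULL) {
  stopifnot(inherits(geom, "acquisition_geometry"))
  raw_shape <- as.integer(raw_shape)
  stopifnot(length(raw_shape) == 3L, all(raw_shape > 0L))
  raw_bytes <- prod(as.numeric(raw_shape)) * bytes_voxel
  trace <- list(raw = raw_shape)
  work_shape <- raw_shape
  padded_bytes <- NULL
  if (geom$scan_mode == "standard_shear") {
    if (!is.null(crop_cols))
      stop("standard shear stacks cannot be cropped before the affine step")
    drift_pix <- (raw_shape[1] - 1) * geom$z_step_um * tan(theta_rad(geom)) /
      geom$pixel_pitch_um
    sheared <- c(raw_shape[1], raw_shape[2], raw_shape[3] + ceiling(drift_pix))
    trace$padded_shear <- sheared
    padded_bytes <- prod(as.numeric(sheared)) * bytes_voxel
  } else if (!is.null(crop_cols)) {
    nc <- if (crop_cols > 0 && crop_cols <= 1) ceiling(crop_cols * raw_shape[3])
          else as.integer(crop_cols)
    stopifnot(nc >= 1L, nc <= raw_shape[3])
    work_shape <- c(raw_shape[1], raw_shape[2], nc)
    trace$cropped <- work_shape
  }
  tr <- build_affine(geom, work_shape, origin_um = origin_um,
                     out_pitch_um = out_pitch_um)
  trace$final <- tr$output_shape
  final_bytes <- prod(as.numeric(tr$output_shape)) * bytes_voxel
  structure(list(
    mode = geom$scan_mode,
    raw_bytes = raw_bytes,
    padded_bytes_after_shear_step = padded_bytes,
    final_bytes = final_bytes,
    size_factor = final_bytes / raw_bytes,
    padding_fraction = tr$padding_fraction,
    shape_trace = trace,
    transform = tr
  ), class = "overhead_report")
}

#' @export
print.overhead_report <- function(x, ...) {
  cat(sprintf("overhead_report (%s): size factor %.3f, padding %.1f%%\n",
              x$mode, x$size_factor, 100 * x$padding_fraction))
  for (nm in names(x$shape_trace))
    cat(sprintf("  %-14s %s\n", nm,
                paste(x$shape_trace[[nm]], collapse = " x ")))
  invisible(x)
}

#' Ratio of final to raw data size
#'
#' @param raw_bytes,final_bytes Byte counts; `raw_bytes` must be positive.
#' @return `final_bytes / raw_bytes`.
#' @export
size_factor <- function(raw_bytes, final_bytes) {
  if (raw_bytes <= 0) stop("raw_bytes must be positive")
  final_bytes / raw_bytes
}

tile_count_1d <- function(extent, fov, overlap) {
  if (extent <= fov) return(1L)
  as.integer(ceiling((extent - fov) / (fov * (1 - overlap)))) + 1L
}

#' Plan a tiled acquisition
#'
#' Minimal tile counts covering a sample larger than one field of view,
#' with step `fov * (1 - overlap)`. The tiled axes depend on the scan mode:
#' the standard shear acquisition of a tilted slice must tile the in-plane
#' x' extent as coupled x-z tiles (both laboratory axes move, each with the
#' stated overlap), whereas the oblique compensation scan covers the whole
#' x' extent in a single sweep -- it never tiles x' -- and only the shared y
#' axis may need tiles.
#'
#' @param sample_extent_mm Named or positional extents `c(xp = ..., y = ...)`
#'   of the slice in millimetres (a single value is taken as the x' extent
#'   with a y extent within one field).
#' @param fov_mm Field of view per tile (mm).
#' @param overlap_fraction Overlap between adjacent tiles, in `[0, 0.5)`.
#' @param mode `"standard_shear"` or `"oblique_comp"`.
#' @return A `tile_layout`: per-axis tile `counts`, `n_tiles` (their
#'   product), `step_mm`, per-axis `offsets_mm` and the `tiled_axes` label.
#' @export
tiling_plan <- function(sample_extent_mm, fov_mm, overlap_fraction = 0.10,
                        mode = c("oblique_comp", "standard_shear")) {
  mode <- match.arg(mode)
  if (overlap_fraction < 0 || overlap_fraction >= 0.5)
    stop("overlap_fraction must lie in [0, 0.5)")
  stopifnot(fov_mm > 0, all(sample_extent_mm > 0))
  ext <- if (length(sample_extent_mm) == 1L)
    c(xp = unname(sample_extent_mm), y = fov_mm) else
    c(xp = unname(sample_extent_mm[1]), y = unname(sample_extent_mm[2]))
  step <- fov_mm * (1 - overlap_fraction)
  n_y <- tile_count_1d(ext["y"], fov_mm, overlap_fraction)
  n_xp <- tile_count_1d(ext["xp"], fov_mm, overlap_fraction)
  counts <- if (mode == "oblique_comp") c(xp = 1L, y = n_y)
            else c(xp = n_xp, y = n_y)
  offsets <- lapply(counts, function(n) (seq_len(n) - 1) * step)
  structure(list(mode = mode, counts = counts,
                 n_tiles = prod(counts),
                 overlap_fraction = overlap_fraction,
                 step_mm = step, fov_mm = fov_mm,
                 extent_mm = ext, offsets_mm = offsets,
                 tiled_axes = if (mode == "oblique_comp") "y"
                              else "x' (as coupled x-z tiles) and y"),
            class = "tile_layout")
}

#' @export
print.tile_layout <- function(x, ...) {
  cat(sprintf("tile_layout (%s): %s tiles (x' %d, y %d), step %.3g mm, overlap %g%%\n",
              x$mode, x$n_tiles, x$counts["xp"], x$counts["y"], x$step_mm,
              100 * x$overlap_fraction))
  invisible(x)
}
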