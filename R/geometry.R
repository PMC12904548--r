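#' Acquisition geometry for an obliquely mounted slice
#'
#' Describes a stage-scanned light-sheet acquisition of a thin slice mounted
#' at an angle `theta_deg` between the sample plane and the detection axis.
#' Two scan modes are supported:
#'
#' * `"standard_shear"`: the stage moves only along the detection axis
#'   (z); slice content drifts across the camera by `z_step_um * tan(theta)`
#'   micrometres per frame and the raw stack is sheared.
#' * `"oblique_comp"`: a compensating lateral motion
#'   `x_s = scan_sign * n * z_step_um * tan(theta)` is added so that the
#'   slice stays centred on the camera; the raw stack needs only cropping,
#'   a 90-degree reorientation, one scaling and one shear to land in sample
#'   coordinates.
#'
#' Coordinate conventions used throughout the package: the laboratory frame
#' is (x = camera horizontal, y = camera vertical, z = detection axis) with
#' the light sheet at z = 0; the sample frame is (x' in-plane along the
#' slide, y shared, z' normal to the slide). The (x, z) components of the
#' two frames are related by the orthogonal, self-inverse block
#' `S = [[sin(theta), cos(theta)], [cos(theta), -sin(theta)]]`, applied to
#' stage-corrected lab coordinates. With `scan_sign = +1` the compensated
#' scan keeps every sample point at fixed camera x (the centring property);
#' `scan_sign = -1` corresponds to a camera whose x axis runs against the
#' stage x axis.
#'
#' @param theta_deg Mounting angle in degrees, in (0, 90]; strictly below
#'   90 in `"oblique_comp"` mode, where the compensating step diverges at
#'   perpendicular mounting.
#' @param z_step_um Stage z increment per frame (micrometres), > 0.
#' @param pixel_pitch_um Camera pixel pitch at the sample (micrometres), > 0.
#' @param scan_mode `"standard_shear"` or `"oblique_comp"`.
#' @param scan_sign Direction (+1 or -1) of the compensating x motion.
#' @param n_frames Number of frames in the stack (may be `NA` until an
#'   acquisition fixes it).
#' @return An object of class `acquisition_geometry`.
#' @examples
#' geom <- acquisition_geometry(45, z_step_um = 1, pixel_pitch_um = 1.31,
#'                              scan_mode = "oblique_comp")
#' stage_offset(10, geom)  # x and z offsets both 10 um at 45 degrees
#' @export
acquisition_geometry <- function(theta_deg, z_step_um, pixel_pitch_um,
                                 scan_mode = c("oblique_comp", "standard_shear"),
                                 scan_sign = 1L, n_frames = NA_integer_) {
  scan_mode <- match.arg(scan_mode)
  stopifnot(is.numeric(theta_deg), length(theta_deg) == 1L)
  if (!(theta_deg > 0 && theta_deg <= 90))
    stop("theta_deg must lie in (0, 90]")
  if (scan_mode == "oblique_comp" && theta_deg >= 90)
    stop("oblique compensation is degenerate at theta = 90 degrees ",
         "(the compensating x step z_step * tan(theta) diverges)")
  if (!(z_step_um > 0)) stop("z_step_um must be positive")
  if (!(pixel_pitch_um > 0)) stop("pixel_pitch_um must be positive")
  if (!scan_sign %in% c(-1, 1)) stop("scan_sign must be +1 or -1")
  theta <- theta_deg * pi / 180
  structure(list(
    theta_deg = theta_deg,
    z_step_um = z_step_um,
    pixel_pitch_um = pixel_pitch_um,
    scan_mode = scan_mode,
    scan_sign = as.integer(scan_sign),
    n_frames = n_frames,
    x_step_um = if (scan_mode == "oblique_comp") z_step_um * tan(theta) else 0
  ), class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf("acquisition_geometry: theta = %g deg, mode = %s\n",
              x$theta_deg, x$scan_mode))
  cat(sprintf("  z step %g um, x step %g um, pixel pitch %g um, frames %s\n",
              x$z_step_um, x$x_step_um, x$pixel_pitch_um,
              ifelse(is.na(x$n_frames), "?", x$n_frames)))
  invisible(x)
}

theta_rad <- function(geom) geom$theta_deg * pi / 180

#' Stage translation for a given frame
#'
#' Returns the stage offset applied to the sample before frame `n`
#' (0-based).  The z component is always `n * z_step_um`; in
#' `"oblique_comp"` mode a lateral component
#' `scan_sign * n * z_step_um * tan(theta)` re-centres the slice on the
#' camera, which at 45 degrees simplifies to an x step equal to the z step.
#'
#' @param n Frame index (0-based); vectorised, must be >= 0.
#' @param geom An [acquisition_geometry()].
#' @return A matrix with one row per frame and columns `x_um`, `y_um`,
#'   `z_um` (laboratory frame).
#' @export
stage_offset <- function(n, geom) {
  stopifnot(inherits(geom, "acquisition_geometry"))
  if (any(n < 0)) stop("frame index n must be non-negative")
  # written so that offset(n) == n * offset(1) holds exactly
  x <- if (geom$scan_mode == "oblique_comp")
    geom$scan_sign * n * geom$x_step_um else rep(0, length(n))
  cbind(x_um = x, y_um = rep(0, length(n)), z_um = n * geom$z_step_um)
}

# Linear map (z', y, x') <- (zpos, y_lab, x_lab) in micrometres, where
# zpos = n * z_step is the stage travel of frame n.  The same matrix serves
# the inverse voxel mapping and build_affine().
sample_map_matrix <- function(geom) {
  th <- theta_rad(geom)
  s <- if (geom$scan_mode == "oblique_comp") geom$scan_sign else 0
  # u = x_lab - s * zpos * tan(theta); (x', z') = S %*% c(u, -zpos) with the
  # reflection S, written out per component:
  #   z' = (sin(th) * (1 - s)) * zpos + cos(th) * x_lab
  #   x' = -(cos(th) + s * sin(th)^2 / cos(th)) * zpos + sin(th) * x_lab
  rbind(
    zp = c(sin(th) * (1 - s), 0, cos(th)),
    y  = c(0, 1, 0),
    xp = c(-(cos(th) + s * sin(th)^2 / cos(th)), 0, sin(th))
  )
}

#' Map raw stack indices to sample-frame coordinates
#'
#' Converts camera pixel indices and frame numbers of a raw acquisition to
#' sample-frame positions (x', y, z') in micrometres, accounting for the
#' per-frame stage offset and the mounting angle. Indices are 0-based and
#' voxel-centred.
#'
#' @param x_pix,y_pix Camera pixel indices (columns, rows); vectorised.
#' @param n Frame indices (0-based); vectorised.
#' @param geom An [acquisition_geometry()].
#' @param origin_um Length-3 origin of the stack in (stage-travel z, lab y,
#'   lab x) micrometres; the default places voxel (0, 0, 0) at zero.
#' @return A data frame with columns `xp_um`, `y_um`, `zp_um`.
#' @export
raw_index_to_sample <- function(x_pix, y_pix, n, geom, origin_um = c(0, 0, 0)) {
  stopifnot(inherits(geom, "acquisition_geometry"))
  M <- sample_map_matrix(geom)
  lab <- rbind(origin_um[1] + n * geom$z_step_um,
               origin_um[2] + y_pix * geom$pixel_pitch_um,
               origin_um[3] + x_pix * geom$pixel_pitch_um)
  out <- M %*% lab
  data.frame(xp_um = out["xp", ], y_um = out["y", ], zp_um = out["zp", ])
}

#' Map sample-frame coordinates to raw stack indices
#'
#' Inverse of [raw_index_to_sample()]: for a point fixed in the sample,
#' returns the (continuous) frame index at which it crosses the light sheet
#' and the camera pixel at which it is then imaged.
#'
#' @param xp_um,y_um,zp_um Sample-frame coordinates (micrometres); vectorised.
#' @inheritParams raw_index_to_sample
#' @return A data frame with columns `n`, `y_pix`, `x_pix` (continuous,
#'   0-based).
#' @export
sample_to_raw_index <- function(xp_um, y_um, zp_um, geom, origin_um = c(0, 0, 0)) {
  stopifnot(inherits(geom, "acquisition_geometry"))
  th <- theta_rad(geom)
  zpos <- sin(th) * zp_um - cos(th) * xp_um           # stage travel at focus
  xlab <- sin(th) * xp_um + cos(th) * zp_um
  if (geom$scan_mode == "oblique_comp")
    xlab <- xlab + geom$scan_sign * zpos * tan(th)
  data.frame(
    n = (zpos - origin_um[1]) / geom$z_step_um,
    y_pix = (y_um - origin_um[2]) / geom$pixel_pitch_um,
    x_pix = (xlab - origin_um[3]) / geom$pixel_pitch_um
  )
}

# Laboratory-frame position of sample points at a given stage travel zpos
# (micrometres).  Used by the phantom simulator.
lab_position <- function(xp_um, y_um, zp_um, zpos, geom) {
  th <- theta_rad(geom)
  sx <- if (geom$scan_mode == "oblique_comp")
    geom$scan_sign * zpos * tan(th) else 0
  list(
    x = sin(th) * xp_um + cos(th) * zp_um + sx,
    y = y_um,
    z = cos(th) * xp_um - sin(th) * zp_um + zpos
  )
}

#' Build the voxel-index affine transform for volume reconstruction
#'
#' Computes the affine transform taking raw-stack voxel indices
#' (frame, row, column) to output voxel indices on a rectilinear
#' sample-frame grid (z' planes, y rows, x' columns). The output shape is
#' the tight bounding box of the eight transformed corners of the input
#' stack. In `"standard_shear"` mode the linear part contains a rotation
#' block (rotation + scaling); in `"oblique_comp"` mode it is a scaling
#' plus a single shear term once the implied 90-degree reorientation
#' (camera x becomes the z' plane axis) is taken into account -- that
#' reorientation is folded into the matrix as an axis permutation rather
#' than performed as a separate resampling step.
#'
#' @param geom An [acquisition_geometry()].
#' @param raw_shape Integer triple (frames, rows, columns) of the raw stack.
#' @param origin_um Raw-stack origin, see [raw_index_to_sample()].
#' @param out_pitch_um Output voxel pitch (z', y, x') in micrometres.
#'   Default: the native pitches `(p cos(theta), p, z_step / cos(theta))`,
#'   which at 45 degrees are `(p / sqrt(2), p, sqrt(2) z_step)`.
#' @param isotropic If `TRUE`, resample to an isotropic grid at the finest
#'   native pitch instead.
#' @param snap_origin Snap the output origin to integer multiples of the
#'   pitch so that reconstructions of one sample under different scan modes
#'   land on a common lattice (default `TRUE`).
#' @return An object of class `affine_transform` with the linear part and
#'   offset in both micrometre and voxel-index form, `output_shape`,
#'   `out_origin_um`, `out_pitch_um`, `padding_voxels` and
#'   `padding_fraction`.
#' @export
build_affine <- function(geom, raw_shape, origin_um = c(0, 0, 0),
                         out_pitch_um = NULL, isotropic = FALSE,
                         snap_origin = TRUE) {
  stopifnot(inherits(geom, "acquisition_geometry"))
  raw_shape <- as.integer(raw_shape)
  if (length(raw_shape) != 3L || any(raw_shape <= 0L))
    stop("raw_shape must be a positive integer triple")
  th <- theta_rad(geom)
  M_um <- sample_map_matrix(geom)
  spacing_in <- c(geom$z_step_um, geom$pixel_pitch_um, geom$pixel_pitch_um)
  M_idx <- M_um %*% diag(spacing_in)          # sample um <- raw voxel index
  offset_um <- as.numeric(M_um %*% origin_um)

  if (is.null(out_pitch_um)) {
    out_pitch_um <- c(geom$pixel_pitch_um * cos(th), geom$pixel_pitch_um,
                      geom$z_step_um / cos(th))
    if (isotropic) out_pitch_um <- rep(min(out_pitch_um), 3L)
  }
  stopifnot(length(out_pitch_um) == 3L, all(out_pitch_um > 0))

  corners <- as.matrix(expand.grid(k = c(0, raw_shape[1] - 1),
                                   j = c(0, raw_shape[2] - 1),
                                   i = c(0, raw_shape[3] - 1)))
  cc <- t(M_idx %*% t(corners)) + rep(offset_um, each = 8L)
  mins <- unname(apply(cc, 2, min))
  maxs <- unname(apply(cc, 2, max))
  out_origin <- if (snap_origin)
    floor(mins / out_pitch_um + 1e-9) * out_pitch_um else mins
  out_shape <- as.integer(floor((maxs - out_origin) / out_pitch_um + 1e-7)) + 1L

  A <- diag(1 / out_pitch_um) %*% M_idx       # out idx <- in idx (linear)
  b <- (offset_um - out_origin) / out_pitch_um
  Ainv <- solve(A)
  n_out <- prod(as.numeric(out_shape))
  covered <- prod(as.numeric(raw_shape)) * abs(det(A))
  padding <- max(0, round(n_out - covered))

  structure(list(
    mode = geom$scan_mode,
    M_idx = M_idx, offset_um = offset_um,
    A = A, b = b, Ainv = Ainv,
    out_pitch_um = out_pitch_um, out_origin_um = out_origin,
    output_shape = out_shape,
    padding_voxels = padding,
    padding_fraction = padding / n_out
  ), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("affine_transform (%s): output shape %s, padding %.1f%%\n",
              x$mode, paste(x$output_shape, collapse = " x "),
              100 * x$padding_fraction))
  invisible(x)
}

#' Export an affine transform as JSON
#'
#' Serialises the voxel-index transform as a row-major 3x4 matrix
#' (linear part followed by the offset column) together with the output
#' grid definition.
#'
#' @param transform An `affine_transform` from [build_affine()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
transform_to_json <- function(transform, path = NULL) {
  stopifnot(inherits(transform, "affine_transform"))
  m34 <- cbind(transform$A, transform$b)
  obj <- list(
    mode = transform$mode,
    matrix_row_major = as.vector(t(m34)),
    output_shape = transform$output_shape,
    out_origin_um = transform$out_origin_um,
    out_pitch_um = transform$out_pitch_um,
    padding_voxels = transform$padding_voxels,
    padding_fraction = transform$padding_fraction
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Optics specification for field-of-view and excitation-NA helpers
#'
#' @param sensor_diagonal_mm Camera sensor diagonal (mm).
#' @param detection_magnification Detection magnification (e.g. 5 for 5x).
#' @param beam_diameter_mm Excitation beam diameter at the objective pupil (mm).
#' @param excitation_focal_mm Focal length of the excitation objective (mm).
#' @param immersion_index Refractive index used for the NA helper (default 1;
#'   the imaging-chamber medium index, e.g. 1.46 for quartz-matched TDE, is
#'   documentation only and does not enter the small-angle NA estimate).
#' @return An object of class `optics_spec`.
#' @export
optics_spec <- function(sensor_diagonal_mm = 29, detection_magnification = 5,
                        beam_diameter_mm = 10, excitation_focal_mm = 50,
                        immersion_index = 1.0) {
  vals <- c(sensor_diagonal_mm, detection_magnification, beam_diameter_mm,
            excitation_focal_mm, immersion_index)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("optics_spec fields must be non-negative and finite")
  if (detection_magnification <= 0 || excitation_focal_mm <= 0)
    stop("magnification and focal length must be positive")
  structure(list(sensor_diagonal_mm = sensor_diagonal_mm,
                 detection_magnification = detection_magnification,
                 beam_diameter_mm = beam_diameter_mm,
                 excitation_focal_mm = excitation_focal_mm,
                 immersion_index = immersion_index),
            class = "optics_spec")
}

#' Field-of-view diagonal at the sample
#'
#' @param optics An [optics_spec()].
#' @return Sensor diagonal divided by detection magnification, in mm.
#' @examples
#' fov_diagonal(optics_spec(29, 5))  # 5.8 mm
#' @export
fov_diagonal <- function(optics) {
  stopifnot(inherits(optics, "optics_spec"))
  optics$sensor_diagonal_mm / optics$detection_magnification
}

#' Excitation numerical aperture
#'
#' Computes `n * sin(atan(D / (2 f)))` from the beam diameter `D` and the
#' excitation focal length `f`.
#'
#' @param optics An [optics_spec()].
#' @return Dimensionless numerical aperture.
#' @examples
#' excitation_na(optics_spec(beam_diameter_mm = 10, excitation_focal_mm = 50))
#' @export
excitation_na <- function(optics) {
  stopifnot(inherits(optics, "optics_spec"))
  optics$immersion_index *
    sin(atan(optics$beam_diameter_mm / (2 * optics$excitation_focal_mm)))
}
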