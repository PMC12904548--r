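#' Gaussian point-spread-function model
#'
#' Anisotropic Gaussian PSF expressed in the laboratory frame
#' (x, y lateral; z along the detection axis). Two optional factors modify
#' the base widths: `astigmatism_delta` multiplies the x width to emulate
#' the lateral asymmetry induced by stress in the quartz mounting slides,
#' and `mode_axial_inflation` multiplies the z width in
#' `"standard_shear"` acquisitions only, emulating the axial penalty of
#' sweeping the tunable-lens focus across the full field instead of the
#' confined central region used by the compensated scan.
#'
#' @param sigma_x_um,sigma_y_um,sigma_z_um Gaussian widths (micrometres),
#'   all positive. FWHM per axis is `2 sqrt(2 log(2))` times sigma.
#' @param astigmatism_delta Multiplicative lateral asymmetry (default 1,
#'   symmetric).
#' @param mode_axial_inflation Factor applied to `sigma_z_um` in standard
#'   shear mode (default 1, no mode difference).
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(sigma_x_um, sigma_y_um = sigma_x_um,
                      sigma_z_um = 2 * sigma_x_um,
                      astigmatism_delta = 1, mode_axial_inflation = 1) {
  if (any(c(sigma_x_um, sigma_y_um, sigma_z_um) <= 0))
    stop("PSF sigmas must be positive")
  if (astigmatism_delta <= 0 || mode_axial_inflation <= 0)
    stop("astigmatism_delta and mode_axial_inflation must be positive")
  structure(list(sigma_x_um = sigma_x_um, sigma_y_um = sigma_y_um,
                 sigma_z_um = sigma_z_um,
                 astigmatism_delta = astigmatism_delta,
                 mode_axial_inflation = mode_axial_inflation),
            class = "psf_model")
}

# Effective lab-frame sigmas for a given scan mode.
psf_sigmas <- function(psf, scan_mode) {
  sz <- psf$sigma_z_um *
    if (identical(scan_mode, "standard_shear")) psf$mode_axial_inflation else 1
  c(x = psf$sigma_x_um * psf$astigmatism_delta, y = psf$sigma_y_um, z = sz)
}

#' Conversion between Gaussian sigma and FWHM
#'
#' @param sigma,fwhm Values to convert.
#' @return `fwhm_from_sigma` returns `2 sqrt(2 log 2) * sigma`;
#'   `sigma_from_fwhm` the inverse.
#' @export
fwhm_from_sigma <- function(sigma) 2 * sqrt(2 * log(2)) * sigma

#' @rdname fwhm_from_sigma
#' @export
sigma_from_fwhm <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Camera noise model
#'
#' Shot noise (Poisson, scaled by `photon_scale` photons per intensity
#' unit), additive Gaussian read noise and a constant offset. All
#' randomness is governed by `seed`.
#'
#' @param photon_scale Photons per intensity unit for the Poisson stage;
#'   `Inf` disables shot noise.
#' @param read_sigma Standard deviation of additive Gaussian read noise.
#' @param offset Constant camera offset added last.
#' @param seed RNG seed for [add_noise()].
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(photon_scale = Inf, read_sigma = 0, offset = 0,
                        seed = 1L) {
  if (photon_scale <= 0 || read_sigma < 0)
    stop("noise parameters must be non-negative (photon_scale positive)")
  structure(list(photon_scale = photon_scale, read_sigma = read_sigma,
                 offset = offset, seed = as.integer(seed)),
            class = "noise_model")
}

#' Synthetic phantom specification
#'
#' Describes a slab-shaped phantom in sample coordinates: either
#' sub-resolution fluorescent beads (1 um diameter by default, effectively
#' point emitters) or ellipsoidal nuclei whose FWHM-equivalent axes are
#' drawn uniformly from `nuclei_fwhm_range_um` (default 5 to 15 um, the
#' typical cardiomyocyte / fibroblast nuclear size range). Objects are
#' modelled as 3D Gaussian blobs with the stated FWHM-equivalent extents;
#' the blob model makes the convolution with the Gaussian PSF exact in
#' closed form, so rendered stacks carry no rasterisation aliasing.
#'
#' @param kind `"beads"` or `"nuclei"`.
#' @param n_objects Number of objects to place.
#' @param bounds_um Slab extent (x', y, z') in micrometres; the z' extent
#'   plays the role of the nominal slice thickness.
#' @param bead_diameter_um Bead FWHM-equivalent diameter (default 1).
#' @param nuclei_fwhm_range_um Range the per-axis nuclear FWHM-equivalent
#'   extents are drawn from.
#' @param orientation `"aligned"` (nuclear axes along the sample axes) or
#'   `"tilted"` (random tilt in the x'-z' plane, up to +/- 45 degrees).
#' @param intensity Peak intensity of the rendered, PSF-blurred object.
#' @param seed RNG seed; the seed fully determines the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("beads", "nuclei"), n_objects,
                         bounds_um = c(200, 200, 50),
                         bead_diameter_um = 1,
                         nuclei_fwhm_range_um = c(5, 15),
                         orientation = c("aligned", "tilted"),
                         intensity = 1000, seed = 1L) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  if (n_objects < 0) stop("n_objects must be non-negative")
  if (length(bounds_um) != 3L || any(bounds_um <= 0))
    stop("bounds_um must be three positive extents")
  structure(list(kind = kind, n_objects = as.integer(n_objects),
                 bounds_um = as.numeric(bounds_um),
                 bead_diameter_um = bead_diameter_um,
                 nuclei_fwhm_range_um = nuclei_fwhm_range_um,
                 orientation = orientation, intensity = intensity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate phantom ground truth
#'
#' Draws object positions, sizes and orientations according to a
#' [phantom_spec()]. Deterministic for a fixed seed; objects (including
#' their full FWHM-equivalent extent) lie inside `bounds_um`.
#'
#' @param spec A [phantom_spec()].
#' @return A data frame with columns `id`, `xp_um`, `y_um`, `zp_um`
#'   (sample-frame position), `intensity`, `sigma_xp_um`, `sigma_y_um`,
#'   `sigma_zp_um` (Gaussian object widths) and `tilt_rad` (rotation in the
#'   x'-z' plane).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_objects
  if (n == 0L) {
    return(data.frame(id = integer(), xp_um = numeric(), y_um = numeric(),
                      zp_um = numeric(), intensity = numeric(),
                      sigma_xp_um = numeric(), sigma_y_um = numeric(),
                      sigma_zp_um = numeric(), tilt_rad = numeric()))
  }
  with_seed(spec$seed, {
    if (spec$kind == "beads") {
      s <- sigma_from_fwhm(spec$bead_diameter_um)
      sig <- matrix(s, nrow = n, ncol = 3)
      fwhm <- matrix(spec$bead_diameter_um, nrow = n, ncol = 3)
      tilt <- rep(0, n)
    } else {
      fwhm <- matrix(stats::runif(3 * n, spec$nuclei_fwhm_range_um[1],
                                  spec$nuclei_fwhm_range_um[2]), ncol = 3)
      sig <- sigma_from_fwhm(fwhm)
      tilt <- if (spec$orientation == "tilted")
        stats::runif(n, -pi / 4, pi / 4) else rep(0, n)
    }
    margin <- apply(fwhm, 2, max) / 2
    lo <- margin
    hi <- spec$bounds_um - margin
    if (any(hi <= lo))
      stop("bounds_um too small to place objects of the requested size")
    data.frame(
      id = seq_len(n),
      xp_um = stats::runif(n, lo[1], hi[1]),
      y_um = stats::runif(n, lo[2], hi[2]),
      zp_um = stats::runif(n, lo[3], hi[3]),
      intensity = rep(spec$intensity, n),
      sigma_xp_um = sig[, 1], sigma_y_um = sig[, 2], sigma_zp_um = sig[, 3],
      tilt_rad = tilt
    )
  })
}

#' Simulate a raw stage-scanned acquisition of a phantom
#'
#' Renders the PSF-blurred phantom frame by frame on the camera grid: frame
#' `n` samples the blurred object field on the light-sheet plane after
#' applying [stage_offset()]. Objects and PSF are both Gaussian, so each
#' frame is evaluated in closed form (a z-weight times a separable
#' conditional Gaussian in camera x and y; object tilt and the mounting
#' angle introduce an x-z covariance handled by the conditional mean).
#' In `"oblique_comp"` mode a point's camera-x position is constant across
#' frames; in `"standard_shear"` mode it drifts by
#' `z_step * tan(theta) / pixel_pitch` pixels per frame.
#'
#' @param phantom Ground-truth data frame from [make_phantom()].
#' @param psf A [psf_model()].
#' @param geom An [acquisition_geometry()].
#' @param noise Optional [noise_model()] applied to the rendered stack.
#' @param camera Optional list overriding the automatic camera framing:
#'   `nx`, `ny` (pixels), `x0_um`, `y0_um` (lab-frame position of pixel 0),
#'   `n0` (first frame's stage index), `n_frames`.
#' @param pad_sigma Framing margin around the phantom in units of the
#'   blurred object sigma (default 4); rendering support is capped at
#'   6 sigma, so larger values only add empty border (useful when a
#'   measurement window must fit around edge objects).
#' @param dtype Nominal storage dtype of the returned stack.
#' @return A `"lab_raw"` [volume_stack()] with spacing
#'   `(z_step, pitch, pitch)` and origin recording the stage and camera
#'   offsets actually used.
#' @export
acquire <- function(phantom, psf, geom, noise = NULL, camera = NULL,
                    pad_sigma = 4, dtype = "uint16") {
  stopifnot(inherits(psf, "psf_model"), inherits(geom, "acquisition_geometry"))
  th <- theta_rad(geom)
  p <- geom$pixel_pitch_um
  zs <- geom$z_step_um
  sig <- psf_sigmas(psf, geom$scan_mode)
  n_obj <- nrow(phantom)

  # per-object lab-frame covariance of the blurred blob
  cov_list <- vector("list", max(n_obj, 0L))
  S <- matrix(c(sin(th), cos(th), cos(th), -sin(th)), 2, 2)
  zpos_focus <- numeric(n_obj)
  for (q in seq_len(n_obj)) {
    ph <- phantom[q, ]
    R2 <- matrix(c(cos(ph$tilt_rad), sin(ph$tilt_rad),
                   -sin(ph$tilt_rad), cos(ph$tilt_rad)), 2, 2)
    C2s <- R2 %*% diag(c(ph$sigma_xp_um^2, ph$sigma_zp_um^2)) %*% t(R2)
    C2l <- S %*% C2s %*% S
    cov_list[[q]] <- list(
      Sxx = C2l[1, 1] + sig["x"]^2,
      Sxz = C2l[1, 2],
      Szz = C2l[2, 2] + sig["z"]^2,
      Syy = ph$sigma_y_um^2 + sig["y"]^2
    )
    zpos_focus[q] <- sin(th) * ph$zp_um - cos(th) * ph$xp_um
  }

  # automatic camera framing: cover every object out to pad_sigma support
  if (n_obj > 0L) {
    sz <- sqrt(vapply(cov_list, function(cv) cv$Szz, 0))
    sx <- sqrt(vapply(cov_list, function(cv) cv$Sxx, 0))
    sy <- sqrt(vapply(cov_list, function(cv) cv$Syy, 0))
    z_lo <- min(zpos_focus - pad_sigma * sz)
    z_hi <- max(zpos_focus + pad_sigma * sz)
    xl_at <- function(zpos_vec) {
      sxc <- if (geom$scan_mode == "oblique_comp")
        geom$scan_sign * zpos_vec * tan(th) else 0
      sin(th) * phantom$xp_um + cos(th) * phantom$zp_um + sxc
    }
    x_all <- c(xl_at(zpos_focus - pad_sigma * sz),
               xl_at(zpos_focus + pad_sigma * sz))
    x_lo <- min(x_all - pad_sigma * max(sx))
    x_hi <- max(x_all + pad_sigma * max(sx))
    y_lo <- min(phantom$y_um - pad_sigma * sy)
    y_hi <- max(phantom$y_um + pad_sigma * sy)
  } else {
    z_lo <- 0; z_hi <- zs; x_lo <- 0; x_hi <- p; y_lo <- 0; y_hi <- p
  }
  camera <- camera %||% list()
  # explicit sensor sizes without explicit origins centre the content,
  # emulating a camera wider than the imaged slab
  x0 <- camera$x0_um %||% if (!is.null(camera$nx))
    (round((x_lo + x_hi) / (2 * p)) - floor(camera$nx / 2)) * p else
    floor(x_lo / p) * p
  y0 <- camera$y0_um %||% if (!is.null(camera$ny))
    (round((y_lo + y_hi) / (2 * p)) - floor(camera$ny / 2)) * p else
    floor(y_lo / p) * p
  n0 <- camera$n0 %||% floor(z_lo / zs)
  n_frames <- camera$n_frames %||% (ceiling(z_hi / zs) - n0 + 1)
  nx <- camera$nx %||% (ceiling((x_hi - x0) / p) + 1)
  ny <- camera$ny %||% (ceiling((y_hi - y0) / p) + 1)
  n_frames <- max(n_frames, 1L)

  arr <- array(0, dim = c(n_frames, ny, nx))
  xg <- x0 + (seq_len(nx) - 1) * p
  yg <- y0 + (seq_len(ny) - 1) * p
  zpos_frames <- (n0 + seq_len(n_frames) - 1) * zs

  clipped <- FALSE
  rend_sigma <- min(pad_sigma, 6)            # Gaussian support for rendering
  for (q in seq_len(n_obj)) {
    ph <- phantom[q, ]
    cv <- cov_list[[q]]
    sc2 <- cv$Sxx - cv$Sxz^2 / cv$Szz        # conditional x variance
    dz <- zpos_focus[q] - zpos_frames
    vis <- which(abs(dz) <= rend_sigma * sqrt(cv$Szz))
    if (!length(vis)) { clipped <- TRUE; next }
    w <- exp(-0.5 * dz[vis]^2 / cv$Szz)
    sxc <- if (geom$scan_mode == "oblique_comp")
      geom$scan_sign * zpos_frames[vis] * tan(th) else 0
    bx <- sin(th) * ph$xp_um + cos(th) * ph$zp_um + sxc
    mu_x <- bx + (cv$Sxz / cv$Szz) * dz[vis]
    jy <- which(abs(yg - ph$y_um) <= rend_sigma * sqrt(cv$Syy))
    if (!length(jy)) { clipped <- TRUE; next }
    gy <- exp(-0.5 * (yg[jy] - ph$y_um)^2 / cv$Syy)
    for (m in seq_along(vis)) {
      ix <- which(abs(xg - mu_x[m]) <= rend_sigma * sqrt(sc2))
      if (!length(ix)) { clipped <- TRUE; next }
      gx <- exp(-0.5 * (xg[ix] - mu_x[m])^2 / sc2)
      arr[vis[m], jy, ix] <- arr[vis[m], jy, ix] +
        ph$intensity * w[m] * outer(gy, gx)
    }
  }
  if (clipped)
    warning("phantom content extends beyond the simulated field; clipped")

  geom$n_frames <- as.integer(n_frames)
  stack <- volume_stack(arr, spacing_um = c(zs, p, p),
                        origin_um = c(n0 * zs, y0, x0),
                        frame = "lab_raw", geometry = geom, dtype = dtype)
  if (!is.null(noise)) stack <- add_noise(stack, noise)
  stack
}

#' Apply camera noise to a stack
#'
#' Shot noise, read noise and offset per the [noise_model()]; deterministic
#' for a fixed model seed and mean-preserving up to the offset.
#'
#' @param stack A [volume_stack()].
#' @param noise A [noise_model()].
#' @return The noisy stack.
#' @export
add_noise <- function(stack, noise) {
  stopifnot(inherits(stack, "volume_stack"), inherits(noise, "noise_model"))
  d <- stack$data
  with_seed(noise$seed, {
    if (is.finite(noise$photon_scale))
      d[] <- stats::rpois(length(d), pmax(d, 0) * noise$photon_scale) /
        noise$photon_scale
    if (noise$read_sigma > 0)
      d[] <- d + stats::rnorm(length(d), 0, noise$read_sigma)
  })
  d <- d + noise$offset
  stack$data <- d
  stack
}
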