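#' Segment nuclei in a sample-frame volume
#'
#' Deterministic baseline segmentation: Gaussian smoothing, a global
#' threshold (Otsu's method on the smoothed intensities by default),
#' connected-component labelling and a minimum-volume filter. Touching
#' nuclei are not split; no watershed is applied.
#'
#' @param stack A `"sample"`-frame [volume_stack()].
#' @param sigma_smooth_um Smoothing width (micrometres; isotropic).
#' @param threshold `"otsu"` or a numeric intensity threshold applied to
#'   the smoothed volume.
#' @param min_volume_um3 Components smaller than this are discarded.
#' @param connectivity 6 (faces, default) or 26.
#' @return An integer label array (0 = background) with the stack's
#'   dimensions; labels are consecutive from 1 in raster order. Attributes
#'   `spacing_um` and `origin_um` are carried over. Returns an all-zero
#'   array with a warning when nothing is found.
#' @export
segment_nuclei <- function(stack, sigma_smooth_um = 1.5, threshold = "otsu",
                           min_volume_um3 = 20, connectivity = 6) {
  stopifnot(inherits(stack, "volume_stack"))
  sm <- gaussian_blur3d(stack$data, sigma_smooth_um / stack$spacing_um)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(sm)
         else as.numeric(threshold)
  mask <- sm > thr
  lab <- label_components_cpp(mask, dim(stack$data), connectivity)
  if (max(lab) > 0L) {
    voxel_um3 <- prod(stack$spacing_um)
    counts <- tabulate(lab[lab > 0L])
    keep <- which(counts * voxel_um3 >= min_volume_um3)
    remap <- integer(length(counts))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  if (max(lab) == 0L) warning("no nuclei found")
  attr(lab, "spacing_um") <- stack$spacing_um
  attr(lab, "origin_um") <- stack$origin_um
  lab
}

#' Measure one segmented nucleus
#'
#' Gaussian-profile FWHM per sample axis through the nucleus centroid,
#' using the same fitter as the bead analysis. Profiles are taken on the
#' intensity volume inside the label's bounding box expanded by a margin;
#' fit failures are flagged so they can be excluded from distributions.
#'
#' @param stack The intensity [volume_stack()] the labels were derived from
#'   (sample frame: plane = z', row = y, col = x').
#' @param labels Label array from [segment_nuclei()].
#' @param id Label id to measure.
#' @param margin_factor Bounding-box expansion factor (default 1.5).
#' @param psf_fwhm_um Optional length-3 PSF FWHM (z', y, x') used to also
#'   report quadrature-corrected object sizes
#'   (`sqrt(max(measured^2 - psf^2, 0))`).
#' @return A one-row data frame: `label`, centroid (`xp_um`, `y_um`,
#'   `zp_um`), `fwhm_xp`, `fwhm_y`, `fwhm_zp` (micrometres), R-squared per
#'   axis, `volume_um3`, `ok`, and `fwhm_*_corr` when `psf_fwhm_um` is
#'   given.
#' @export
measure_nucleus <- function(stack, labels, id, margin_factor = 1.5,
                            psf_fwhm_um = NULL) {
  stopifnot(inherits(stack, "volume_stack"))
  sel <- which(labels == id)
  if (!length(sel)) stop("label ", id, " not present")
  d <- dim(stack$data)
  sp <- stack$spacing_um
  ai <- arrayInd(sel, d)
  w <- stack$data[sel]
  cg <- colSums(ai * w) / sum(w)                 # 1-based continuous
  half <- pmax(3, ceiling(margin_factor *
                            (apply(ai, 2, max) - apply(ai, 2, min) + 1) / 2))
  lo <- pmax(1L, floor(cg - half))
  hi <- pmin(d, ceiling(cg + half))
  win <- stack$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  wd <- dim(win)
  cw <- cg - lo                                   # 0-based within window
  fits <- lapply(1:3, function(a) {
    pts <- matrix(rep(cw, each = wd[a]), ncol = 3)
    pts[, a] <- seq_len(wd[a]) - 1
    fit_profile_gaussian(interp_trilinear(win, pts),
                         position = (seq_len(wd[a]) - 1) * sp[a])
  })
  f <- vapply(fits, function(z) z$fwhm, 0)
  r2 <- vapply(fits, function(z) z$r2, 0)
  ctr_um <- stack$origin_um + (cg - 1) * sp
  out <- data.frame(
    label = id, xp_um = ctr_um[3], y_um = ctr_um[2], zp_um = ctr_um[1],
    fwhm_xp = f[3], fwhm_y = f[2], fwhm_zp = f[1],
    r2_xp = r2[3], r2_y = r2[2], r2_zp = r2[1],
    volume_um3 = length(sel) * prod(sp),
    ok = all(vapply(fits, function(z) z$converged, TRUE)))
  if (!is.null(psf_fwhm_um)) {
    out$fwhm_xp_corr <- sqrt(pmax(f[3]^2 - psf_fwhm_um[3]^2, 0))
    out$fwhm_y_corr <- sqrt(pmax(f[2]^2 - psf_fwhm_um[2]^2, 0))
    out$fwhm_zp_corr <- sqrt(pmax(f[1]^2 - psf_fwhm_um[1]^2, 0))
  }
  out
}

#' Measure all segmented nuclei
#'
#' @inheritParams measure_nucleus
#' @param roi Optional vector of ROI names assigned per nucleus by a
#'   function of the centroid, or a single name for all.
#' @param ... Passed to [measure_nucleus()].
#' @return A data frame with one row per label (fit failures flagged
#'   `ok = FALSE`).
#' @export
measure_nuclei <- function(stack, labels, roi = NULL, ...) {
  n <- max(labels)
  if (n == 0L) return(data.frame())
  out <- do.call(rbind, lapply(seq_len(n), function(id)
    measure_nucleus(stack, labels, id, ...)))
  out$roi <- if (is.null(roi)) "all" else
    if (length(roi) == 1L) roi else roi[out$label]
  out
}

#' Resolvability of nuclei against mode-specific axial limits
#'
#' For each nucleus, compares the measured axial FWHM (z') with the axial
#' resolution limits of the standard shear and oblique compensation
#' acquisition modes, and reports the fraction of nuclei at or above each
#' limit -- i.e. the fraction whose axial extent the mode can resolve.
#'
#' @param measurements Data frame from [measure_nuclei()] (needs `fwhm_zp`,
#'   optionally `roi` and `ok`).
#' @param axial_limit_standard_um,axial_limit_oblique_um Axial FWHM
#'   resolution limits (micrometres), both > 0.
#' @return A list: `fractions` (overall resolvable fraction per mode and
#'   counts), `per_roi` (same per ROI) and `measurements` with added
#'   `resolvable_standard` / `resolvable_oblique` flags.
#' @export
resolvability_report <- function(measurements, axial_limit_standard_um,
                                 axial_limit_oblique_um) {
  if (!nrow(measurements)) stop("empty measurement set")
  stopifnot(axial_limit_standard_um > 0, axial_limit_oblique_um > 0)
  m <- measurements
  if (!is.null(m$ok)) m <- m[m$ok & is.finite(m$fwhm_zp), , drop = FALSE]
  m$resolvable_standard <- m$fwhm_zp >= axial_limit_standard_um
  m$resolvable_oblique <- m$fwhm_zp >= axial_limit_oblique_um
  frac <- data.frame(
    n = nrow(m),
    fraction_resolvable_standard = mean(m$resolvable_standard),
    fraction_resolvable_oblique = mean(m$resolvable_oblique))
  per_roi <- NULL
  if (!is.null(m$roi)) {
    per_roi <- do.call(rbind, lapply(split(m, m$roi), function(g)
      data.frame(roi = g$roi[1], n = nrow(g),
                 fraction_resolvable_standard = mean(g$resolvable_standard),
                 fraction_resolvable_oblique = mean(g$resolvable_oblique))))
    rownames(per_roi) <- NULL
  }
  list(fractions = frac, per_roi = per_roi, measurements = m)
}
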