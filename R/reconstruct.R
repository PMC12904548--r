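#' Resample a stack through an affine voxel transform
#'
#' Inverse-mapped trilinear interpolation onto the output grid defined by an
#' `affine_transform`; reads outside the input stack return zero. This is
#' the single resampling primitive both reconstruction pipelines use.
#'
#' @param stack A [volume_stack()].
#' @param transform An `affine_transform` from [build_affine()].
#' @return A `"sample"`-frame [volume_stack()] on the transform's output
#'   grid (float32 nominal dtype; reconstruction keeps floating point to
#'   avoid quantisation bias in downstream profile fits).
#' @export
resample_affine <- function(stack, transform) {
  stopifnot(inherits(stack, "volume_stack"),
            inherits(transform, "affine_transform"))
  if (abs(det(transform$A)) < .Machine$double.eps)
    stop("singular transform")
  binv <- cbind(transform$Ainv, -transform$Ainv %*% transform$b)
  out <- affine_resample_cpp(as.numeric(stack$data), dim(stack$data),
                             transform$output_shape, binv)
  dim(out) <- transform$output_shape
  volume_stack(out, spacing_um = transform$out_pitch_um,
               origin_um = transform$out_origin_um, frame = "sample",
               geometry = stack$geometry, dtype = "float32")
}

reconstruction_result <- function(volume, transform, raw_bytes, raw_dtype,
                                  crop = NULL) {
  structure(list(volume = volume, transform = transform,
                 raw_bytes = raw_bytes,
                 reconstructed_bytes = prod(as.numeric(dim(volume$data))) *
                   bytes_per_voxel(raw_dtype),
                 padding_fraction = transform$padding_fraction,
                 crop = crop),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf("reconstruction_result (%s): %s -> %s voxels, size factor %.3g\n",
              x$transform$mode,
              format(x$raw_bytes, big.mark = ","),
              paste(dim(x$volume$data), collapse = " x "),
              x$reconstructed_bytes / x$raw_bytes))
  invisible(x)
}

#' De-skew a standard-shear acquisition
#'
#' Reconstruction path for `"standard_shear"` raw stacks: a single affine
#' resampling combining rotation and scaling. Because the raw volume is
#' sheared, no cropping is possible before the transform; empty regions of
#' the output bounding box are zero-filled, which is where the
#' characteristic padding overhead of this mode comes from.
#'
#' @param raw A `"lab_raw"` [volume_stack()] acquired in standard shear mode.
#' @param out_pitch_um,isotropic Output grid options, see [build_affine()].
#' @return A `reconstruction_result` with the sample-frame volume, the
#'   transform, raw and reconstructed byte counts and the padding fraction.
#' @export
deskew_standard <- function(raw, out_pitch_um = NULL, isotropic = FALSE) {
  stopifnot(inherits(raw, "volume_stack"))
  if (raw$frame != "lab_raw") stop("raw stack must be tagged lab_raw")
  geom <- raw$geometry
  if (is.null(geom) || geom$scan_mode != "standard_shear")
    stop("deskew_standard requires scan_mode = standard_shear")
  tr <- build_affine(geom, dim(raw$data), origin_um = raw$origin_um,
                     out_pitch_um = out_pitch_um, isotropic = isotropic)
  vol <- resample_affine(raw, tr)
  reconstruction_result(vol, tr, stack_bytes(raw), raw$dtype)
}

#' Reconstruct an oblique-compensation acquisition
#'
#' Reconstruction path for `"oblique_comp"` raw stacks: because the slice
#' stays centred on the camera, content-free columns can be cropped
#' *before* any resampling; the remaining transform is the 90-degree
#' reorientation (an axis permutation folded into the matrix), a scaling
#' along z' and a single shear along x'.
#'
#' @param raw A `"lab_raw"` [volume_stack()] acquired in oblique
#'   compensation mode.
#' @param crop Crop content-free camera-x margins before the affine step
#'   (default `TRUE`).
#' @param crop_threshold Intensity at or below which a column counts as
#'   empty (default 0: exactly-zero background, as in noise-free
#'   simulations; raise it for noisy data).
#' @param guard_pix Extra columns retained on each side of the content.
#' @param out_pitch_um,isotropic Output grid options, see [build_affine()].
#' @return A `reconstruction_result`; its `crop` field records the retained
#'   column bounds.
#' @export
reconstruct_oblique <- function(raw, crop = TRUE, crop_threshold = 0,
                                guard_pix = 2, out_pitch_um = NULL,
                                isotropic = FALSE) {
  stopifnot(inherits(raw, "volume_stack"))
  if (raw$frame != "lab_raw") stop("raw stack must be tagged lab_raw")
  geom <- raw$geometry
  if (is.null(geom) || geom$scan_mode != "oblique_comp")
    stop("reconstruct_oblique requires scan_mode = oblique_comp")
  raw_bytes <- stack_bytes(raw)
  cropped <- if (crop) {
    cr <- crop_to_content(raw, threshold = crop_threshold,
                          guard_pix = guard_pix)
    cr
  } else list(stack = raw, bounds = NULL)
  tr <- build_affine(geom, dim(cropped$stack$data),
                     origin_um = cropped$stack$origin_um,
                     out_pitch_um = out_pitch_um, isotropic = isotropic)
  vol <- resample_affine(cropped$stack, tr)
  reconstruction_result(vol, tr, raw_bytes, raw$dtype, crop = cropped$bounds)
}

#' Crop content-free margins from a raw stack
#'
#' Finds the smallest index range along camera x (and optionally camera y)
#' whose excluded margins contain only intensities at or below `threshold`,
#' keeps a guard margin, and subsets the stack. Retained voxel values are
#' untouched (bit-exact) and the stack origin is updated so coordinate
#' mappings remain valid.
#'
#' @param stack A [volume_stack()].
#' @param threshold Background level; margins with all values `<= threshold`
#'   are removed.
#' @param guard_pix Guard margin (pixels) retained beyond the content.
#' @param crop_rows Also crop along camera y (default `FALSE`).
#' @return A list with the cropped `stack` and the retained `bounds`
#'   (0-based inclusive index ranges per cropped axis).
#' @export
crop_to_content <- function(stack, threshold = 0, guard_pix = 2,
                            crop_rows = FALSE) {
  stopifnot(inherits(stack, "volume_stack"), threshold >= 0)
  d <- dim(stack$data)
  col_max <- apply(stack$data, 3, max)
  keep <- which(col_max > threshold)
  if (!length(keep)) stop("no content above threshold; nothing to retain")
  i0 <- max(1L, min(keep) - guard_pix)
  i1 <- min(d[3], max(keep) + guard_pix)
  bounds <- list(col = c(i0, i1) - 1L)
  rows <- seq_len(d[2])
  if (crop_rows) {
    row_max <- apply(stack$data, 2, max)
    keepr <- which(row_max > threshold)
    j0 <- max(1L, min(keepr) - guard_pix)
    j1 <- min(d[2], max(keepr) + guard_pix)
    rows <- j0:j1
    bounds$row <- c(j0, j1) - 1L
  }
  out <- stack
  out$data <- stack$data[, rows, i0:i1, drop = FALSE]
  out$origin_um <- stack$origin_um +
    c(0, (rows[1] - 1L) * stack$spacing_um[2], (i0 - 1L) * stack$spacing_um[3])
  list(stack = out, bounds = bounds)
}

#' Fuse tiles with known offsets
#'
#' Places sample-frame tiles on their shared lattice (tile origins must be
#' integer multiples of a common voxel pitch, as produced by the
#' reconstruction functions with origin snapping) and blends overlaps with
#' a linear ramp. Registration is out of scope: offsets are taken as exact.
#'
#' @param tiles A list of [volume_stack()]s (or `reconstruction_result`s,
#'   whose volumes are used).
#' @param overlap_fraction Nominal overlap fraction used to size the blend
#'   ramp, in `[0, 0.5)`.
#' @return The fused [volume_stack()].
#' @export
fuse_tiles <- function(tiles, overlap_fraction = 0.10) {
  if (overlap_fraction < 0 || overlap_fraction >= 0.5)
    stop("overlap_fraction must lie in [0, 0.5)")
  tiles <- lapply(tiles, function(t)
    if (inherits(t, "reconstruction_result")) t$volume else t)
  stopifnot(length(tiles) >= 1L,
            all(vapply(tiles, inherits, TRUE, "volume_stack")))
  if (length(tiles) == 1L) return(tiles[[1]])
  pitch <- tiles[[1]]$spacing_um
  for (t in tiles)
    if (max(abs(t$spacing_um - pitch)) > 1e-9)
      stop("inconsistent tile grids: voxel pitches differ")
  orig <- t(vapply(tiles, function(t) t$origin_um, numeric(3)))
  off <- sweep(orig, 2, apply(orig, 2, min)) / rep(pitch, each = nrow(orig))
  if (max(abs(off - round(off))) > 1e-6)
    stop("inconsistent tile grids: origins not on a common lattice")
  off <- round(off)
  dims <- t(vapply(tiles, function(t) dim(t$data), integer(3)))
  out_dim <- apply(off + dims, 2, max)
  acc <- array(0, out_dim)
  wacc <- array(0, out_dim)
  for (q in seq_along(tiles)) {
    d <- dims[q, ]
    ramp <- pmax(1L, round(overlap_fraction * d))
    w1 <- lapply(1:3, function(a) {
      idx <- seq_len(d[a])
      pmin(1, pmin(idx, d[a] - idx + 1) / (ramp[a] + 1))
    })
    w <- outer(outer(w1[[1]], w1[[2]]), w1[[3]])
    dim(w) <- d
    sl <- lapply(1:3, function(a) off[q, a] + seq_len(d[a]))
    acc[sl[[1]], sl[[2]], sl[[3]]] <- acc[sl[[1]], sl[[2]], sl[[3]]] +
      w * tiles[[q]]$data
    wacc[sl[[1]], sl[[2]], sl[[3]]] <- wacc[sl[[1]], sl[[2]], sl[[3]]] + w
  }
  fused <- acc
  nz <- wacc > 0
  fused[nz] <- acc[nz] / wacc[nz]
  volume_stack(fused, spacing_um = pitch,
               origin_um = apply(orig, 2, min),
               frame = tiles[[1]]$frame, geometry = tiles[[1]]$geometry,
               dtype = "float32")
}
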