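# Shared fixtures: all synthetic inputs are built in code, deterministically.

# A random but valid geometry; theta in [30, 60] degrees, sub-micron to
# 1.5 um steps, either scan mode.
random_geometry <- function(seed, mode = NULL) {
  with_seed_test(seed, {
    mode <- mode %||% sample(c("standard_shear", "oblique_comp"), 1)
    acquisition_geometry(
      theta_deg = runif(1, 30, 60),
      z_step_um = runif(1, 0.7, 1.4),
      pixel_pitch_um = runif(1, 0.7, 1.4),
      scan_mode = mode)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Beads with a guaranteed minimum pairwise separation: draw a phantom and
# greedily drop members of close pairs (deterministic).
separated_beads <- function(n, bounds_um, min_sep_um, seed,
                            intensity = 1000) {
  ph <- make_phantom(phantom_spec("beads", 3 * n, bounds_um = bounds_um,
                                  intensity = intensity, seed = seed))
  pos <- as.matrix(ph[, c("xp_um", "y_um", "zp_um")])
  keep <- integer()
  for (q in seq_len(nrow(pos))) {
    if (length(keep) == n) break
    if (!length(keep) ||
        min(sqrt(rowSums((pos[keep, , drop = FALSE] -
                            rep(pos[q, ], each = length(keep)))^2))) >= min_sep_um)
      keep <- c(keep, q)
  }
  ph <- ph[keep, , drop = FALSE]
  ph$id <- seq_len(nrow(ph))
  rownames(ph) <- NULL
  ph
}

# Nuclei with a guaranteed minimum centre separation (touching nuclei are
# deliberately not split by the segmenter, so recall fixtures keep them apart).
separated_nuclei <- function(n, bounds_um, min_sep_um, seed) {
  ph <- make_phantom(phantom_spec("nuclei", 4 * n, bounds_um = bounds_um,
                                  seed = seed))
  pos <- as.matrix(ph[, c("xp_um", "y_um", "zp_um")])
  keep <- integer()
  for (q in seq_len(nrow(pos))) {
    if (length(keep) == n) break
    if (!length(keep) ||
        min(sqrt(rowSums((pos[keep, , drop = FALSE] -
                            rep(pos[q, ], each = length(keep)))^2))) >= min_sep_um)
      keep <- c(keep, q)
  }
  ph <- ph[keep, , drop = FALSE]
  ph$id <- seq_len(nrow(ph))
  rownames(ph) <- NULL
  ph
}

reconstruct_any <- function(raw, ...) {
  if (raw$geometry$scan_mode == "oblique_comp") reconstruct_oblique(raw, ...)
  else deskew_standard(raw, ...)
}

# Intensity-weighted centroid (in voxel units) of a window centred on the
# expected output index; returns the per-bead centroid error in voxels.
centroid_errors_vox <- function(volume, phantom, half_vox = NULL) {
  v <- volume$data
  d <- dim(v)
  expected_idx <- cbind((phantom$zp_um - volume$origin_um[1]) / volume$spacing_um[1],
                        (phantom$y_um - volume$origin_um[2]) / volume$spacing_um[2],
                        (phantom$xp_um - volume$origin_um[3]) / volume$spacing_um[3])
  half_vox <- half_vox %||% pmax(3L, ceiling(6 / volume$spacing_um))
  vapply(seq_len(nrow(phantom)), function(q) {
    ctr <- round(expected_idx[q, ]) + 1L
    lo <- pmax(1L, ctr - half_vox)
    hi <- pmin(d, ctr + half_vox)
    w <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    if (sum(w) == 0) return(Inf)
    wd <- dim(w)
    cg <- vapply(1:3, function(a) {
      m <- apply(w, a, sum)
      sum((seq_len(wd[a]) - 1) * m) / sum(m)
    }, 0)
    sqrt(sum((cg + (lo - 1L) - expected_idx[q, ])^2))
  }, 0)
}

# Overlap two sample-frame volumes on their shared lattice and correlate
# voxels where either carries content.
cross_mode_correlation <- function(va, vb) {
  io <- (vb$origin_um - va$origin_um) / va$spacing_um
  stopifnot(max(abs(io - round(io))) < 1e-6)
  io <- round(io)
  da <- dim(va$data); db <- dim(vb$data)
  lo <- pmax(c(1, 1, 1), io + 1)
  hi <- pmin(da, io + db)
  A <- va$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  B <- vb$data[(lo[1]:hi[1]) - io[1], (lo[2]:hi[2]) - io[2], (lo[3]:hi[3]) - io[3]]
  m <- A > 1e-3 * max(A) | B > 1e-3 * max(B)
  stats::cor(A[m], B[m])
}
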