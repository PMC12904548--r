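make_transform <- function(A, b, out_shape, pitch = c(1, 1, 1),
                           origin = c(0, 0, 0)) {
  structure(list(mode = "manual", M_idx = A, offset_um = b, A = A, b = b,
                 Ainv = solve(A), out_pitch_um = pitch, out_origin_um = origin,
                 output_shape = as.integer(out_shape), padding_voxels = 0,
                 padding_fraction = 0), class = "affine_transform")
}

test_that("the resampler is exact on identity and integer translations", {
  arr <- with_seed_test(1, array(runif(8 * 9 * 10), c(8, 9, 10)))
  st <- volume_stack(arr, c(1, 1, 1))
  idt <- make_transform(diag(3), c(0, 0, 0), dim(arr))
  expect_equal(resample_affine(st, idt)$data, arr, tolerance = 1e-12)

  shift <- make_transform(diag(3), c(2, -1, 3), dim(arr) + c(2, 0, 3))
  out <- resample_affine(st, shift)$data
  expect_equal(out[3:10, 1:8, 4:13], arr[, 2:9, ], tolerance = 1e-12)
  expect_true(all(out[1:2, , ] == 0))          # zero fill outside the input

  sing <- make_transform(diag(3), c(0, 0, 0), dim(arr))
  sing$A[1, ] <- 0
  expect_error(resample_affine(st, sing), "singular")
})

test_that("a rotated Gaussian ball keeps its centre and width", {
  # closed-form reference: an isotropic Gaussian is invariant under rotation
  n <- 41
  ctr <- (n - 1) / 2
  idx <- seq_len(n) - 1
  g1 <- exp(-0.5 * (idx - ctr)^2 / 4^2)
  ball <- outer(outer(g1, g1), g1)
  st <- volume_stack(array(ball, c(n, n, n)), c(1, 1, 1))
  th <- pi / 4
  R <- rbind(c(cos(th), 0, -sin(th)), c(0, 1, 0), c(sin(th), 0, cos(th)))
  b <- as.numeric((diag(3) - R) %*% rep(ctr, 3))   # rotate about the centre
  out <- resample_affine(st, make_transform(R, b, c(n, n, n)))$data
  fits <- lapply(1:3, function(a) {
    prof <- switch(a, out[, 21, 21], out[21, , 21], out[21, 21, ])
    fit_profile_gaussian(prof)
  })
  for (f in fits) {
    expect_equal(f$mu, ctr, tolerance = 0.01)
    expect_equal(f$sigma, 4, tolerance = 0.01)
  }
})

test_that("acquire -> reconstruct recovers ground-truth bead centroids", {
  for (seed in 1:5) {
    ph <- separated_beads(5, c(60, 40, 20), 14, seed = seed)
    psf <- psf_model(1.2, 1.2, 2)
    for (mode in c("oblique_comp", "standard_shear")) {
      g <- random_geometry(seed + 50, mode)
      raw <- acquire(ph, psf, g)
      rec <- reconstruct_any(raw)
      err <- centroid_errors_vox(rec$volume, ph)
      expect_lt(max(err), 0.5)
    }
  }
})

test_that("the two pipelines agree on common support", {
  ph <- separated_beads(8, c(90, 50, 25), 14, seed = 31)
  psf <- psf_model(1.2, 1.2, 2)
  gob <- acquisition_geometry(45, 1, 1, "oblique_comp")
  gst <- acquisition_geometry(45, 1, 1, "standard_shear")
  va <- reconstruct_oblique(acquire(ph, psf, gob))$volume
  vb <- deskew_standard(acquire(ph, psf, gst))$volume
  expect_gt(cross_mode_correlation(va, vb), 0.99)
})

test_that("reconstruction enforces mode and frame preconditions", {
  ph <- separated_beads(3, c(40, 30, 15), 10, seed = 7)
  psf <- psf_model(1.2, 1.2, 2)
  raw_ob <- acquire(ph, psf, acquisition_geometry(45, 1, 1, "oblique_comp"))
  raw_st <- acquire(ph, psf, acquisition_geometry(45, 1, 1, "standard_shear"))
  expect_error(deskew_standard(raw_ob), "standard_shear")
  expect_error(reconstruct_oblique(raw_st), "oblique_comp")
  expect_error(deskew_standard(raw_st$geometry), "volume_stack")
  sample_vol <- reconstruct_oblique(raw_ob)$volume
  expect_error(reconstruct_oblique(sample_vol), "lab_raw")
})

test_that("perpendicular mounting with matched pitches is an identity path", {
  g90 <- acquisition_geometry(90, 1, 1, "standard_shear")
  ph <- separated_beads(3, c(30, 30, 30), 10, seed = 8)
  raw <- acquire(ph, psf_model(1.2, 1.2, 1.8), g90)
  rec <- deskew_standard(raw, out_pitch_um = c(1, 1, 1))
  expect_equal(dim(rec$volume$data), dim(raw$data))
  expect_equal(rec$volume$data, raw$data, tolerance = 1e-9)
  expect_equal(rec$reconstructed_bytes, rec$raw_bytes)
})

test_that("byte accounting reflects padding and cropping", {
  ph <- separated_beads(10, c(220, 50, 30), 16, seed = 9)
  psf <- psf_model(1.3, 1.3, 2.2)
  gst <- acquisition_geometry(45, 1, 1, "standard_shear")
  rec_st <- deskew_standard(acquire(ph, psf, gst))
  expect_gt(rec_st$reconstructed_bytes, rec_st$raw_bytes)

  # slab in the central ~40% of a wide camera: cropping wins
  gob <- acquisition_geometry(45, 1, 1, "oblique_comp")
  raw_ob <- acquire(ph, psf, gob, camera = list(nx = 280))
  rec_ob <- reconstruct_oblique(raw_ob)
  expect_lt(rec_ob$reconstructed_bytes, rec_ob$raw_bytes)
  expect_gt(rec_st$padding_fraction, rec_ob$padding_fraction)
  expect_gt(rec_st$reconstructed_bytes / rec_st$raw_bytes,
            rec_ob$reconstructed_bytes / rec_ob$raw_bytes)
})

test_that("cropping removes only content-free margins, bit-exactly", {
  arr <- array(0, c(4, 5, 30))
  arr[2, 3, 12:17] <- c(5, 7, 9, 9, 7, 5)
  st <- volume_stack(arr, c(1, 1, 1), origin_um = c(0, 0, 4))
  cr <- crop_to_content(st, threshold = 0, guard_pix = 2)
  # brute-force column scan oracle
  nz <- range(which(apply(arr, 3, max) > 0))
  expect_equal(cr$bounds$col, c(nz[1] - 2L, nz[2] + 2L) - 1L)
  expect_identical(cr$stack$data, arr[, , (nz[1] - 2):(nz[2] + 2)])
  expect_equal(cr$stack$origin_um[3], 4 + (nz[1] - 3) * 1)

  # uniform stack: nothing to crop
  u <- volume_stack(array(3, c(3, 4, 5)), c(1, 1, 1))
  cu <- crop_to_content(u, threshold = 0, guard_pix = 0)
  expect_identical(cu$stack$data, u$data)

  expect_error(crop_to_content(volume_stack(array(0, c(2, 2, 2)), c(1, 1, 1))),
               "no content")
})

test_that("cropping never alters what the reconstruction sees", {
  ph <- separated_beads(5, c(60, 40, 20), 12, seed = 10)
  psf <- psf_model(1.2, 1.2, 2)
  g <- acquisition_geometry(45, 1, 1, "oblique_comp")
  raw <- acquire(ph, psf, g, camera = list(nx = 150))
  with_crop <- reconstruct_oblique(raw, crop = TRUE)
  without <- reconstruct_oblique(raw, crop = FALSE)
  err <- centroid_errors_vox(with_crop$volume, ph)
  expect_lt(max(err), 0.5)
  expect_lte(with_crop$reconstructed_bytes, without$reconstructed_bytes)
})

test_that("interpolation conserves interior flux", {
  ph <- data.frame(id = 1, xp_um = 30, y_um = 20, zp_um = 12, intensity = 1000,
                   sigma_xp_um = 0.42, sigma_y_um = 0.42, sigma_zp_um = 0.42,
                   tilt_rad = 0)
  psf <- psf_model(1.5, 1.5, 2.4)
  for (mode in c("oblique_comp", "standard_shear")) {
    g <- acquisition_geometry(45, 0.9, 1.1, mode)
    raw <- acquire(ph, psf, g)
    rec <- reconstruct_any(raw)
    flux_in <- sum(raw$data) * prod(raw$spacing_um)
    flux_out <- sum(rec$volume$data) * prod(rec$volume$spacing_um)
    expect_lt(abs(flux_out - flux_in) / flux_in, 0.005)
  }
})

test_that("tile fusion blends overlaps without seams or duplicates", {
  # constant field: any blend must return the constant
  mk <- function(origin, dims, val) volume_stack(array(val, dims), c(1, 1, 1),
                                                 origin_um = origin,
                                                 frame = "sample")
  t1 <- mk(c(0, 0, 0), c(8, 10, 40), 7)
  t2 <- mk(c(0, 0, 36), c(8, 10, 40), 7)
  fz <- fuse_tiles(list(t1, t2), overlap_fraction = 0.10)
  expect_equal(dim(fz$data), c(8, 10, 76))
  expect_true(all(abs(fz$data - 7) < 1e-12))

  # single tile: identity
  expect_identical(fuse_tiles(list(t1))$data, t1$data)

  # two tiles of one phantom: fused bead count equals the phantom count
  ph <- separated_beads(8, c(120, 40, 20), 14, seed = 12)
  psf <- psf_model(1.2, 1.2, 2)
  g <- acquisition_geometry(45, 1, 1, "oblique_comp")
  vol <- reconstruct_oblique(acquire(ph, psf, g))$volume
  nx <- dim(vol$data)[3]
  cut <- round(nx * 0.55)
  a <- vol; a$data <- vol$data[, , 1:cut, drop = FALSE]
  b <- vol
  b$data <- vol$data[, , (cut - round(0.1 * nx)):nx, drop = FALSE]
  b$origin_um <- vol$origin_um +
    c(0, 0, (cut - round(0.1 * nx) - 1) * vol$spacing_um[3])
  fused <- fuse_tiles(list(a, b), overlap_fraction = 0.10)
  det <- detect_beads(fused, 10, 0.25 * max(fused$data))
  expect_equal(nrow(det), nrow(ph))

  # inconsistent grids are rejected
  bad <- t2; bad$origin_um <- c(0, 0, 36.37)
  expect_error(fuse_tiles(list(t1, bad)), "lattice")
  badp <- t2; badp$spacing_um <- c(1, 1, 1.1)
  expect_error(fuse_tiles(list(t1, badp)), "pitch")
  expect_error(fuse_tiles(list(t1, t2), overlap_fraction = 0.6), "overlap")
})
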