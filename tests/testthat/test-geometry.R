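test_that("stage offsets follow the shear-compensation law", {
  g45 <- acquisition_geometry(45, 1, 1.31, "oblique_comp")
  off <- stage_offset(10, g45)
  expect_equal(unname(abs(off[, "x_um"])), 10, tolerance = 1e-12)
  expect_equal(unname(off[, "z_um"]), 10)
  expect_equal(unname(off[, "y_um"]), 0)

  g3 <- acquisition_geometry(45, 3, 1.31, "oblique_comp")
  expect_equal(unname(abs(stage_offset(5, g3)[, "x_um"])), 15,
               tolerance = 1e-12)

  gs <- acquisition_geometry(45, 1, 1.31, "standard_shear")
  expect_equal(stage_offset(c(0, 7, 123), gs)[, "x_um"], rep(0, 3),
               ignore_attr = TRUE)

  # linearity: offset(n) = n * offset(1), exactly
  for (seed in 1:5) {
    g <- random_geometry(seed)
    expect_identical(stage_offset(13, g), 13 * stage_offset(1, g))
  }
  expect_error(stage_offset(-1, g45), "non-negative")
})

test_that("geometry constructor enforces its invariants", {
  expect_error(acquisition_geometry(0, 1, 1), "theta")
  expect_error(acquisition_geometry(91, 1, 1), "theta")
  expect_error(acquisition_geometry(45, -1, 1), "z_step")
  expect_error(acquisition_geometry(45, 1, 0), "pixel_pitch")
  expect_error(acquisition_geometry(45, 1, 1, scan_sign = 2), "scan_sign")
  g <- acquisition_geometry(45, 2, 1, "oblique_comp")
  expect_equal(g$x_step_um, g$z_step_um, tolerance = 1e-12)  # tan(45) = 1
  gs <- acquisition_geometry(30, 2, 1, "standard_shear")
  expect_equal(gs$x_step_um, 0)
})

test_that("index mapping round trips to sample coordinates in both modes", {
  for (seed in 1:10) {
    g <- random_geometry(seed)
    pts <- with_seed_test(seed + 100, data.frame(
      xp = runif(8, -60, 60), y = runif(8, 0, 50), zp = runif(8, -25, 25)))
    origin <- with_seed_test(seed + 200, runif(3, -10, 10))
    origin[1] <- round(origin[1] / g$z_step_um) * g$z_step_um
    ri <- sample_to_raw_index(pts$xp, pts$y, pts$zp, g, origin_um = origin)
    back <- raw_index_to_sample(ri$x_pix, ri$y_pix, ri$n, g, origin_um = origin)
    expect_lt(max(abs(back$xp_um - pts$xp), abs(back$y_um - pts$y),
                  abs(back$zp_um - pts$zp)), 1e-9)
  }
})

test_that("both scan modes invert to the same sample point", {
  for (seed in 1:5) {
    gob <- random_geometry(seed, "oblique_comp")
    gst <- acquisition_geometry(gob$theta_deg, gob$z_step_um,
                                gob$pixel_pitch_um, "standard_shear")
    p <- c(xp = 17.3, y = 4.2, zp = -6.1)
    b <- lapply(list(gob, gst), function(g) {
      ri <- sample_to_raw_index(p["xp"], p["y"], p["zp"], g)
      unlist(raw_index_to_sample(ri$x_pix, ri$y_pix, ri$n, g))
    })
    expect_lt(max(abs(b[[1]] - b[[2]])), 1e-9)
  }
})

test_that("compensated scans centre in-focus content; standard scans drift", {
  g <- acquisition_geometry(45, 1, 1.31, "oblique_comp")
  # points sharing z' map to the same camera column whatever their x'
  ri <- sample_to_raw_index(c(-40, 0, 80), c(5, 5, 5), c(12, 12, 12), g)
  expect_lt(diff(range(ri$x_pix)), 1e-9)
  expect_gt(diff(range(ri$n)), 1)           # ...recorded in different frames
  # z' pitch from camera x is p * cos(theta) = p / sqrt(2) at 45 degrees
  s1 <- raw_index_to_sample(1, 0, 0, g)
  s0 <- raw_index_to_sample(0, 0, 0, g)
  expect_equal(s1$zp_um - s0$zp_um, 1.31 / sqrt(2), tolerance = 1e-12)
  # in-plane step along x' per frame has magnitude sqrt(2) * z_step
  f1 <- raw_index_to_sample(0, 0, 1, g)
  expect_equal(abs(f1$xp_um - s0$xp_um), sqrt(2) * 1, tolerance = 1e-12)

  gs <- acquisition_geometry(45, 1, 1.31, "standard_shear")
  # in-focus content at fixed z' drifts by z_step * tan(theta) / p px/frame
  zp <- 7
  cam <- vapply(0:5, function(n) {
    # x' that is in focus at frame n for this z'
    ri <- sample_to_raw_index(
      xp_um = (sin(pi / 4) * zp - n * 1) / cos(pi / 4), y_um = 0, zp_um = zp, gs)
    ri$x_pix
  }, 0)
  expect_equal(diff(cam), rep(-tan(pi / 4) / 1.31, 5), tolerance = 1e-9)
})

test_that("affine bounding boxes match the 8-corner oracle exactly", {
  for (seed in 1:100) {
    g <- random_geometry(seed)
    shape <- with_seed_test(seed, sample(5:40, 3, replace = TRUE))
    origin <- c(-3.7, 1.2, 5.5)
    tr <- build_affine(g, shape, origin_um = origin)
    # independent oracle: transform all 8 corners through the point mapping
    corners <- expand.grid(k = c(0, shape[1] - 1), j = c(0, shape[2] - 1),
                           i = c(0, shape[3] - 1))
    sp <- raw_index_to_sample(corners$i, corners$j, corners$k, g,
                              origin_um = origin)
    mins <- c(min(sp$zp_um), min(sp$y_um), min(sp$xp_um))
    maxs <- c(max(sp$zp_um), max(sp$y_um), max(sp$xp_um))
    expect_equal(tr$out_origin_um,
                 floor(mins / tr$out_pitch_um) * tr$out_pitch_um,
                 tolerance = 1e-9)
    expect_identical(
      tr$output_shape,
      as.integer(floor((maxs - tr$out_origin_um) / tr$out_pitch_um + 1e-7)) + 1L)
    # determinant = input voxel volume / output voxel volume
    vin <- g$z_step_um * g$pixel_pitch_um^2
    expect_equal(abs(det(tr$A)), vin / prod(tr$out_pitch_um),
                 tolerance = 1e-9)
  }
})

test_that("affine structure reflects the reconstruction mode", {
  # perpendicular mounting with matched pitches: identity linear part
  g90 <- acquisition_geometry(90, 1, 1, "standard_shear")
  tr <- build_affine(g90, c(10, 10, 10), out_pitch_um = c(1, 1, 1))
  expect_equal(tr$A, diag(3), tolerance = 1e-12)

  # oblique path: z' never depends on the frame index (the 90-degree
  # reorientation maps camera x to the z' plane axis); single shear in x'
  gob <- acquisition_geometry(45, 1, 1.31, "oblique_comp")
  trob <- build_affine(gob, c(20, 10, 30))
  expect_equal(unname(trob$M_idx["zp", 1]), 0, tolerance = 1e-12)
  expect_equal(unname(trob$M_idx["zp", 2]), 0)
  # standard path: rotation block couples frame and camera x to both axes
  gst <- acquisition_geometry(45, 1, 1.31, "standard_shear")
  trst <- build_affine(gst, c(20, 10, 30))
  expect_true(all(abs(trst$M_idx[c("zp", "xp"), c(1, 3)]) > 1e-9))

  expect_error(build_affine(gob, c(0, 5, 5)), "positive")
  # padding: the compensated mode needs less than the standard mode for
  # one and the same acquired phantom
  ph <- separated_beads(6, c(80, 40, 20), 12, seed = 4)
  psf <- psf_model(1.2, 1.2, 2)
  raws <- lapply(c("oblique_comp", "standard_shear"), function(m)
    acquire(ph, psf, acquisition_geometry(45, 1, 1, m)))
  pads <- vapply(raws, function(r)
    build_affine(r$geometry, dim(r$data), r$origin_um)$padding_fraction, 0)
  expect_lt(pads[1], pads[2])
})

test_that("transform JSON export carries the row-major 3x4 matrix", {
  g <- acquisition_geometry(45, 1, 1.31, "oblique_comp")
  tr <- build_affine(g, c(10, 8, 12))
  js <- jsonlite::fromJSON(transform_to_json(tr))
  expect_equal(matrix(js$matrix_row_major, 3, 4, byrow = TRUE),
               cbind(tr$A, tr$b), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(js$output_shape, tr$output_shape)
})

test_that("optics helpers reproduce the instrument's worked numbers", {
  expect_equal(fov_diagonal(optics_spec(29, 5)), 5.8)
  expect_equal(fov_diagonal(optics_spec(29, 1)), 29)
  expect_equal(fov_diagonal(optics_spec(29, 2)), 14.5)
  na <- excitation_na(optics_spec(beam_diameter_mm = 10,
                                  excitation_focal_mm = 50))
  expect_equal(na, sin(atan(0.1)), tolerance = 1e-12)
  expect_equal(round(na, 1), 0.1)
  expect_equal(excitation_na(optics_spec(beam_diameter_mm = 1e-9,
                                         excitation_focal_mm = 50)), 0,
               tolerance = 1e-9)
  expect_equal(excitation_na(optics_spec(beam_diameter_mm = 100,
                                         excitation_focal_mm = 50,
                                         immersion_index = 1.33)),
               1.33 * sin(pi / 4), tolerance = 1e-12)
  expect_error(optics_spec(detection_magnification = 0), "positive")
})
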