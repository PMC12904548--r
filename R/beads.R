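#' Detect bead candidates as local intensity maxima
#'
#' Finds voxels above `intensity_threshold` that are maxima of their 26-voxel
#' neighbourhood, then applies non-maximum suppression at `min_separation_um`
#' (brighter bead wins; exact ties go to the lower linear index). The
#' procedure is deterministic.
#'
#' @param stack A [volume_stack()] in a single frame tag.
#' @param min_separation_um Minimum centre-to-centre distance between
#'   detections, in micrometres.
#' @param intensity_threshold Minimum peak intensity.
#' @return A data frame with 0-based voxel indices (`plane`, `row`, `col`),
#'   physical positions (`plane_um`, `row_um`, `col_um`) and `intensity`;
#'   empty when nothing is detected.
#' @export
detect_beads <- function(stack, min_separation_um, intensity_threshold) {
  stopifnot(inherits(stack, "volume_stack"))
  arr <- stack$data
  d <- dim(arr)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  is_max <- arr > intensity_threshold
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- pad[(2:(d[1] + 1)) + dx, (2:(d[2] + 1)) + dy, (2:(d[3] + 1)) + dz]
    is_max <- is_max & (arr >= nb)
  }
  idx <- which(is_max)
  empty <- data.frame(plane = integer(), row = integer(), col = integer(),
                      plane_um = numeric(), row_um = numeric(),
                      col_um = numeric(), intensity = numeric())
  if (!length(idx)) return(empty)
  ai <- arrayInd(idx, d) - 1L
  inten <- arr[idx]
  ord <- order(-inten, idx)
  ai <- ai[ord, , drop = FALSE]
  inten <- inten[ord]
  pos <- sweep(ai, 2, stack$spacing_um, "*")
  pos <- sweep(pos, 2, stack$origin_um, "+")
  keep <- logical(length(inten))
  for (q in seq_along(inten)) {
    if (q == 1L) { keep[1] <- TRUE; next }
    prev <- which(keep[seq_len(q - 1L)])
    dmin <- min(sqrt(rowSums(
      (pos[prev, , drop = FALSE] - rep(pos[q, ], each = length(prev)))^2)))
    keep[q] <- dmin >= min_separation_um
  }
  out <- data.frame(plane = ai[keep, 1], row = ai[keep, 2], col = ai[keep, 3],
                    plane_um = pos[keep, 1], row_um = pos[keep, 2],
                    col_um = pos[keep, 3], intensity = inten[keep])
  out[order(out$plane, out$row, out$col), , drop = FALSE]
}

#' Fit a Gaussian-plus-offset model to a 1D intensity profile
#'
#' Least-squares fit of `offset + amplitude * exp(-(t - mu)^2 / (2 sigma^2))`
#' with moment-based starting values. The coefficient of determination is
#' computed against the fitted model; degenerate profiles (constant, or
#' failed convergence) are flagged with `converged = FALSE` and `r2 = 0`.
#'
#' @param intensity Numeric vector of profile samples (at least 5).
#' @param spacing Sample spacing (used when `position` is not given).
#' @param position Optional sample positions; overrides `spacing`.
#' @return A list with `mu`, `sigma`, `amplitude`, `offset`, `r2`, `fwhm`
#'   (`2 sqrt(2 log 2) * sigma`) and `converged`.
#' @export
fit_profile_gaussian <- function(intensity, spacing = 1, position = NULL) {
  y <- as.numeric(intensity)
  if (length(y) < 5L) stop("profile must have at least 5 samples")
  t <- position %||% ((seq_along(y) - 1) * spacing)
  fail <- list(mu = NA_real_, sigma = NA_real_, amplitude = NA_real_,
               offset = NA_real_, r2 = 0, fwhm = NA_real_, converged = FALSE)
  if (max(y) == min(y)) return(fail)
  b0 <- min(y)
  a0 <- max(y) - b0
  w <- pmax(y - b0, 0)
  mu0 <- sum(t * w) / sum(w)
  s0 <- sqrt(sum((t - mu0)^2 * w) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(t)) / 6
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a * exp(-(t - mu)^2 / (2 * s^2)),
      start = list(b = b0, a = a0, mu = mu0, s = s0),
      lower = c(-Inf, 0, min(t) - diff(range(t)), 1e-6),
      upper = c(Inf, Inf, max(t) + diff(range(t)), 10 * diff(range(t))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- stats::coef(fit)
  resid <- y - stats::predict(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else 0
  list(mu = unname(cf["mu"]), sigma = abs(unname(cf["s"])),
       amplitude = unname(cf["a"]), offset = unname(cf["b"]),
       r2 = r2, fwhm = fwhm_from_sigma(abs(unname(cf["s"]))),
       converged = TRUE)
}

# lateral/axial axis roles by frame tag; stacks are (plane, row, col)
axis_roles <- function(frame) {
  # lab_raw: plane = detection axis (axial), row = camera y, col = camera x
  # sample:  plane = z' (axial),            row = y,        col = x'
  list(axial = 1L, lateral = c(2L, 3L))
}

#' Measure one bead: per-axis Gaussian profile fits
#'
#' Extracts a window around the detected bead, refines the centre with an
#' intensity-weighted centroid (background-subtracted), then fits a
#' Gaussian to three axis-aligned profiles through the refined centre.
#' Profiles are either interpolated line profiles through the centre
#' (default, PSFj-style) or sum projections of the window onto each axis.
#' The two lateral widths are reported sorted as `fwhm_min` and `fwhm_max`,
#' a labelling robust to astigmatism axis swaps; the plane-axis width is
#' `fwhm_axial` (z in a raw stack, z' in a sample-frame stack). A bead is
#' `accepted` when all three fits reach the R-squared threshold and the
#' window was not clipped by the stack boundary.
#'
#' @param stack A [volume_stack()].
#' @param center Length-3 0-based voxel index of the candidate (a row of
#'   [detect_beads()] output works via `unlist(row[c("plane","row","col")])`).
#' @param window_um Window edge length per axis in micrometres; default six
#'   times `expected_fwhm_um`.
#' @param expected_fwhm_um Expected FWHM per axis used to size the default
#'   window.
#' @param r2_threshold Acceptance threshold on all three R-squared values.
#' @param profile `"line"` or `"projection"`.
#' @return A one-row data frame: refined centre (um), per-axis `fwhm_*`,
#'   `sigma_*` and `r2_*` for plane/row/col, `fwhm_min`, `fwhm_max`,
#'   `fwhm_axial`, `accepted` and `reason`.
#' @export
measure_bead <- function(stack, center, window_um = NULL,
                         expected_fwhm_um = NULL, r2_threshold = 0.95,
                         profile = c("line", "projection")) {
  stopifnot(inherits(stack, "volume_stack"))
  profile <- match.arg(profile)
  d <- dim(stack$data)
  sp <- stack$spacing_um
  expected_fwhm_um <- expected_fwhm_um %||% (4 * sp)
  if (length(expected_fwhm_um) == 1L) expected_fwhm_um <- rep(expected_fwhm_um, 3)
  window_um <- window_um %||% (6 * expected_fwhm_um)
  if (length(window_um) == 1L) window_um <- rep(window_um, 3)
  hw <- pmax(2L, round(window_um / (2 * sp)))
  ctr <- as.integer(round(center)) + 1L          # to 1-based
  lo <- ctr - hw
  hi <- ctr + hw
  na_row <- data.frame(
    plane_um = NA_real_, row_um = NA_real_, col_um = NA_real_,
    fwhm_plane = NA_real_, fwhm_row = NA_real_, fwhm_col = NA_real_,
    sigma_plane = NA_real_, sigma_row = NA_real_, sigma_col = NA_real_,
    r2_plane = 0, r2_row = 0, r2_col = 0,
    fwhm_min = NA_real_, fwhm_max = NA_real_, fwhm_axial = NA_real_,
    accepted = FALSE, reason = "clipped", stringsAsFactors = FALSE)
  if (any(lo < 1L) || any(hi > d)) return(na_row)
  win <- stack$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  wd <- dim(win)
  bg <- min(win)
  w <- pmax(win - bg, 0)
  if (sum(w) == 0) { na_row$reason <- "empty"; return(na_row) }
  cg <- vapply(1:3, function(a) {
    m <- apply(w, a, sum)
    sum((seq_len(wd[a]) - 1) * m) / sum(m)
  }, 0)                                          # 0-based within window
  fits <- vector("list", 3L)
  for (a in 1:3) {
    if (profile == "projection") {
      vals <- apply(w, a, sum)
      pos <- (seq_len(wd[a]) - 1) * sp[a]
    } else {
      pts <- matrix(rep(cg, each = wd[a]), ncol = 3)
      pts[, a] <- seq_len(wd[a]) - 1
      vals <- interp_trilinear(win, pts)
      pos <- (seq_len(wd[a]) - 1) * sp[a]
    }
    fits[[a]] <- fit_profile_gaussian(vals, position = pos)
  }
  f <- vapply(fits, function(z) z$fwhm, 0)
  r2 <- vapply(fits, function(z) z$r2, 0)
  conv <- vapply(fits, function(z) z$converged, TRUE)
  ctr_um <- stack$origin_um + ((lo - 1L) + cg) * sp
  lat <- sort(f[2:3])
  accepted <- all(conv) && all(r2 >= r2_threshold)
  data.frame(
    plane_um = ctr_um[1], row_um = ctr_um[2], col_um = ctr_um[3],
    fwhm_plane = f[1], fwhm_row = f[2], fwhm_col = f[3],
    sigma_plane = fits[[1]]$sigma, sigma_row = fits[[2]]$sigma,
    sigma_col = fits[[3]]$sigma,
    r2_plane = r2[1], r2_row = r2[2], r2_col = r2[3],
    fwhm_min = lat[1], fwhm_max = lat[2], fwhm_axial = f[1],
    accepted = accepted,
    reason = if (accepted) "" else if (!all(conv)) "fit_failure" else "low_r2",
    stringsAsFactors = FALSE)
}

#' Measure a set of detected beads
#'
#' Applies [measure_bead()] to every row of a [detect_beads()] result.
#'
#' @param stack A [volume_stack()].
#' @param centers Data frame from [detect_beads()] (columns `plane`, `row`,
#'   `col`).
#' @param ... Passed to [measure_bead()].
#' @return A data frame with one row per candidate plus a `bead` id column.
#' @export
measure_beads <- function(stack, centers, ...) {
  rows <- lapply(seq_len(nrow(centers)), function(q)
    measure_bead(stack, unlist(centers[q, c("plane", "row", "col")]), ...))
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  cbind(bead = seq_len(nrow(out)), out)
}

#' Summarise FWHM distributions per group
#'
#' Cohort statistics over accepted bead fits, per group and per dimension
#' (`fwhm_min`, `fwhm_max`, `fwhm_axial`): mean, standard deviation,
#' median, quartiles and 1.5 x IQR whisker bounds, plus the lateral
#' anisotropy ratio A = FWHM_min / FWHM_max, reported both as the ratio of
#' group means (the headline statistic) and as the per-bead median.
#'
#' @param fits Data frame from [measure_beads()] (or any frame with
#'   `fwhm_min`, `fwhm_max`, `fwhm_axial`, `accepted`).
#' @param group Optional vector of group labels (e.g. mount or scan mode),
#'   one per row of `fits`.
#' @return A list with `per_dimension` (long-format statistics) and
#'   `anisotropy` (one row per group). Groups with no accepted fits are
#'   omitted with a warning.
#' @export
summarize_fwhm <- function(fits, group = NULL) {
  group <- group %||% rep("all", nrow(fits))
  stopifnot(length(group) == nrow(fits))
  keep <- fits$accepted & is.finite(fits$fwhm_min) & is.finite(fits$fwhm_axial)
  dropped <- setdiff(unique(group), unique(group[keep]))
  if (length(dropped))
    warning("groups with no accepted fits omitted: ",
            paste(dropped, collapse = ", "))
  fits <- fits[keep, , drop = FALSE]
  group <- group[keep]
  dims <- c("fwhm_min", "fwhm_max", "fwhm_axial")
  per_dim <- do.call(rbind, lapply(split(seq_along(group), group), function(ii) {
    do.call(rbind, lapply(dims, function(dm) {
      v <- fits[[dm]][ii]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      iqr <- q[3] - q[1]
      wl <- min(v[v >= q[1] - 1.5 * iqr])
      wh <- max(v[v <= q[3] + 1.5 * iqr])
      data.frame(group = group[ii[1]], dimension = dm, n_beads = length(v),
                 mean = mean(v), sd = stats::sd(v), median = q[2],
                 q25 = q[1], q75 = q[3], whisker_lo = wl, whisker_hi = wh,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(per_dim) <- NULL
  aniso <- do.call(rbind, lapply(split(seq_along(group), group), function(ii) {
    data.frame(group = group[ii[1]], n_beads = length(ii),
               anisotropy_mean = mean(fits$fwhm_min[ii]) /
                 mean(fits$fwhm_max[ii]),
               anisotropy_perbead_median =
                 stats::median(fits$fwhm_min[ii] / fits$fwhm_max[ii]),
               stringsAsFactors = FALSE)
  }))
  rownames(aniso) <- NULL
  list(per_dimension = per_dim, anisotropy = aniso)
}
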