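# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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

# Separable 3D Gaussian blur with sigma given in voxels per axis.
# Implemented as dense banded matrix products per axis; kernels are
# truncated at 4 sigma and renormalised.
gaussian_blur3d <- function(arr, sigma_vox) {
  stopifnot(length(dim(arr)) == 3L, length(sigma_vox) == 3L)
  d <- dim(arr)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    n <- d[axis]
    idx <- seq_len(n)
    K <- exp(-0.5 * (outer(idx, idx, "-") / s)^2)
    K <- K / rowSums(K)                       # renormalised truncation at edges
    m <- if (axis == 1L) {
      matrix(arr, nrow = d[1])
    } else if (axis == 2L) {
      matrix(aperm(arr, c(2, 1, 3)), nrow = d[2])
    } else {
      matrix(aperm(arr, c(3, 1, 2)), nrow = d[3])
    }
    m <- K %*% m
    arr <- if (axis == 1L) {
      array(m, d)
    } else if (axis == 2L) {
      aperm(array(m, d[c(2, 1, 3)]), c(2, 1, 3))
    } else {
      aperm(array(m, d[c(3, 1, 2)]), c(2, 3, 1))
    }
  }
  arr
}

# Otsu threshold on a numeric vector (maximises between-class variance over
# a 256-bin histogram of the value range).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(pmin(n_bins, 1L + floor((x - r[1]) / (r[2] - r[1]) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(n_bins) - 0.5) * (r[2] - r[1]) / n_bins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# Trilinear interpolation of a 3D array at continuous 0-based indices.
# pts: matrix with columns (plane, row, col). Out-of-bounds reads return 0.
interp_trilinear <- function(arr, pts) {
  d <- dim(arr)
  out <- numeric(nrow(pts))
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  xf <- floor(x); yf <- floor(y); zf <- floor(z)
  fx <- x - xf; fy <- y - yf; fz <- z - zf
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    xi <- xf + dx; yi <- yf + dy; zi <- zf + dz
    w <- (dx * fx + (1 - dx) * (1 - fx)) *
         (dy * fy + (1 - dy) * (1 - fy)) *
         (dz * fz + (1 - dz) * (1 - fz))
    ok <- xi >= 0 & xi < d[1] & yi >= 0 & yi < d[2] & zi >= 0 & zi < d[3] & w > 0
    if (any(ok)) {
      lin <- xi[ok] + d[1] * (yi[ok] + d[2] * zi[ok]) + 1
      out[ok] <- out[ok] + w[ok] * arr[lin]
    }
  }
  out
}
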