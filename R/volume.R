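#' 3D intensity stack with spacing and frame metadata
#'
#' The package's volume container: a numeric 3D array indexed
#' (plane, row, column) with per-axis voxel spacing, a frame tag saying
#' whether the stack is a raw camera acquisition (`"lab_raw"`: planes are
#' frames, rows are camera y, columns are camera x) or a reconstructed
#' sample-frame volume (`"sample"`: planes are z', rows y, columns x'),
#' the originating [acquisition_geometry()], and a nominal storage dtype
#' used for byte accounting.
#'
#' @param data Numeric 3D array, dimension (plane, row, col).
#' @param spacing_um Length-3 voxel spacing in micrometres (plane, row, col).
#' @param origin_um Length-3 coordinate of voxel (0, 0, 0). For `lab_raw`
#'   stacks the plane-axis origin is expressed as stage travel
#'   (frame offset times z step).
#' @param frame `"lab_raw"` or `"sample"`.
#' @param geometry Optional [acquisition_geometry()].
#' @param dtype Nominal storage type: `"uint16"` (default), `"float32"` or
#'   `"uint8"`.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(data, spacing_um, origin_um = c(0, 0, 0),
                         frame = c("lab_raw", "sample"), geometry = NULL,
                         dtype = c("uint16", "float32", "uint8")) {
  frame <- match.arg(frame)
  dtype <- match.arg(dtype)
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (length(spacing_um) != 3L || any(spacing_um <= 0))
    stop("spacing_um must be three positive values")
  if (length(origin_um) != 3L) stop("origin_um must have length 3")
  structure(list(data = data, spacing_um = as.numeric(spacing_um),
                 origin_um = as.numeric(origin_um), frame = frame,
                 geometry = geometry, dtype = dtype),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  cat(sprintf("volume_stack [%s, %s]: %s voxels, spacing (%s) um\n",
              x$frame, x$dtype, paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing_um, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.volume_stack <- function(x) dim(x$data)

bytes_per_voxel <- function(x) {
  dtype <- if (inherits(x, "volume_stack")) x$dtype else x
  switch(dtype, uint16 = 2L, float32 = 4L, uint8 = 1L,
         stop("unknown dtype: ", dtype))
}

#' Total stored size of a stack in bytes
#'
#' Uncompressed voxel count times the nominal dtype size. Container
#' overhead of any particular file format is deliberately excluded so that
#' size factors between acquisition modes are comparable.
#'
#' @param stack A [volume_stack()].
#' @return Number of bytes.
#' @export
stack_bytes <- function(stack) {
  stopifnot(inherits(stack, "volume_stack"))
  prod(as.numeric(dim(stack$data))) * bytes_per_voxel(stack)
}

# Physical coordinates (um) of 0-based voxel indices along one axis.
axis_coords <- function(stack, axis) {
  stack$origin_um[axis] + (seq_len(dim(stack$data)[axis]) - 1) * stack$spacing_um[axis]
}
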