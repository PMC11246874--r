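#' Construct a volume grid
#'
#' A `volume_grid` is the package's unit of volumetric I/O: one 3D scalar
#' image together with its physical voxel spacing.  The axis convention is
#' fixed throughout the package as (slice, row, col), 0-based in all
#' coordinate arithmetic, with `spacing` giving the physical size of one
#' voxel step along each of those axes in millimetres (slice gap, row
#' spacing, column spacing).
#'
#' Volumes containing non-finite values are rejected at construction time so
#' NaN/Inf can never propagate silently into normalization or training.
#'
#' @param data 3D numeric array, dimensions (slices, rows, cols), each >= 1.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin_note free-text provenance tag carried along unmodified.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing, origin_note = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume_grid: 'data' must be a 3D array (slices x rows x cols)")
  if (any(dim(data) < 1L))
    stop("volume_grid: every axis must have length >= 1")
  if (!all(is.finite(data)))
    stop("volume_grid: non-finite intensities (NaN/Inf) are not allowed")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("volume_grid: 'spacing' must be 3 positive numbers (mm)")
  structure(
    list(data = data, spacing = spacing, origin_note = as.character(origin_note)[1]),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %d x %d x %d (slice x row x col)\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing : %.4g x %.4g x %.4g mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  range   : [%.4g, %.4g]\n", min(x$data), max(x$data)))
  if (nzchar(x$origin_note)) cat("  origin  : ", x$origin_note, "\n", sep = "")
  invisible(x)
}

#' Read a medical image volume
#'
#' Reads a NIfTI file or a directory containing one DICOM series into a
#' [volume_grid()].  Intensities are passed through unmodified; spacing is
#' taken from the file header(s).  For NIfTI the on-disk axis order (x, y, z)
#' is mapped to the package convention so that axis 3 of the file becomes the
#' slice axis; for DICOM the slice axis is the series' position axis.
#'
#' The DICOM reader handles uncompressed explicit-VR little-endian series
#' (the common export format for MR); it validates that slice positions form
#' a uniform grid and reports the offending neighbours when they do not
#' (e.g. a missing slice).
#'
#' @param path file path (NIfTI) or directory path (DICOM series).
#' @param format `"nifti"` or `"dicom_series"`.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path, format = c("nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "nifti") {
    if (!file.exists(path)) stop("read_volume: no such file: ", path)
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) != 3L)
      stop("read_volume: expected a 3D NIfTI, got ", length(dim(a)), " dims")
    pd <- RNifti::pixdim(img)
    # on-disk (x=col-fastest, y, z=slice); package order is (slice, row, col)
    data <- aperm(a, c(3, 2, 1))
    volume_grid(data, spacing = c(pd[3], pd[2], pd[1]),
                origin_note = paste0("nifti:", path))
  } else {
    read_dicom_series(path)
  }
}

#' Write a volume as NIfTI
#'
#' Inverse of [read_volume()]: the slice axis is written as the NIfTI z axis.
#' Data are stored as float64, so a write/read round-trip reproduces the
#' array bit-for-bit and the spacing to header precision.
#'
#' @param vol a [volume_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param format only `"nifti"` is supported.
#' @param datatype on-disk scalar type (default `"double"`, which makes the
#'   round-trip bit-exact; `"float"` halves file size for bulk intermediate
#'   stacks).
#' @return `invisible(path)`.
#' @export
write_volume <- function(vol, path, format = "nifti", datatype = "double") {
  stopifnot(inherits(vol, "volume_grid"))
  format <- match.arg(format, "nifti")
  if (!dir.exists(dirname(path)))
    stop("write_volume: parent directory does not exist: ", dirname(path))
  a <- aperm(vol$data, c(3, 2, 1))   # back to (x, y, z=slice)
  storage.mode(a) <- "double"
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(vol$spacing[3], vol$spacing[2], vol$spacing[1])
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

## ---- resampling ------------------------------------------------------------

# Interpolation weights mapping n_in samples at spacing s_in onto n_out
# samples at spacing s_out, both grids anchored at physical coordinate 0.
# Returns an n_out x n_in matrix with at most two non-zeros per row (linear)
# or exactly one (nearest).  Positions beyond the input extent (possible by
# < s_out from the rounding convention) clamp to the edge sample.
interp_weights <- function(n_in, s_in, n_out, s_out, interp) {
  pos <- (seq_len(n_out) - 1) * s_out / s_in     # in input-index units
  pos <- pmin(pmax(pos, 0), n_in - 1)
  W <- matrix(0, n_out, n_in)
  if (interp == "nearest") {
    j <- floor(pos + 0.5)
    j <- pmin(j, n_in - 1)
    W[cbind(seq_len(n_out), j + 1)] <- 1
  } else {
    j0 <- pmin(floor(pos), n_in - 2)
    j0 <- pmax(j0, 0)
    t <- pos - j0
    W[cbind(seq_len(n_out), j0 + 1)] <- W[cbind(seq_len(n_out), j0 + 1)] + (1 - t)
    W[cbind(seq_len(n_out), j0 + 2)] <- W[cbind(seq_len(n_out), j0 + 2)] + t
  }
  W
}

# 1-based source indices realizing nearest-neighbour interpolation along one
# axis (same grid convention as interp_weights)
nearest_index_map <- function(n_in, s_in, n_out, s_out) {
  pos <- (seq_len(n_out) - 1) * s_out / s_in
  pos <- pmin(pmax(pos, 0), n_in - 1)
  pmin(floor(pos + 0.5), n_in - 1) + 1
}

# Apply an n_out x n_in weight matrix along axis `axis` of a 3D array.
apply_axis <- function(a, W, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- if (axis == 1) a else aperm(a, perm)
  dp <- dim(ap)
  m <- W %*% matrix(ap, nrow = dp[1])
  out <- array(m, dim = c(nrow(W), dp[2], dp[3]))
  if (axis == 1) out else aperm(out, order(perm))
}

# src/dst index ranges realizing a symmetric center-crop (n > tgt) or
# symmetric zero-pad (n < tgt) of one axis
crop_pad_ranges <- function(n, tgt) {
  if (n >= tgt) {
    start <- floor((n - tgt) / 2)
    list(src = (start + 1):(start + tgt), dst = 1:tgt, offset = -start)
  } else {
    pad_lo <- floor((tgt - n) / 2)
    list(src = 1:n, dst = (pad_lo + 1):(pad_lo + n), offset = pad_lo)
  }
}

# Symmetric center-crop or zero-pad a 3D array's axes 2:3 to `plane_size`.
crop_pad_plane <- function(a, plane_size) {
  d <- dim(a)
  if (d[2] == plane_size[1] && d[3] == plane_size[2]) return(a)
  r2 <- crop_pad_ranges(d[2], plane_size[1])
  r3 <- crop_pad_ranges(d[3], plane_size[2])
  out <- array(0, c(d[1], plane_size[1], plane_size[2]))
  out[, r2$dst, r3$dst] <- a[, r2$src, r3$src, drop = FALSE]
  out
}

#' Resample a volume to a target grid
#'
#' Interpolates a volume onto a new physical grid (typically 1 mm isotropic)
#' and standardizes the in-plane matrix to `plane_size` (typically 512 x 512)
#' by symmetric center-crop or symmetric zero-pad.  Both the input and output
#' grids are treated as point lattices anchored at the same physical origin,
#' so the slice count follows the endpoint-preserving convention
#' `n_out = round((n_in - 1) * s_in / s_out) + 1`: the first and last input
#' slices are reproduced exactly and the physical extent changes by less than
#' one target spacing per axis.
#'
#' Linear interpolation reproduces any intensity field that is affine in
#' physical coordinates exactly (used for images); nearest-neighbour
#' interpolation introduces no new intensity values (used for label masks).
#'
#' @param vol a [volume_grid()].
#' @param target_spacing length-3 positive mm spacing of the output grid.
#' @param plane_size length-2 (rows, cols) of the standardized plane, or
#'   `NULL` to keep the interpolated in-plane size.
#' @param interp `"linear"` or `"nearest"`.
#' @return A [volume_grid()] on the target grid.
#' @export
resample_volume <- function(vol, target_spacing = c(1, 1, 1),
                            plane_size = c(512, 512),
                            interp = c("linear", "nearest")) {
  stopifnot(inherits(vol, "volume_grid"))
  interp <- match.arg(interp)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("resample_volume: target_spacing must be 3 positive numbers")
  d <- dim(vol$data)
  n_out <- round((d - 1) * vol$spacing / target_spacing) + 1
  n_out <- pmax(n_out, 1)
  a <- vol$data
  if (interp == "nearest") {
    # nearest resampling is a pure index re-map: subset instead of matmul
    maps <- lapply(1:3, function(ax)
      nearest_index_map(d[ax], vol$spacing[ax], n_out[ax], target_spacing[ax]))
    a <- a[maps[[1]], maps[[2]], maps[[3]], drop = FALSE]
  } else {
    for (ax in 1:3) {
      if (n_out[ax] == d[ax] && vol$spacing[ax] == target_spacing[ax]) next
      W <- interp_weights(d[ax], vol$spacing[ax], n_out[ax], target_spacing[ax], interp)
      a <- apply_axis(a, W, ax)
    }
  }
  if (!is.null(plane_size)) {
    plane_size <- as.integer(plane_size)
    stopifnot(length(plane_size) == 2L, all(plane_size >= 1))
    a <- crop_pad_plane(a, plane_size)
  }
  volume_grid(a, spacing = target_spacing,
              origin_note = paste0(vol$origin_note, "|resampled"))
}
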