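#' Pad in-plane extents to a common multiple of eight
#'
#' Pads the coronal and sagittal extents to one shared size `S`, the smallest
#' multiple of `pad_multiple` that is at least as large as both. The axial
#' extent is unchanged and the original content is centered, with the extra
#' voxel going to the high side when a pad width is odd. Density volumes are
#' padded with the truncation floor (-400 mg HA/cm^3), standardized volumes
#' with -1, and masks with background (0), so padding always looks like
#' background to the network and the morphology.
#'
#' @param x a [density_volume()], [normalized_volume()] or
#'   [compartment_mask()].
#' @param pad_multiple extents are padded up to a multiple of this (default 8,
#'   matching the U-Net's down/upsampling factor granularity).
#' @return An object of the same class as `x` with square in-plane extents.
#' @export
#' @examples
#' v <- density_volume(array(0, c(4, 155, 141)))
#' dim(pad_in_plane(v)$voxels)   # 4 160 160
pad_in_plane <- function(x, pad_multiple = 8L) {
  UseMethod("pad_in_plane")
}

#' @export
pad_in_plane.density_volume <- function(x, pad_multiple = 8L) {
  x$voxels <- pad_array(x$voxels, pad_multiple, fill = -400)
  x
}

#' @export
pad_in_plane.normalized_volume <- function(x, pad_multiple = 8L) {
  x$voxels <- pad_array(x$voxels, pad_multiple, fill = -1)
  x
}

#' @export
pad_in_plane.compartment_mask <- function(x, pad_multiple = 8L) {
  x$voxels <- pad_array(x$voxels, pad_multiple, fill = FALSE)
  x
}

pad_target_size <- function(d, pad_multiple = 8L) {
  as.integer(pad_multiple * ceiling(max(d[2], d[3]) / pad_multiple))
}

pad_array <- function(a, pad_multiple, fill) {
  d <- dim(a)
  s <- pad_target_size(d, pad_multiple)
  if (d[2] == s && d[3] == s) return(a)
  out <- array(fill, dim = c(d[1], s, s))
  lo2 <- (s - d[2]) %/% 2L
  lo3 <- (s - d[3]) %/% 2L
  out[, lo2 + seq_len(d[2]), lo3 + seq_len(d[3])] <- a
  out
}

# Inverse of pad_array: recover the centered original extents.
crop_array <- function(a, orig_dim) {
  d <- dim(a)
  lo2 <- (d[2] - orig_dim[2]) %/% 2L
  lo3 <- (d[3] - orig_dim[3]) %/% 2L
  a[, lo2 + seq_len(orig_dim[2]), lo3 + seq_len(orig_dim[3]), drop = FALSE]
}

#' Standardize densities onto \[-1, 1\]
#'
#' Truncated linear mapping of calibrated densities: values are clamped to
#' `[-400, 1400]` mg HA/cm^3 and rescaled as `(2 * rho - 1000) / 1800`, so
#' -400 maps to -1, 1400 to 1 and 275 mg HA/cm^3 to -0.25 (the density
#' threshold used by the morphological bone mask filter).
#'
#' @param vol a [density_volume()].
#' @param floor,ceiling truncation bounds in mg HA/cm^3.
#' @return A [normalized_volume()].
#' @export
#' @examples
#' v <- density_volume(array(c(-400, 275, 1400), c(3, 1, 1)))
#' standardize(v)$voxels[, 1, 1]   # -1 -0.25 1
standardize <- function(vol, floor = -400, ceiling = 1400) {
  stopifnot(inherits(vol, "density_volume"))
  rho <- pmin(pmax(vol$voxels, floor), ceiling)
  nv <- (2 * rho - (floor + ceiling)) / (ceiling - floor)
  normalized_volume(array(nv, dim = dim(vol$voxels)), vol$voxel_size_mm,
                    vol$name)
}

#' Invert the density standardization
#'
#' Exact inverse of [standardize()] for densities inside the non-truncated
#' range `[-400, 1400]`.
#'
#' @param nv a [normalized_volume()] (values in `[-1, 1]`).
#' @param floor,ceiling truncation bounds used by [standardize()].
#' @return A [density_volume()].
#' @export
destandardize <- function(nv, floor = -400, ceiling = 1400) {
  stopifnot(inherits(nv, "normalized_volume"))
  rng <- range(nv$voxels)
  if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9)
    stop("input values outside [-1, 1]")
  rho <- ((ceiling - floor) * nv$voxels + (floor + ceiling)) / 2
  density_volume(array(rho, dim = dim(nv$voxels)), nv$voxel_size_mm, nv$name)
}

#' Build the five-slice input stack for one axial position
#'
#' Returns slices `c-2, c-1, c, c+1, c+2` of the volume, stacked on the first
#' dimension. Indices beyond the volume ends are mirror-reflected about the
#' boundary without repeating the edge slice (for a 1-based center `c = 1`:
#' indices 3, 2, 1, 2, 3).
#'
#' @param nv a [normalized_volume()] with at least 3 axial slices.
#' @param center_index 1-based axial index of the slice to predict.
#' @return A [slice_stack()].
#' @export
make_slice_stack <- function(nv, center_index) {
  stopifnot(inherits(nv, "normalized_volume"))
  n <- dim(nv$voxels)[1]
  if (n < 3L) stop("volume must have at least 3 axial slices")
  center_index <- as.integer(center_index)
  if (center_index < 1L || center_index > n)
    stop("center_index out of range")
  idx <- reflect_index(center_index + (-2L:2L), n)
  slice_stack(nv$voxels[idx, , , drop = FALSE], center_index)
}

# mirror indexing excluding the boundary sample (numpy/ITK "reflect"):
# 0 -> 2, -1 -> 3, n+1 -> n-1, n+2 -> n-2 (1-based)
reflect_index <- function(i, n) {
  i <- ifelse(i < 1L, 2L - i, i)
  i <- ifelse(i > n, 2L * n - i, i)
  if (any(i < 1L | i > n)) stop("reflection out of range; volume too short")
  as.integer(i)
}
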