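#' Calibrated density volume
#'
#' Container for a 3D grid of calibrated bone densities in mg HA/cm^3 on an
#' isotropic voxel grid. The first array axis is the axial (slice) axis, so a
#' single slice is `voxels[z, , ]`, a coronal x sagittal matrix.
#'
#' @param voxels numeric 3D array of densities (mg HA/cm^3),
#'   indexed `[axial, coronal, sagittal]`.
#' @param voxel_size_mm positive isotropic voxel size in mm (HR-pQCT second
#'   generation scans use 0.0607 mm).
#' @param name free-text identifier carried through the pipeline.
#' @return An object of class `density_volume` with fields `voxels`,
#'   `voxel_size_mm` and `name`.
#' @export
#' @examples
#' vol <- density_volume(array(0, c(4, 8, 8)))
#' dim(vol$voxels)
density_volume <- function(voxels, voxel_size_mm = 0.0607, name = "") {
  voxels <- check_grid3(voxels, "voxels")
  if (!all(is.finite(voxels))) stop("densities must be finite")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("voxel_size_mm must be a positive scalar")
  structure(list(voxels = voxels, voxel_size_mm = as.numeric(voxel_size_mm),
                 name = as.character(name)),
            class = "density_volume")
}

#' Standardized (unitless) volume
#'
#' Densities mapped onto `[-1, 1]` by [standardize()]; the direct input
#' representation for the U-Net.
#'
#' @param voxels numeric 3D array with all values in `[-1, 1]`.
#' @param voxel_size_mm positive isotropic voxel size in mm.
#' @param name free-text identifier.
#' @return An object of class `normalized_volume`.
#' @export
normalized_volume <- function(voxels, voxel_size_mm = 0.0607, name = "") {
  voxels <- check_grid3(voxels, "voxels")
  rng <- range(voxels)
  if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9)
    stop("normalized volume values must lie in [-1, 1]")
  structure(list(voxels = voxels, voxel_size_mm = as.numeric(voxel_size_mm),
                 name = as.character(name)),
            class = "normalized_volume")
}

#' Binary compartment mask
#'
#' @param voxels logical or 0/1 numeric 3D array, `[axial, coronal, sagittal]`.
#' @param label one of `"cortical"`, `"trabecular"`, `"bone"`, `"background"`.
#' @param voxel_size_mm positive isotropic voxel size in mm.
#' @return An object of class `compartment_mask`; `voxels` is stored as a
#'   logical array.
#' @export
#' @examples
#' m <- compartment_mask(array(c(0, 1), c(2, 4, 4)), "cortical")
#' sum(m$voxels)
compartment_mask <- function(voxels, label = c("bone", "cortical",
                                               "trabecular", "background"),
                             voxel_size_mm = 0.0607) {
  label <- match.arg(label)
  voxels <- check_grid3(voxels, "voxels")
  if (is.numeric(voxels)) {
    if (!all(voxels %in% c(0, 1))) stop("mask values must be 0 or 1")
    voxels <- array(voxels != 0, dim = dim(voxels))
  }
  if (!is.logical(voxels)) stop("mask voxels must be logical or 0/1 numeric")
  structure(list(voxels = voxels, label = label,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "compartment_mask")
}

#' Disjoint cortical/trabecular segmentation
#'
#' @param cortical,trabecular [compartment_mask()] objects (or logical arrays)
#'   on the same grid; they must not overlap.
#' @param voxel_size_mm voxel size used when plain arrays are supplied.
#' @return An object of class `segmentation_pair` with `$cortical` and
#'   `$trabecular` compartment masks.
#' @export
segmentation_pair <- function(cortical, trabecular, voxel_size_mm = 0.0607) {
  if (!inherits(cortical, "compartment_mask"))
    cortical <- compartment_mask(cortical, "cortical", voxel_size_mm)
  if (!inherits(trabecular, "compartment_mask"))
    trabecular <- compartment_mask(trabecular, "trabecular", voxel_size_mm)
  if (!identical(dim(cortical$voxels), dim(trabecular$voxels)))
    stop("cortical and trabecular masks must share a grid")
  if (any(cortical$voxels & trabecular$voxels))
    stop("cortical and trabecular masks overlap")
  structure(list(cortical = cortical, trabecular = trabecular),
            class = "segmentation_pair")
}

#' Five-slice input stack for the U-Net
#'
#' @param slices numeric array `5 x H x W`: the center slice flanked by its two
#'   neighbors on each side (reflected at the volume ends).
#' @param center_index 1-based axial index of the center slice in the source
#'   volume.
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(slices, center_index) {
  if (!is.array(slices) || length(dim(slices)) != 3L || dim(slices)[1] != 5L)
    stop("slices must be a 5 x H x W array")
  if (dim(slices)[2] %% 8L != 0L || dim(slices)[3] %% 8L != 0L)
    stop("in-plane extents of a slice stack must be multiples of 8 (pad first)")
  structure(list(slices = slices, center_index = as.integer(center_index)),
            class = "slice_stack")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<density_volume> %s%d x %d x %d voxels (axial x coronal x sagittal), %.4f mm\n",
              if (nzchar(x$name)) paste0(x$name, ": ") else "",
              d[1], d[2], d[3], x$voxel_size_mm))
  cat(sprintf("  density range [%.1f, %.1f] mg HA/cm^3\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.compartment_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<compartment_mask> %s, %d x %d x %d, %d foreground voxels\n",
              x$label, d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

#' @export
print.segmentation_pair <- function(x, ...) {
  cat("<segmentation_pair>\n  ")
  print(x$cortical)
  cat("  ")
  print(x$trabecular)
  invisible(x)
}

# shared validation for rank-3 grids
check_grid3 <- function(x, what) {
  if (is.logical(x) || is.integer(x)) storage_ok <- TRUE
  else if (is.numeric(x)) storage_ok <- TRUE
  else storage_ok <- FALSE
  if (!storage_ok || !is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("%s must be a rank-3 array", what))
  if (any(dim(x) < 1L)) stop(sprintf("%s must have all extents >= 1", what))
  if (is.integer(x)) x <- array(as.numeric(x), dim = dim(x))
  x
}
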