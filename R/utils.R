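#' Convert between millimetres and voxels
#'
#' Convenience conversions at a given isotropic voxel size. At the HR-pQCT
#' voxel size of 0.0607 mm, 0.91 mm corresponds to approximately 15 voxels and
#' an 8-voxel dilation to approximately 0.5 mm.
#'
#' @param mm,voxels quantity to convert.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @return Numeric vector of converted values.
#' @export
#' @examples
#' mm_to_voxels(0.91)      # ~15
#' voxels_to_mm(8)         # ~0.49
mm_to_voxels <- function(mm, voxel_size_mm = 0.0607) {
  stopifnot(voxel_size_mm > 0)
  mm / voxel_size_mm
}

#' @rdname mm_to_voxels
#' @export
voxels_to_mm <- function(voxels, voxel_size_mm = 0.0607) {
  stopifnot(voxel_size_mm > 0)
  voxels * voxel_size_mm
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# logical 3D array helpers ----------------------------------------------------

as_mask_array <- function(x) {
  if (inherits(x, "compartment_mask")) return(x$voxels)
  if (is.array(x) && length(dim(x)) == 3L) {
    if (is.logical(x)) return(x)
    if (is.numeric(x)) return(array(x != 0, dim = dim(x)))
  }
  stop("expected a compartment_mask or a logical rank-3 array")
}

mask_like <- function(template, voxels, label = NULL) {
  if (inherits(template, "compartment_mask"))
    compartment_mask(voxels, label %||% template$label, template$voxel_size_mm)
  else compartment_mask(voxels, label %||% "bone")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
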