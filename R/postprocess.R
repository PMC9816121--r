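#' Post-processing parameters
#'
#' Constants of the morphological post-processing procedure. Defaults follow
#' the published protocol: open/close maximum radii of 5/15 voxels for the
#' network masks and 3/15 for the density-derived bone mask, an 8-voxel
#' (~0.5 mm) minimum cortical shell, a -0.25 normalized density threshold
#' (275 mg HA/cm^3), and a 3 x 3 x 1 in-plane median kernel.
#'
#' @param open_max_radius_unet,close_max_radius_unet maximum structuring
#'   element radii (voxels) of the iterative filter applied to U-Net masks.
#' @param open_max_radius_bone,close_max_radius_bone radii for the
#'   morphological bone mask filter.
#' @param shell_thickness minimum cortical shell thickness in voxels.
#' @param bone_threshold_normalized density threshold in standardized
#'   (`[-1, 1]`) intensity space.
#' @param fg_connectivity,bg_connectivity connectivities used for foreground
#'   components and background hole-filling (standard complementary pair
#'   26/6).
#' @return A list of class `postprocess_params`.
#' @export
postprocess_params <- function(open_max_radius_unet = 5L,
                               close_max_radius_unet = 15L,
                               open_max_radius_bone = 3L,
                               close_max_radius_bone = 15L,
                               shell_thickness = 8L,
                               bone_threshold_normalized = -0.25,
                               fg_connectivity = 26L,
                               bg_connectivity = 6L) {
  stopifnot(open_max_radius_unet >= 1, close_max_radius_unet >= 1,
            open_max_radius_bone >= 1, close_max_radius_bone >= 1,
            shell_thickness >= 1,
            bone_threshold_normalized >= -1, bone_threshold_normalized <= 1)
  structure(list(open_max_radius_unet = as.integer(open_max_radius_unet),
                 close_max_radius_unet = as.integer(close_max_radius_unet),
                 open_max_radius_bone = as.integer(open_max_radius_bone),
                 close_max_radius_bone = as.integer(close_max_radius_bone),
                 shell_thickness = as.integer(shell_thickness),
                 bone_threshold_normalized = bone_threshold_normalized,
                 fg_connectivity = as.integer(fg_connectivity),
                 bg_connectivity = as.integer(bg_connectivity)),
            class = "postprocess_params")
}

#' Iterative binary segmentation filter
#'
#' A modified alternating sequential filter: for structuring-element radii
#' r = 1, 2, ... the mask is opened (up to `open_max`) and closed (up to
#' `close_max`) with Euclidean balls, with two connectivity steps inserted:
#' between the erosion and dilation of the open only the largest foreground
#' component is kept, and between the dilation and erosion of the close only
#' the largest background component is kept (all enclosed cavities are
#' filled). Removes union and subtractive noise and excludes the secondary
#' bone (ulna/fibula) from the primary mask.
#'
#' Border conventions: the open's erosion is computed relative to the
#' observed (in-grid) background, so a bone spanning the axial ends of the
#' scan is not artificially trimmed there; the close runs on a grid padded
#' by its radius, which keeps it extensive near the image border and
#' guarantees that the outside background is a single (and the largest)
#' component when the largest-background-component rule is applied.
#'
#' @param mask binary 3D mask ([compartment_mask()] or logical array).
#' @param open_max,close_max maximum ball radii (voxels) of the open and
#'   close passes.
#' @param fg_connectivity,bg_connectivity component connectivities.
#' @return Same type as `mask`. If an erosion empties the mask a warning is
#'   emitted and an empty mask returned.
#' @export
iterative_binary_segmentation_filter <- function(mask, open_max = 5L,
                                                 close_max = 15L,
                                                 fg_connectivity = 26L,
                                                 bg_connectivity = 6L) {
  m <- as_mask_array(mask)
  was_mask <- inherits(mask, "compartment_mask")
  if (!any(m)) return(mask)
  for (r in seq_len(max(open_max, close_max))) {
    if (r <= open_max) {
      er <- binary_erode(m, r, border = "foreground")
      if (!any(er)) {
        warning("mask vanished during opening at radius ", r)
        m <- er
        break
      }
      m <- binary_dilate(largest_component(er, fg_connectivity), r)
    }
    if (r <= close_max)
      m <- close_with_fill(m, r, bg_connectivity)
  }
  if (was_mask) mask_like(mask, m) else m
}

#' Minimum cortical shell filter
#'
#' Dilates the trabecular mask by `shell_thickness` voxels (8 voxels is
#' ~0.5 mm at the 0.0607 mm voxel size) and subtracts the original, leaving
#' a shell that guarantees a minimum cortical thickness around the
#' trabecular compartment.
#'
#' @param trab trabecular mask ([compartment_mask()] or logical array).
#' @param shell_thickness dilation radius in voxels.
#' @return Shell mask of the same type as `trab`; disjoint from `trab` by
#'   construction; empty input yields an empty shell.
#' @export
minimum_cortical_shell_filter <- function(trab, shell_thickness = 8L) {
  m <- as_mask_array(trab)
  shell <- binary_dilate(m, shell_thickness) & !m
  if (inherits(trab, "compartment_mask"))
    mask_like(trab, shell, label = "cortical")
  else shell
}

#' Morphological bone mask filter
#'
#' The first step of the classical dual-threshold segmentation: the
#' standardized image is binarized at -0.25 (275 mg HA/cm^3), smoothed with
#' a 3 x 3 x 1 in-plane binary median filter, and cleaned with the
#' iterative binary segmentation filter (open/close maxima 3/15). The result
#' is a rough single-component mask of the whole primary bone, used as a
#' safety net against the network missing part of the bone.
#'
#' @param nv a [normalized_volume()].
#' @param params a [postprocess_params()] set.
#' @return A [compartment_mask()] with label `"bone"`; a warning is emitted
#'   if it comes out empty (possible catastrophic miss).
#' @export
morphological_bone_mask_filter <- function(nv, params = postprocess_params()) {
  stopifnot(inherits(nv, "normalized_volume"))
  thr <- nv$voxels >= params$bone_threshold_normalized
  med <- array(cpp_binary_median3x3(thr, dim(thr)), dim(thr))
  m <- iterative_binary_segmentation_filter(
    med, params$open_max_radius_bone, params$close_max_radius_bone,
    params$fg_connectivity, params$bg_connectivity)
  if (!any(m)) warning("morphological bone mask is empty")
  compartment_mask(m, "bone", nv$voxel_size_mm)
}

#' Morphological post-processing of a raw segmentation
#'
#' Enforces the topology of distal radius/tibia anatomy on the raw network
#' masks: one connected component per compartment, no background gaps
#' between them, and a minimum-thickness cortical shell separating the
#' trabecular compartment from the background. Procedure: (1) filter the
#' raw trabecular mask with the iterative filter; (2) derive the minimum
#' cortical shell from it; (3) filter the raw whole-bone mask
#' (cortical OR trabecular) with the iterative filter; (4) compute the
#' density-based bone mask; (5) union (3), (4), the filtered trabecular
#' mask and the shell into the final bone mask; (6) subtract the filtered
#' trabecular mask to obtain the cortical mask.
#'
#' @param nv the standardized image the raw masks came from (a
#'   [normalized_volume()]).
#' @param raw a raw [segmentation_pair()] from [embeddings_to_masks()].
#' @param params a [postprocess_params()] set.
#' @return A cleaned [segmentation_pair()]; cortical and trabecular are
#'   disjoint and the shell is contained in the cortical mask.
#' @export
postprocess_segmentation <- function(nv, raw, params = postprocess_params()) {
  stopifnot(inherits(nv, "normalized_volume"),
            inherits(raw, "segmentation_pair"))
  if (!identical(dim(nv$voxels), dim(raw$cortical$voxels)))
    stop("image and raw mask shapes differ")
  trab_f <- iterative_binary_segmentation_filter(
    raw$trabecular$voxels, params$open_max_radius_unet,
    params$close_max_radius_unet, params$fg_connectivity,
    params$bg_connectivity)
  shell <- binary_dilate(trab_f, params$shell_thickness) & !trab_f
  bone_u <- iterative_binary_segmentation_filter(
    raw$cortical$voxels | raw$trabecular$voxels,
    params$open_max_radius_unet, params$close_max_radius_unet,
    params$fg_connectivity, params$bg_connectivity)
  bone_m <- morphological_bone_mask_filter(nv, params)$voxels
  bone_f <- bone_u | bone_m | trab_f | shell
  if (!any(bone_f)) stop("empty bone mask: possible failed segmentation")
  segmentation_pair(
    cortical = compartment_mask(bone_f & !trab_f, "cortical",
                                nv$voxel_size_mm),
    trabecular = compartment_mask(trab_f, "trabecular", nv$voxel_size_mm))
}
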