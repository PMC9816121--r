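#' Predict embedding fields for a whole volume
#'
#' Sweeps the 2D model over the axial axis, predicting each slice
#' independently from its five-slice stack, and assembles two rank-3
#' embedding fields. Evaluation mode throughout, so repeated calls are
#' identical.
#'
#' @param model an [build_unet()] model.
#' @param nv a [normalized_volume()] whose in-plane extents are divisible by
#'   `2^depth`.
#' @param batch_slices slices evaluated per forward pass (per-slice outputs
#'   are independent of the batching).
#' @return A list of class `volume_embeddings` with rank-3 arrays `endo` and
#'   `peri` matching the volume grid.
#' @export
predict_volume <- function(model, nv, batch_slices = 4L) {
  stopifnot(inherits(model, "embedding_unet"),
            inherits(nv, "normalized_volume"))
  d <- dim(nv$voxels)
  n <- d[1]; H <- d[2]; W <- d[3]
  endo <- array(0, d)
  peri <- array(0, d)
  HW <- H * W
  for (st in seq(1L, n, by = batch_slices)) {
    idx <- st:min(st + batch_slices - 1L, n)
    B <- length(idx)
    X <- matrix(0, B * HW, 5L)
    for (b in seq_len(B)) {
      stk <- make_slice_stack(nv, idx[b])
      X[(b - 1L) * HW + seq_len(HW), ] <- t(matrix(stk$slices, nrow = 5L))
    }
    out <- unet_forward_mat(model, X, B, H, W, training = FALSE,
                            keep_cache = FALSE)$out
    for (b in seq_len(B)) {
      rows <- (b - 1L) * HW + seq_len(HW)
      endo[idx[b], , ] <- matrix(out[rows, 1], H, W)
      peri[idx[b], , ] <- matrix(out[rows, 2], H, W)
    }
  }
  structure(list(endo = endo, peri = peri,
                 voxel_size_mm = nv$voxel_size_mm),
            class = "volume_embeddings")
}

#' Convert embedding fields to binary masks
#'
#' Trabecular is the region strictly inside the endosteal surface
#' (`phi_endo < 0`); cortical lies strictly between the surfaces
#' (`phi_endo > 0` and `phi_peri < 0`). Voxels exactly on a zero level set
#' belong to neither mask, so the two masks are disjoint by construction.
#'
#' @param emb a `volume_embeddings` object from [predict_volume()] (or a
#'   list with rank-3 arrays `endo`, `peri`).
#' @param voxel_size_mm voxel size recorded on the masks.
#' @return A [segmentation_pair()].
#' @export
embeddings_to_masks <- function(emb, voxel_size_mm = NULL) {
  stopifnot(all(is.finite(emb$endo)), all(is.finite(emb$peri)),
            identical(dim(emb$endo), dim(emb$peri)))
  vs <- voxel_size_mm %||% (emb$voxel_size_mm %||% 0.0607)
  segmentation_pair(
    cortical = compartment_mask(emb$endo > 0 & emb$peri < 0, "cortical", vs),
    trabecular = compartment_mask(emb$endo < 0, "trabecular", vs))
}

#' End-to-end automated segmentation of a density volume
#'
#' The full pipeline: in-plane padding, density standardization, axial sweep
#' of the U-Net, sign-based mask conversion, morphological post-processing,
#' and cropping back to the original extents. Deterministic: rerunning on
#' the same input yields identical masks.
#'
#' @param vol a calibrated [density_volume()].
#' @param model an [build_unet()] model.
#' @param params a [postprocess_params()] set.
#' @param postprocess apply the morphological post-processing (disable to
#'   inspect the raw U-Net masks).
#' @param verbose print per-stage timings.
#' @return A [segmentation_pair()] on the original grid. Per-stage timings
#'   (seconds) are attached as attribute `"timings"`.
#' @export
segment_volume <- function(vol, model, params = postprocess_params(),
                           postprocess = TRUE, verbose = FALSE) {
  stopifnot(inherits(vol, "density_volume"))
  orig_dim <- dim(vol$voxels)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  nv <- pad_in_plane(standardize(vol))
  timings["preprocess"] <- tic() - t0

  t0 <- tic()
  emb <- predict_volume(model, nv)
  timings["predict"] <- tic() - t0

  t0 <- tic()
  raw <- embeddings_to_masks(emb, vol$voxel_size_mm)
  timings["masks"] <- tic() - t0

  if (postprocess) {
    t0 <- tic()
    seg <- postprocess_segmentation(nv, raw, params)
    timings["postprocess"] <- tic() - t0
  } else seg <- raw

  cort <- crop_array(seg$cortical$voxels, orig_dim)
  trab <- crop_array(seg$trabecular$voxels, orig_dim)
  out <- segmentation_pair(
    compartment_mask(cort, "cortical", vol$voxel_size_mm),
    compartment_mask(trab, "trabecular", vol$voxel_size_mm))
  attr(out, "timings") <- timings
  if (verbose)
    message(paste(sprintf("%s: %.2fs", names(timings), timings),
                  collapse = ", "))
  out
}
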