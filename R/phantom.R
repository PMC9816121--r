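#' Synthetic HR-pQCT phantom specification
#'
#' Describes a desk-scale synthetic distal-bone image: a high-density
#' cortical annulus around a lower-density textured trabecular interior on
#' a quiet background, with optional cortical pores, a slow axial drift of
#' the bone axis, an optional smaller secondary bone (emulating the
#' ulna/fibula) and additive Gaussian noise. Densities are chosen so the
#' -0.25 normalized threshold (275 mg HA/cm^3) cleanly separates cortical
#' bone (900) from the trabecular compartment mean (200).
#'
#' @param n_slices axial slices (16 by default; full scans use 168).
#' @param in_plane in-plane extent in voxels (square grid).
#' @param outer_radius_mm periosteal radius.
#' @param cortical_thickness_mm thickness of the cortical annulus.
#' @param cortical_density cortical density in mg HA/cm^3.
#' @param trabecular_mean_density mean density of the trabecular interior.
#' @param trabecular_strut_contrast half-distance between strut and marrow
#'   densities; the interior is a thresholded band-limited texture at
#'   `mean -/+ contrast`.
#' @param trabecular_texture_scale_mm correlation length of the trabecular
#'   texture.
#' @param pore_count number of low-density spherical pores in the cortex.
#' @param pore_radius_mm pore radius.
#' @param noise_sd additive Gaussian noise SD in mg HA/cm^3.
#' @param background_density background (soft tissue / air) density.
#' @param secondary_bone include a smaller secondary bone near the image
#'   edge (excluded from the ground truth).
#' @param drift_per_slice_mm in-plane drift of the bone center per slice.
#' @param voxel_size_mm isotropic voxel size.
#' @param seed seed fixing all anatomy and noise randomness.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 16L, in_plane = 160L,
                         outer_radius_mm = 3.0, cortical_thickness_mm = 0.8,
                         cortical_density = 900,
                         trabecular_mean_density = 200,
                         trabecular_strut_contrast = 150,
                         trabecular_texture_scale_mm = 0.3,
                         pore_count = 4L, pore_radius_mm = 0.12,
                         noise_sd = 30, background_density = 0,
                         secondary_bone = FALSE,
                         drift_per_slice_mm = 0.01,
                         voxel_size_mm = 0.0607, seed = 1L) {
  stopifnot(n_slices >= 3L, in_plane >= 16L,
            cortical_thickness_mm < outer_radius_mm,
            outer_radius_mm > 0, noise_sd >= 0, voxel_size_mm > 0)
  structure(as.list(environment()), class = "phantom_spec")
}

#' Generate a synthetic phantom with analytic ground truth
#'
#' The periosteal and endosteal surfaces are concentric circles per slice
#' (with a slow axial drift of the center), so the ground-truth masks and
#' the signed-distance embeddings (negative inside, voxel units) are exact
#' analytic quantities rather than derived from the rasterized image.
#'
#' @param spec a [phantom_spec()].
#' @param center_offset_mm additional in-plane displacement of the bone
#'   (used for repeat-scan repositioning).
#' @param rotation_deg rotation of the anatomy (drift direction and pore
#'   placement) about the bone axis.
#' @param noise_seed seed of the additive noise; anatomy randomness always
#'   derives from `spec$seed` so repeat scans share their anatomy.
#' @return A list of class `phantom_sample`: `volume` (a
#'   [density_volume()]), `truth` (a [segmentation_pair()]), `endo_sdf` and
#'   `peri_sdf` (rank-3 arrays, voxel units), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec(),
                             center_offset_mm = c(0, 0),
                             rotation_deg = 0,
                             noise_seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  vs <- spec$voxel_size_mm
  n <- spec$n_slices
  s <- spec$in_plane
  extent_mm <- s * vs
  r_out <- spec$outer_radius_mm
  r_in <- r_out - spec$cortical_thickness_mm
  drift_span <- spec$drift_per_slice_mm * n / 2
  if (r_out + drift_span + max(abs(center_offset_mm)) + 2 * vs >
      extent_mm / 2)
    stop("phantom geometry exceeds the grid")

  rot <- rotation_deg * pi / 180
  anat <- with_seed(spec$seed, {
    list(center_jitter = runif(2, -0.5, 0.5) * vs,
         drift_angle = runif(1, 0, 2 * pi),
         pore_r = runif(spec$pore_count, (r_in + spec$pore_radius_mm),
                        (r_out - spec$pore_radius_mm)),
         pore_theta = runif(spec$pore_count, 0, 2 * pi),
         pore_z = sample(n, spec$pore_count, replace = TRUE),
         secondary_angle = runif(1, 0, 2 * pi),
         texture = array(rnorm(n * s * s), c(n, s, s)))
  })

  # grid coordinates of voxel centers (mm), origin at the image center
  coord <- (seq_len(s) - (s + 1) / 2) * vs
  gx <- matrix(coord, s, s)          # coronal axis
  gy <- matrix(coord, s, s, byrow = TRUE)  # sagittal axis

  drift_dir <- anat$drift_angle + rot
  cz <- (seq_len(n) - (n + 1) / 2)
  centers <- cbind(
    anat$center_jitter[1] + center_offset_mm[1] +
      cz * spec$drift_per_slice_mm * cos(drift_dir),
    anat$center_jitter[2] + center_offset_mm[2] +
      cz * spec$drift_per_slice_mm * sin(drift_dir))

  tex <- smooth_texture(anat$texture,
                        spec$trabecular_texture_scale_mm / vs)

  endo_sdf <- array(0, c(n, s, s))
  peri_sdf <- array(0, c(n, s, s))
  dens <- array(spec$background_density, c(n, s, s))
  for (z in seq_len(n)) {
    d <- sqrt((gx - centers[z, 1])^2 + (gy - centers[z, 2])^2)
    endo_sdf[z, , ] <- (d - r_in) / vs
    peri_sdf[z, , ] <- (d - r_out) / vs
    slice <- matrix(spec$background_density, s, s)
    cort <- d > r_in & d < r_out
    trab <- d < r_in
    slice[cort] <- spec$cortical_density
    struts <- tex[z, , ] > 0
    slice[trab & struts] <- spec$trabecular_mean_density +
      spec$trabecular_strut_contrast
    slice[trab & !struts] <- spec$trabecular_mean_density -
      spec$trabecular_strut_contrast
    dens[z, , ] <- slice
  }

  # low-density pores inside the cortical annulus (masks keep them cortical)
  if (spec$pore_count > 0) {
    pr_vox <- spec$pore_radius_mm / vs
    for (k in seq_len(spec$pore_count)) {
      th <- anat$pore_theta[k] + rot
      px <- centers[anat$pore_z[k], 1] + anat$pore_r[k] * cos(th)
      py <- centers[anat$pore_z[k], 2] + anat$pore_r[k] * sin(th)
      for (z in seq_len(n)) {
        dz <- (z - anat$pore_z[k])
        if (abs(dz) > pr_vox) next
        rr2 <- pr_vox^2 - dz^2
        inside <- ((gx - px)^2 + (gy - py)^2) / vs^2 <= rr2
        sl <- dens[z, , ]
        sl[inside] <- spec$trabecular_mean_density
        dens[z, , ] <- sl
      }
    }
  }

  if (spec$secondary_bone) {
    r2 <- 0.4 * r_out
    dist_c <- extent_mm / 2 - r2 - 3 * vs
    if (dist_c < r_out + r2 + 5 * vs)
      stop("phantom geometry exceeds the grid: the secondary bone would ",
           "touch the primary (reduce outer_radius_mm or enlarge in_plane)")
    sx <- dist_c * cos(anat$secondary_angle + rot)
    sy <- dist_c * sin(anat$secondary_angle + rot)
    for (z in seq_len(n)) {
      d2 <- sqrt((gx - sx)^2 + (gy - sy)^2)
      sl <- dens[z, , ]
      sl[d2 < r2] <- ifelse(d2[d2 < r2] > r2 - spec$cortical_thickness_mm / 2,
                            spec$cortical_density,
                            spec$trabecular_mean_density)
      dens[z, , ] <- sl
    }
  }

  if (spec$noise_sd > 0)
    dens <- dens + with_seed(noise_seed,
                             array(rnorm(length(dens), sd = spec$noise_sd),
                                   dim(dens)))
  dens <- pmin(pmax(dens, -400), 1400)

  truth <- segmentation_pair(
    cortical = compartment_mask(endo_sdf > 0 & peri_sdf < 0, "cortical", vs),
    trabecular = compartment_mask(endo_sdf < 0, "trabecular", vs))
  structure(list(volume = density_volume(array(dens, c(n, s, s)), vs,
                                         name = "phantom"),
                 truth = truth,
                 endo_sdf = endo_sdf, peri_sdf = peri_sdf,
                 spec = spec),
            class = "phantom_sample")
}

# separable in-plane Gaussian smoothing of a (slices x H x W) noise field,
# renormalized to unit variance
smooth_texture <- function(noise, sigma_vox) {
  if (sigma_vox <= 0) return(noise)
  half <- max(1L, as.integer(ceiling(2 * sigma_vox)))
  k <- exp(-0.5 * ((-half):half / sigma_vox)^2)
  k <- k / sum(k)
  d <- dim(noise)
  out <- noise
  smooth_axis <- function(a, axis) {
    res <- array(0, dim(a))
    n_ax <- dim(a)[axis]
    for (t in seq_along(k)) {
      offs <- t - half - 1L
      src <- pmin(pmax(seq_len(n_ax) + offs, 1L), n_ax)  # replicate edges
      if (axis == 2L) res <- res + k[t] * a[, src, , drop = FALSE]
      else res <- res + k[t] * a[, , src, drop = FALSE]
    }
    res
  }
  out <- smooth_axis(out, 2L)
  out <- smooth_axis(out, 3L)
  sdv <- sd(out)
  if (sdv > 0) out <- out / sdv
  out
}

#' Generate a repeat-scan phantom pair with repositioning
#'
#' Emulates a duplicate same-day scan: the same anatomy rigidly displaced
#' in-plane (and optionally rotated about the bone axis) with fresh
#' acquisition noise. The true transform is returned for common-volume
#' evaluation.
#'
#' @param spec a [phantom_spec()].
#' @param repositioning_mm in-plane displacement magnitude of the repeat
#'   scan; the direction is drawn from the spec seed.
#' @param rotation_deg axial rotation of the repeat scan.
#' @return List of class `phantom_pair`: samples `a` and `b` and the true
#'   `transform` (`translation_mm`, `rotation_deg`).
#' @export
generate_repeat_pair <- function(spec = phantom_spec(),
                                 repositioning_mm = 0.5, rotation_deg = 5) {
  a <- generate_phantom(spec, noise_seed = spec$seed + 1L)
  dir <- with_seed(spec$seed + 7L, runif(1, 0, 2 * pi))
  offset <- repositioning_mm * c(cos(dir), sin(dir))
  b <- generate_phantom(spec, center_offset_mm = offset,
                        rotation_deg = rotation_deg,
                        noise_seed = spec$seed + 2L)
  structure(list(a = a, b = b,
                 transform = list(translation_mm = offset,
                                  rotation_deg = rotation_deg)),
            class = "phantom_pair")
}

#' Stratified train/validation/test split by bone density
#'
#' Participants are stratified by study, binned into quartiles of their
#' minimum total volumetric bone mineral density (Tt.BMD) across images,
#' and randomly assigned within each bin at the requested fractions. All
#' images of a participant stay in one subset. Integer allocation uses the
#' largest-remainder rule on cumulative quotas, so overall subset sizes
#' match the fractions to within one participant.
#'
#' @param participants data frame with columns `participant`, `study` and
#'   `tt_bmd` (one row per image; participants may have several rows).
#' @param fractions named fractions summing to 1 (default 70/15/15
#'   train/validation/test).
#' @param seed seed for the within-bin randomization.
#' @return Data frame with one row per participant: `participant`, `study`,
#'   `bin` and `subset`.
#' @export
stratified_split <- function(participants,
                             fractions = c(train = 0.7, validation = 0.15,
                                           test = 0.15),
                             seed = 1L) {
  stopifnot(is.data.frame(participants),
            all(c("participant", "study", "tt_bmd") %in%
                  names(participants)))
  if (nrow(participants) == 0L) stop("empty participant table")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  agg <- aggregate(tt_bmd ~ participant + study, data = participants,
                   FUN = min)
  agg <- agg[order(agg$study, agg$participant), ]
  subsets <- names(fractions)
  assigned <- numeric(length(fractions))
  cum_n <- 0
  out <- NULL
  with_seed(seed, {
    for (st in unique(agg$study)) {
      grp <- agg[agg$study == st, ]
      qs <- quantile(grp$tt_bmd, probs = c(0.25, 0.5, 0.75), names = FALSE)
      bin <- findInterval(grp$tt_bmd, qs, left.open = TRUE) + 1L
      for (bq in sort(unique(bin))) {
        ids <- grp$participant[bin == bq]
        ids <- ids[sample(length(ids))]
        n_bin <- length(ids)
        cum_n <- cum_n + n_bin
        deficit <- pmax(fractions * cum_n - assigned, 0)
        counts <- allocate_largest_remainder(deficit, n_bin)
        assigned <- assigned + counts
        subset <- rep(subsets, times = counts)
        out <- rbind(out, data.frame(participant = ids, study = st,
                                     bin = bq, subset = subset,
                                     stringsAsFactors = FALSE))
      }
    }
  })
  rownames(out) <- NULL
  out
}

allocate_largest_remainder <- function(deficit, n_bin) {
  fl <- floor(deficit)
  while (sum(fl) > n_bin) {
    i <- which.max(fl)
    fl[i] <- fl[i] - 1
  }
  rem <- deficit - floor(deficit)
  extra <- n_bin - sum(fl)
  if (extra > 0) {
    ord <- order(-rem, seq_along(rem))
    j <- 0L
    while (extra > 0) {
      i <- ord[(j %% length(fl)) + 1L]
      fl[i] <- fl[i] + 1
      extra <- extra - 1L
      j <- j + 1L
    }
  }
  as.integer(fl)
}
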