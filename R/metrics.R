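#' Overlap metrics between two binary masks
#'
#' Dice and Jaccard similarity coefficients. Both are defined as 1 when the
#' two masks are empty (perfect agreement on "nothing").
#'
#' @param a,b masks on the same grid ([compartment_mask()] or logical
#'   arrays).
#' @return List of class `overlap_metrics` with `dsc` and `jsc`
#'   (`dsc = 2 * jsc / (1 + jsc)`).
#' @export
#' @examples
#' m <- array(TRUE, c(2, 5, 5))
#' overlap_metrics(m, m)$dsc   # 1
overlap_metrics <- function(a, b) {
  a <- as_mask_array(a)
  b <- as_mask_array(b)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  inter <- sum(a & b)
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0)
    return(structure(list(dsc = 1, jsc = 1), class = "overlap_metrics"))
  structure(list(dsc = 2 * inter / (na + nb),
                 jsc = inter / (na + nb - inter)),
            class = "overlap_metrics")
}

# boundary voxels: mask voxels with at least one 6-neighbor outside the mask
# (grid borders count as outside)
boundary6 <- function(m) {
  d <- dim(m)
  inner <- m
  shift_and <- function(inner, axis, dir) {
    idx <- vector("list", 3L)
    for (k in 1:3) idx[[k]] <- seq_len(d[k])
    src <- idx
    n <- d[axis]
    if (dir > 0) { idx[[axis]] <- seq_len(n - 1L); src[[axis]] <- 2:n }
    else { idx[[axis]] <- 2:n; src[[axis]] <- seq_len(n - 1L) }
    nb <- array(FALSE, d)
    nb[idx[[1]], idx[[2]], idx[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    inner & nb
  }
  for (axis in 1:3)
    for (dir in c(-1L, 1L))
      if (d[axis] > 1L) inner <- shift_and(inner, axis, dir)
      else inner <- inner & FALSE
  m & !inner
}

#' Symmetric surface distances between two masks
#'
#' Boundary voxels (6-connectivity erosion difference) of each mask are
#' compared with exact Euclidean distance transforms. ASSD is the mean of
#' the surface distances pooled over both directions, the Hausdorff
#' distance is their maximum; both reported in mm.
#'
#' @param a,b nonempty masks on the same grid.
#' @param voxel_size_mm isotropic voxel size; defaults to the masks' own.
#' @return List of class `surface_metrics` with `assd_mm` and
#'   `hausdorff_mm`.
#' @export
surface_distances <- function(a, b, voxel_size_mm = NULL) {
  vs <- voxel_size_mm %||%
    (if (inherits(a, "compartment_mask")) a$voxel_size_mm else 0.0607)
  a <- as_mask_array(a)
  b <- as_mask_array(b)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  if (!any(a) || !any(b)) stop("surface distances need nonempty masks")
  ba <- boundary6(a)
  bb <- boundary6(b)
  dist_to_bb <- sqrt(array(cpp_edt3_sq(!bb, dim(bb)), dim(bb)))
  dist_to_ba <- sqrt(array(cpp_edt3_sq(!ba, dim(ba)), dim(ba)))
  dd <- c(dist_to_bb[ba], dist_to_ba[bb])
  structure(list(assd_mm = mean(dd) * vs, hausdorff_mm = max(dd) * vs),
            class = "surface_metrics")
}

#' Bland-Altman agreement of paired measurements
#'
#' @param pred,ref equal-length numeric vectors (length >= 2).
#' @return List with `bias` (mean error pred - ref), `loa_low`/`loa_high`
#'   (bias -/+ 1.96 SD of the errors, SD with n-1), and `sd_error`.
#' @export
bland_altman <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("length mismatch")
  if (length(pred) < 2L) stop("need at least 2 pairs")
  err <- pred - ref
  bias <- mean(err)
  s <- sd(err)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_error = s)
}

#' Linear agreement of predicted vs reference measurements
#'
#' Ordinary least squares of `pred ~ ref`; 95% confidence intervals are the
#' estimates +/- 1.96 standard errors. Bland-Altman bias and limits of
#' agreement are included for convenience.
#'
#' @param pred,ref numeric vectors (length >= 3; `ref` must vary).
#' @return List of class `agreement_result`: `slope`, `slope_ci`,
#'   `intercept`, `intercept_ci`, `r_squared`, `bias`, `loa_low`,
#'   `loa_high`.
#' @export
linear_agreement <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("length mismatch")
  if (length(pred) < 3L) stop("need at least 3 pairs")
  if (sd(ref) == 0) stop("reference values are degenerate (no variance)")
  fit <- lm(pred ~ ref)
  sm <- summary(fit)
  est <- sm$coefficients[, "Estimate"]
  se <- sm$coefficients[, "Std. Error"]
  ba <- bland_altman(pred, ref)
  structure(list(slope = unname(est[2]),
                 slope_ci = unname(est[2] + c(-1.96, 1.96) * se[2]),
                 intercept = unname(est[1]),
                 intercept_ci = unname(est[1] + c(-1.96, 1.96) * se[1]),
                 r_squared = sm$r.squared,
                 bias = ba$bias, loa_low = ba$loa_low,
                 loa_high = ba$loa_high),
            class = "agreement_result")
}

#' Short-term precision from same-day repeat pairs
#'
#' For each pair the individual standard deviation is `|x1 - x2| / sqrt(2)`
#' and the individual %CV uses the pair mean as denominator. RMS SD and
#' RMS %CV are root-mean-squares over pairs; the least significant change
#' is `lsc_multiplier * RMS SD` (2.77 for 95% confidence with two
#' measurements per timepoint).
#'
#' @param pairs two-column matrix or data frame of repeat measurements
#'   (one row per participant).
#' @param lsc_multiplier multiplier relating precision error to the least
#'   significant change.
#' @return List of class `precision_result`: `rms_sd`, `rms_pct_cv`, `lsc`,
#'   plus per-pair `sd_i` and `pct_cv_i`.
#' @export
#' @examples
#' precision_stats(cbind(100, 102))$lsc   # 2.77 * sqrt(2)
precision_stats <- function(pairs, lsc_multiplier = 2.77) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L || nrow(pairs) < 1L)
    stop("pairs must be an n x 2 table with n >= 1")
  sd_i <- abs(pairs[, 1] - pairs[, 2]) / sqrt(2)
  means <- rowMeans(pairs)
  if (any(means <= 0)) stop("pair means must be positive for %CV")
  cv_i <- 100 * sd_i / means
  rms_sd <- sqrt(mean(sd_i^2))
  structure(list(rms_sd = rms_sd,
                 rms_pct_cv = sqrt(mean(cv_i^2)),
                 lsc = lsc_multiplier * rms_sd,
                 sd_i = sd_i, pct_cv_i = cv_i),
            class = "precision_result")
}

#' Compare the precision of two measurement protocols
#'
#' Matches the published analysis: individual per-participant standard
#' deviations are computed for both protocols, their normality is checked
#' with D'Agostino and Pearson's K^2 test, and the paired difference is
#' tested with a two-sided Wilcoxon signed-rank test using Pratt's
#' treatment of zero differences.
#'
#' @param pred_pairs,ref_pairs n x 2 tables of repeat measurements from the
#'   two protocols (rows aligned by participant).
#' @param alpha significance threshold reported alongside the p-value.
#' @return List of class `precision_comparison` with the per-protocol
#'   [precision_stats()], normality p-values, the signed-rank statistic and
#'   p-value, and `significant`.
#' @export
compare_precision <- function(pred_pairs, ref_pairs, alpha = 0.05) {
  pred_pairs <- as.matrix(pred_pairs)
  ref_pairs <- as.matrix(ref_pairs)
  if (nrow(pred_pairs) != nrow(ref_pairs))
    stop("protocols must have the same participants")
  if (nrow(pred_pairs) < 5L)
    warning("fewer than 5 pairs: large-sample signed-rank test is unreliable")
  pp <- precision_stats(pred_pairs)
  rp <- precision_stats(ref_pairs)
  norm_pred <- tryCatch(dagostino_pearson(pp$sd_i)$p_value,
                        error = function(e) NA_real_)
  norm_ref <- tryCatch(dagostino_pearson(rp$sd_i)$p_value,
                       error = function(e) NA_real_)
  wt <- wilcoxon_signed_rank(pp$sd_i, rp$sd_i, zero_method = "pratt")
  structure(list(pred = pp, ref = rp,
                 normality_p = c(pred = norm_pred, ref = norm_ref),
                 statistic = wt$statistic, p_value = wt$p_value,
                 alpha = alpha,
                 significant = is.finite(wt$p_value) && wt$p_value < alpha),
            class = "precision_comparison")
}

#' Per-compartment density and area summaries
#'
#' Simple descriptive summaries (not the manufacturer morphometric
#' analysis): voxel count, mean density, and mean cross-sectional area in
#' mm^2 (foreground voxels per axial slice times the in-plane voxel area,
#' averaged over slices).
#'
#' @param vol a [density_volume()].
#' @param seg a [segmentation_pair()] on the same grid.
#' @return Data frame with one row per compartment.
#' @export
compartment_summaries <- function(vol, seg) {
  stopifnot(inherits(vol, "density_volume"),
            inherits(seg, "segmentation_pair"))
  if (!identical(dim(vol$voxels), dim(seg$cortical$voxels)))
    stop("volume and segmentation shapes differ")
  vs <- vol$voxel_size_mm
  one <- function(mask, label) {
    m <- mask$voxels
    count <- sum(m)
    per_slice <- apply(m, 1L, sum)
    data.frame(compartment = label,
               voxel_count = count,
               mean_density = if (count > 0) mean(vol$voxels[m]) else NA_real_,
               mean_area_mm2 = mean(per_slice) * vs^2,
               stringsAsFactors = FALSE)
  }
  rbind(one(seg$cortical, "cortical"), one(seg$trabecular, "trabecular"))
}

#' Quartile sub-groups of a parameter table
#'
#' Helper for sub-group analyses such as "low cortical thickness" (bottom
#' quartile of Ct.Th) or "high cortical porosity" (top quartile of Ct.Po).
#'
#' @param values numeric vector of a morphometric parameter.
#' @param which `"bottom"` or `"top"` quartile.
#' @return Logical vector selecting the sub-group.
#' @export
quartile_subgroup <- function(values, which = c("bottom", "top")) {
  which <- match.arg(which)
  q <- quantile(values, probs = if (which == "bottom") 0.25 else 0.75,
                na.rm = TRUE, names = FALSE)
  if (which == "bottom") values <= q else values >= q
}
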