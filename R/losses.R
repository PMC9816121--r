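#' Loss configuration for embedding-field training
#'
#' Bundles the tunable constants of the embedding losses. The curvature
#' threshold is stated in physical units (1/um) and converted to voxel units
#' with the voxel size: 0.005 / um at 60.7 um voxels is 0.3035 / voxel,
#' i.e. surfaces with radius of curvature below ~200 um are penalized.
#'
#' @param epsilon sharpness of the smoothed Heaviside, in voxel units of the
#'   embedding field. The transition width is ~`epsilon`, so 1 voxel localizes
#'   class probabilities to about one voxel around each surface.
#' @param kappa_thresh_um curvature threshold in 1/um below which the
#'   curvature penalty is zero.
#' @param lambda_kappa,lambda_grad weights of the curvature and
#'   signed-distance (gradient-magnitude) regularizers in the total loss.
#' @param voxel_size_mm isotropic voxel size, used to convert
#'   `kappa_thresh_um` to voxel units.
#' @param band_connectivity 4 (default) or 8: neighborhood used to detect
#'   zero crossings of the embedding fields.
#' @param ce_clamp,grad_clamp numerical floors applied inside the logs of the
#'   cross-entropy and gradient-magnitude losses.
#' @return A list of class `loss_weights`; `kappa_thresh_voxel` holds the
#'   converted threshold.
#' @export
#' @examples
#' loss_weights()$kappa_thresh_voxel   # 0.3035
loss_weights <- function(epsilon = 1, kappa_thresh_um = 0.005,
                         lambda_kappa = 1e-4, lambda_grad = 1e-4,
                         voxel_size_mm = 0.0607, band_connectivity = 4L,
                         ce_clamp = 1e-12, grad_clamp = 1e-8) {
  stopifnot(epsilon > 0, kappa_thresh_um > 0, lambda_kappa >= 0,
            lambda_grad >= 0, band_connectivity %in% c(4L, 8L))
  structure(list(epsilon = epsilon,
                 kappa_thresh_um = kappa_thresh_um,
                 kappa_thresh_voxel = kappa_thresh_um * voxel_size_mm * 1000,
                 lambda_kappa = lambda_kappa,
                 lambda_grad = lambda_grad,
                 voxel_size_mm = voxel_size_mm,
                 band_connectivity = as.integer(band_connectivity),
                 ce_clamp = ce_clamp, grad_clamp = grad_clamp),
            class = "loss_weights")
}

#' Pair of predicted embedding fields
#'
#' The network output for one slice: scalar level-set embeddings whose zero
#' level sets are the endosteal and periosteal surfaces. Negative values lie
#' inside the embedded surface, and for a well-trained model the magnitude
#' approximates the distance to the surface in voxels.
#'
#' @param endo,peri numeric matrices of equal shape.
#' @return An object of class `embedding_fields`.
#' @export
embedding_fields <- function(endo, peri) {
  stopifnot(is.matrix(endo), is.matrix(peri),
            identical(dim(endo), dim(peri)),
            all(is.finite(endo)), all(is.finite(peri)))
  structure(list(endo = endo, peri = peri), class = "embedding_fields")
}

#' Smoothed Heaviside function
#'
#' `H(x) = 1/2 + atan(x / epsilon) / pi`, the differentiable step used to
#' convert signed embedding values into class probabilities.
#'
#' @param x numeric vector/matrix/array.
#' @param epsilon positive sharpness parameter (voxel units).
#' @return Values in (0, 1), same shape as `x`.
#' @export
#' @examples
#' heaviside(0)    # 0.5
#' heaviside(1, 1) # 0.75
heaviside <- function(x, epsilon = 1) {
  if (epsilon <= 0) stop("epsilon must be positive")
  0.5 + atan(x / epsilon) / pi
}

# derivative of the smoothed Heaviside (even in x)
d_heaviside <- function(x, epsilon = 1) {
  epsilon / (pi * (epsilon^2 + x^2))
}

#' Convert embedding fields to class probabilities
#'
#' `p_trab = H(-phi_endo)`, `p_cort = H(phi_endo) * H(-phi_peri)`,
#' `p_back = H(phi_peri)`. The three probabilities do not sum to one until
#' [normalize_probs()] is applied.
#'
#' @param fields an [embedding_fields()] pair.
#' @param w a [loss_weights()] object (only `epsilon` is used).
#' @return A list of class `prob_segmentation` with matrices `p_trab`,
#'   `p_cort`, `p_back` and a `normalized` flag.
#' @export
probabilistic_segmentation <- function(fields, w = loss_weights()) {
  stopifnot(inherits(fields, "embedding_fields"))
  e <- w$epsilon
  structure(list(p_trab = heaviside(-fields$endo, e),
                 p_cort = heaviside(fields$endo, e) *
                          heaviside(-fields$peri, e),
                 p_back = heaviside(fields$peri, e),
                 normalized = FALSE),
            class = "prob_segmentation")
}

#' Normalize class probabilities to sum to one per voxel
#'
#' @param p a `prob_segmentation` (see [probabilistic_segmentation()]).
#' @return The same structure with `normalized = TRUE`.
#' @export
normalize_probs <- function(p) {
  stopifnot(inherits(p, "prob_segmentation"))
  s <- p$p_trab + p$p_cort + p$p_back
  if (any(s <= 0)) stop("zero-sum voxel encountered during normalization")
  p$p_trab <- p$p_trab / s
  p$p_cort <- p$p_cort / s
  p$p_back <- p$p_back / s
  p$normalized <- TRUE
  p
}

#' Extract one axial slice of a segmentation as one-hot reference maps
#'
#' @param pair a [segmentation_pair()].
#' @param z 1-based axial index.
#' @return A list of class `seg_slice` with logical matrices `trabecular`,
#'   `cortical` (background is the complement of their union).
#' @export
segmentation_slice <- function(pair, z) {
  stopifnot(inherits(pair, "segmentation_pair"))
  list_ <- list(trabecular = pair$trabecular$voxels[z, , ],
                cortical = pair$cortical$voxels[z, , ])
  structure(list_, class = "seg_slice")
}

as_seg_slice <- function(ref) {
  if (inherits(ref, "seg_slice")) return(ref)
  if (is.list(ref) && all(c("trabecular", "cortical") %in% names(ref)))
    return(structure(ref[c("trabecular", "cortical")], class = "seg_slice"))
  stop("reference must be a seg_slice or a list with trabecular/cortical")
}

#' Mean cross-entropy against a one-hot reference slice
#'
#' Mean over voxels of the negative log-likelihood of the reference class
#' under the normalized predicted probabilities (natural log; probabilities
#' floored at `w$ce_clamp` before the log).
#'
#' @param p a normalized `prob_segmentation`.
#' @param ref a [segmentation_slice()] (or list with `trabecular`/`cortical`
#'   logical matrices).
#' @param w a [loss_weights()] object.
#' @return Nonnegative scalar.
#' @export
cross_entropy <- function(p, ref, w = loss_weights()) {
  stopifnot(inherits(p, "prob_segmentation"))
  if (!isTRUE(p$normalized))
    stop("cross_entropy expects normalized probabilities (see normalize_probs)")
  ref <- as_seg_slice(ref)
  s_t <- ref$trabecular != 0
  s_c <- ref$cortical != 0
  if (!identical(dim(p$p_trab), dim(s_t)))
    stop("probability and reference shapes differ")
  if (any(s_t & s_c)) stop("reference classes are not one-hot")
  s_b <- !(s_t | s_c)
  cl <- w$ce_clamp
  -mean(s_t * log(pmax(p$p_trab, cl)) +
        s_c * log(pmax(p$p_cort, cl)) +
        s_b * log(pmax(p$p_back, cl)))
}

# -- discrete differential operators ------------------------------------------

#' Discrete spatial gradient of a 2D field
#'
#' Central differences in the slice plane (voxel-unit spacing), one-sided at
#' the borders. [gradient_magnitude()] returns the Euclidean norm of the two
#' components.
#'
#' @param phi numeric matrix, at least 3 x 3.
#' @return `spatial_gradient`: list with components `d1` (along rows) and
#'   `d2` (along columns); `gradient_magnitude`: a matrix.
#' @export
#' @examples
#' phi <- outer(1:8, 1:8, function(i, j) 2 * i + j)
#' unique(round(gradient_magnitude(phi)[2:7, 2:7], 12))   # sqrt(5)
spatial_gradient <- function(phi) {
  if (!is.matrix(phi) || nrow(phi) < 3L || ncol(phi) < 3L)
    stop("field must be at least 3 x 3")
  list(d1 = diff_central(phi, 1L), d2 = diff_central(phi, 2L))
}

#' @rdname spatial_gradient
#' @export
gradient_magnitude <- function(phi) {
  g <- spatial_gradient(phi)
  sqrt(g$d1^2 + g$d2^2)
}

diff_central <- function(m, axis) {
  if (axis == 2L) return(t(diff_central(t(m), 1L)))
  n <- nrow(m)
  d <- matrix(0, n, ncol(m))
  d[1L, ] <- m[2L, ] - m[1L, ]
  d[n, ] <- m[n, ] - m[n - 1L, ]
  if (n > 2L) d[2:(n - 1L), ] <- (m[3:n, , drop = FALSE] -
                                  m[1:(n - 2L), , drop = FALSE]) / 2
  d
}

# adjoint (transpose) of diff_central, needed for loss gradients
diff_central_adj <- function(u, axis) {
  if (axis == 2L) return(t(diff_central_adj(t(u), 1L)))
  n <- nrow(u)
  v <- matrix(0, n, ncol(u))
  if (n > 2L) {
    src <- u[2:(n - 1L), , drop = FALSE] / 2
    v[3:n, ] <- v[3:n, , drop = FALSE] + src
    v[1:(n - 2L), ] <- v[1:(n - 2L), , drop = FALSE] - src
  }
  v[1L, ] <- v[1L, ] - u[1L, ]
  v[2L, ] <- v[2L, ] + u[1L, ]
  v[n - 1L, ] <- v[n - 1L, ] - u[n, ]
  v[n, ] <- v[n, ] + u[n, ]
  v
}

#' Zero-crossing band of an embedding field
#'
#' A voxel is in the band if its value is exactly zero or its sign differs
#' from the sign of a neighbor (4-connectivity by default; 8 widens the band
#' by at most one voxel along diagonals).
#'
#' @param phi numeric matrix.
#' @param connectivity 4 or 8.
#' @return Logical matrix of the same shape.
#' @export
zero_crossing_mask <- function(phi, connectivity = 4L) {
  stopifnot(is.matrix(phi), connectivity %in% c(4L, 8L))
  band <- phi == 0
  n <- nrow(phi); m <- ncol(phi)
  if (n > 1L) {
    a <- phi[1:(n - 1L), , drop = FALSE] * phi[2:n, , drop = FALSE] < 0
    band[1:(n - 1L), ] <- band[1:(n - 1L), , drop = FALSE] | a
    band[2:n, ] <- band[2:n, , drop = FALSE] | a
  }
  if (m > 1L) {
    a <- phi[, 1:(m - 1L), drop = FALSE] * phi[, 2:m, drop = FALSE] < 0
    band[, 1:(m - 1L)] <- band[, 1:(m - 1L), drop = FALSE] | a
    band[, 2:m] <- band[, 2:m, drop = FALSE] | a
  }
  if (connectivity == 8L && n > 1L && m > 1L) {
    a <- phi[1:(n - 1L), 1:(m - 1L), drop = FALSE] *
         phi[2:n, 2:m, drop = FALSE] < 0
    band[1:(n - 1L), 1:(m - 1L)] <- band[1:(n - 1L), 1:(m - 1L), drop = FALSE] | a
    band[2:n, 2:m] <- band[2:n, 2:m, drop = FALSE] | a
    a <- phi[2:n, 1:(m - 1L), drop = FALSE] *
         phi[1:(n - 1L), 2:m, drop = FALSE] < 0
    band[2:n, 1:(m - 1L)] <- band[2:n, 1:(m - 1L), drop = FALSE] | a
    band[1:(n - 1L), 2:m] <- band[1:(n - 1L), 2:m, drop = FALSE] | a
  }
  band
}

#' Curvature of the level sets of an embedding field
#'
#' Divergence of the normalized gradient, `div(grad phi / (|grad phi| + eta))`,
#' discretized with central differences. In voxel^-1 units; on the zero band
#' of a circle's signed distance function this approximates 1/R.
#'
#' @param phi numeric matrix, at least 5 x 5.
#' @param eta stabilizer added to the gradient magnitude.
#' @return Matrix of curvature values.
#' @export
curvature <- function(phi, eta = 1e-8) {
  if (!is.matrix(phi) || nrow(phi) < 5L || ncol(phi) < 5L)
    stop("field must be at least 5 x 5")
  g <- spatial_gradient(phi)
  mag <- sqrt(g$d1^2 + g$d2^2)
  diff_central(g$d1 / (mag + eta), 1L) + diff_central(g$d2 / (mag + eta), 2L)
}

#' Zero-level-set curvature penalty
#'
#' Mean over all voxels of `delta(phi) * ReLU((kappa / kappa_thresh)^2 - 1)`:
#' only band voxels whose local curvature magnitude exceeds the threshold
#' contribute. Penalizes non-physical, high-curvature wiggles of the
#' predicted surfaces.
#'
#' @param phi numeric matrix.
#' @param w a [loss_weights()] object.
#' @return Nonnegative scalar.
#' @export
curvature_loss <- function(phi, w = loss_weights()) {
  band <- zero_crossing_mask(phi, w$band_connectivity)
  if (!any(band)) return(0)
  k <- curvature(phi)
  mean(band * pmax((k / w$kappa_thresh_voxel)^2 - 1, 0))
}

#' Signed-distance gradient penalty
#'
#' Mean over voxels of `(1 - delta(phi)) * log^2 |grad phi|`: away from the
#' zero band a proper signed distance function has unit gradient magnitude
#' and contributes nothing. The magnitude is floored at `w$grad_clamp`.
#'
#' @inheritParams curvature_loss
#' @return Nonnegative scalar.
#' @export
gradient_magnitude_loss <- function(phi, w = loss_weights()) {
  band <- zero_crossing_mask(phi, w$band_connectivity)
  mag <- pmax(gradient_magnitude(phi), w$grad_clamp)
  mean((!band) * log(mag)^2)
}

#' Total training loss for one slice
#'
#' `L_total = L_CE + lambda_kappa * (L_kappa_endo + L_kappa_peri) +
#' lambda_grad * (L_grad_endo + L_grad_peri)`.
#'
#' @param fields an [embedding_fields()] pair.
#' @param ref a [segmentation_slice()] for the same slice.
#' @param w a [loss_weights()] object.
#' @return A list of class `loss_breakdown` with the five terms and
#'   `L_total`.
#' @export
total_loss <- function(fields, ref, w = loss_weights()) {
  stopifnot(inherits(fields, "embedding_fields"))
  ref <- as_seg_slice(ref)
  if (!identical(dim(fields$endo), dim(ref$trabecular * 1)))
    stop("field and reference shapes differ")
  p <- normalize_probs(probabilistic_segmentation(fields, w))
  lce <- cross_entropy(p, ref, w)
  lk_e <- curvature_loss(fields$endo, w)
  lk_p <- curvature_loss(fields$peri, w)
  lg_e <- gradient_magnitude_loss(fields$endo, w)
  lg_p <- gradient_magnitude_loss(fields$peri, w)
  structure(list(L_CE = lce,
                 L_kappa_endo = lk_e, L_kappa_peri = lk_p,
                 L_grad_endo = lg_e, L_grad_peri = lg_p,
                 L_total = lce + w$lambda_kappa * (lk_e + lk_p) +
                   w$lambda_grad * (lg_e + lg_p)),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(paste0("<loss_breakdown> total %.6g\n  CE %.6g | kappa (endo %.4g,",
                     " peri %.4g) | |grad| (endo %.4g, peri %.4g)\n"),
              x$L_total, x$L_CE, x$L_kappa_endo, x$L_kappa_peri,
              x$L_grad_endo, x$L_grad_peri))
  invisible(x)
}

#' Gradient of the total loss with respect to the embedding fields
#'
#' Analytic reverse-mode gradient used by the trainer. The zero-crossing
#' indicator is treated as locally constant (it is piecewise constant in
#' `phi`), everything else is differentiated exactly; validated against
#' finite differences in the test suite.
#'
#' @inheritParams total_loss
#' @return List with matrices `endo` and `peri`.
#' @export
total_loss_gradient <- function(fields, ref, w = loss_weights()) {
  stopifnot(inherits(fields, "embedding_fields"))
  ref <- as_seg_slice(ref)
  e <- fields$endo; p <- fields$peri
  N <- length(e)
  eps <- w$epsilon

  # cross-entropy part
  s_t <- ref$trabecular != 0
  s_c <- ref$cortical != 0
  s_b <- !(s_t | s_c)
  He_pos <- heaviside(e, eps); He_neg <- 1 - He_pos
  Hp_pos <- heaviside(p, eps); Hp_neg <- 1 - Hp_pos
  pt <- He_neg
  pc <- He_pos * Hp_neg
  pb <- Hp_pos
  S <- pt + pc + pb
  cl <- w$ce_clamp
  dpt <- -(s_t / pmax(pt, cl) - 1 / S) / N
  dpc <- -(s_c / pmax(pc, cl) - 1 / S) / N
  dpb <- -(s_b / pmax(pb, cl) - 1 / S) / N
  hp_e <- d_heaviside(e, eps)
  hp_p <- d_heaviside(p, eps)
  d_endo <- dpt * (-hp_e) + dpc * (hp_e * Hp_neg)
  d_peri <- dpc * (-He_pos * hp_p) + dpb * hp_p

  reg_grad <- function(phi) {
    band <- zero_crossing_mask(phi, w$band_connectivity)
    g <- spatial_gradient(phi)
    mag <- sqrt(g$d1^2 + g$d2^2)
    mag_safe <- pmax(mag, 1e-12)
    eta <- 1e-8
    out <- matrix(0, nrow(phi), ncol(phi))
    if (w$lambda_kappa > 0 && any(band)) {
      kt <- w$kappa_thresh_voxel
      k <- diff_central(g$d1 / (mag + eta), 1L) +
           diff_central(g$d2 / (mag + eta), 2L)
      dk <- band * ((k / kt)^2 > 1) * (2 * k / kt^2) / length(phi) *
        w$lambda_kappa
      dn1 <- diff_central_adj(dk, 1L)
      dn2 <- diff_central_adj(dk, 2L)
      dm <- -(dn1 * g$d1 + dn2 * g$d2) / (mag + eta)^2
      dg1 <- dn1 / (mag + eta) + dm * g$d1 / mag_safe
      dg2 <- dn2 / (mag + eta) + dm * g$d2 / mag_safe
      out <- out + diff_central_adj(dg1, 1L) + diff_central_adj(dg2, 2L)
    }
    if (w$lambda_grad > 0) {
      mc <- pmax(mag, w$grad_clamp)
      dmag <- (!band) * (2 * log(mc) / mc) * (mag > w$grad_clamp) /
        length(phi) * w$lambda_grad
      dg1 <- dmag * g$d1 / mag_safe
      dg2 <- dmag * g$d2 / mag_safe
      out <- out + diff_central_adj(dg1, 1L) + diff_central_adj(dg2, 2L)
    }
    out
  }

  list(endo = d_endo + reg_grad(e), peri = d_peri + reg_grad(p))
}
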