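make_ref <- function(H, W, p_trab = 0.3, p_cort = 0.3, seed = 1) {
  withr::with_seed(seed, {
    t <- matrix(runif(H * W) < p_trab, H, W)
    c <- matrix(runif(H * W) < p_cort, H, W) & !t
    list(trabecular = t, cortical = c)
  })
}

test_that("smoothed Heaviside has the closed-form anchors and symmetry", {
  expect_equal(heaviside(0), 0.5)
  expect_equal(heaviside(1, epsilon = 1), 0.75)   # atan(1) = pi/4
  x <- rnorm(100) * 5
  expect_equal(heaviside(x) + heaviside(-x), rep(1, 100))
  expect_error(heaviside(0, epsilon = 0), "positive")
})

test_that("probabilistic segmentation follows the field-sign construction", {
  big <- 1e8
  f <- embedding_fields(matrix(c(-big, 0, 0, 1), 2, 2),
                        matrix(c(-big, -big, 0, 1), 2, 2))
  p <- probabilistic_segmentation(f)
  expect_false(p$normalized)
  # deep inside the endosteal surface: pure trabecular
  expect_equal(c(p$p_trab[1, 1], p$p_cort[1, 1], p$p_back[1, 1]),
               c(1, 0, 0), tolerance = 1e-7)
  # on the endosteal surface, deep inside periosteal
  expect_equal(c(p$p_trab[2, 1], p$p_cort[2, 1], p$p_back[2, 1]),
               c(0.5, 0.5, 0), tolerance = 1e-7)
  # both fields zero: (1/2, 1/4, 1/2) before normalization
  expect_equal(c(p$p_trab[1, 2], p$p_cort[1, 2], p$p_back[1, 2]),
               c(0.5, 0.25, 0.5))
  pn <- normalize_probs(p)
  expect_equal(c(pn$p_trab[1, 2], pn$p_cort[1, 2], pn$p_back[1, 2]),
               c(0.4, 0.2, 0.4))
  expect_equal(pn$p_trab + pn$p_cort + pn$p_back,
               matrix(1, 2, 2), tolerance = 1e-6)
  # idempotent on normalized input
  expect_equal(normalize_probs(pn)$p_trab, pn$p_trab)
})

test_that("cross-entropy matches hand-computed values", {
  mk <- function(pt, pc, pb) {
    structure(list(p_trab = matrix(pt, 1, 1), p_cort = matrix(pc, 1, 1),
                   p_back = matrix(pb, 1, 1), normalized = TRUE),
              class = "prob_segmentation")
  }
  ref_c <- list(trabecular = matrix(FALSE, 1, 1),
                cortical = matrix(TRUE, 1, 1))
  expect_equal(cross_entropy(mk(0.25, 0.5, 0.25), ref_c), -log(0.5))
  expect_equal(cross_entropy(mk(1 / 3, 1 / 3, 1 / 3), ref_c), log(3))
  # perfect one-hot prediction gives (clamped) ~0
  expect_lt(cross_entropy(mk(0, 1, 0), ref_c), 1e-10)
  # monotone: raising the true-class probability lowers the loss
  l <- sapply(seq(0.2, 0.9, by = 0.1),
              function(p) cross_entropy(mk((1 - p) / 2, p, (1 - p) / 2),
                                        ref_c))
  expect_true(all(diff(l) < 0))
  expect_error(cross_entropy(probabilistic_segmentation(
    embedding_fields(matrix(0, 1, 1), matrix(0, 1, 1))), ref_c),
    "normalized")
})

test_that("discrete differential operators are exact on linear fields", {
  phi <- outer(1:10, 1:10, function(i, j) 2 * i + j)
  g <- spatial_gradient(phi)
  expect_equal(g$d1[2:9, 2:9], matrix(2, 8, 8))
  expect_equal(g$d2[2:9, 2:9], matrix(1, 8, 8))
  expect_equal(gradient_magnitude(phi)[2:9, 2:9], matrix(sqrt(5), 8, 8))
  expect_equal(gradient_magnitude(matrix(7, 6, 6)), matrix(0, 6, 6))
  # adjoint property: <D x, y> == <x, D^T y> (needed by the loss gradients)
  withr::with_seed(1, {
    for (axis in 1:2) {
      x <- matrix(rnorm(48), 6, 8)
      y <- matrix(rnorm(48), 6, 8)
      expect_equal(sum(pqctseg:::diff_central(x, axis) * y),
                   sum(x * pqctseg:::diff_central_adj(y, axis)))
    }
  })
})

test_that("zero-crossing band flags sign changes and exact zeros", {
  expect_false(any(zero_crossing_mask(matrix(2, 4, 4))))
  prof <- matrix(c(-1.5, -0.5, 0.5, 1.5), 1, 4)
  expect_identical(as.vector(zero_crossing_mask(prof)),
                   c(FALSE, TRUE, TRUE, FALSE))
  z <- matrix(1, 3, 3); z[2, 2] <- 0
  expect_true(zero_crossing_mask(z)[2, 2])
})

test_that("curvature of a circle SDF approximates 1/R on the band", {
  for (R in c(10, 20)) {
    n <- 4L * R
    cx <- (n + 1) / 2 + 0.37
    cy <- (n + 1) / 2 - 0.21
    sdf <- sqrt(outer(((1:n) - cx)^2, ((1:n) - cy)^2, "+")) - R
    band <- zero_crossing_mask(sdf)
    k <- curvature(sdf)
    expect_equal(mean(k[band]), 1 / R, tolerance = 0.1)
    # flat SDF has ~zero curvature away from borders
    plane <- outer(1:20, 1:20, function(i, j) i - 10.5)
    expect_lt(max(abs(curvature(plane)[3:18, 3:18])), 1e-6)
    # sign flip of phi flips the curvature sign
    expect_equal(curvature(-sdf)[band], -k[band], tolerance = 1e-6)
  }
})

test_that("regularizer losses vanish in their stated zero cases", {
  w <- loss_weights()
  n <- 64L
  cc <- (n + 1) / 2 + 0.3
  D <- sqrt(outer(((1:n) - cc)^2, ((1:n) - cc)^2, "+"))
  # radius exactly at the curvature threshold (200 um = 1/kappa_thresh)
  r_thr <- 1 / w$kappa_thresh_voxel
  expect_lt(curvature_loss(D - r_thr, w), 1e-2)
  # much flatter circle: strictly zero
  expect_equal(curvature_loss(D - 2.5 * r_thr, w), 0)
  # above the threshold the band contributes ReLU((k/kt)^2 - 1) per voxel;
  # use a coarser threshold so the circle is large enough for the discrete
  # curvature to be accurate (radius 40 voxels, kappa = 2 * kappa_thresh)
  w2 <- loss_weights(kappa_thresh_um = 1 / (40 * 60.7))
  n2 <- 128L
  D2 <- sqrt(outer(((1:n2) - 64.7)^2, ((1:n2) - 64.2)^2, "+"))
  band <- zero_crossing_mask(D2 - 20)
  expect_equal(curvature_loss(D2 - 20, w2) * n2^2 / sum(band), 3,
               tolerance = 0.15)
  # exact SDF: gradient-magnitude loss ~0; scaling by e adds log^2 e = 1
  expect_lt(gradient_magnitude_loss(D - 20, w), 1e-3)
  scaled <- (D - 20) * exp(1)
  off <- !zero_crossing_mask(scaled)
  expect_equal(gradient_magnitude_loss(scaled, w) * n^2 / sum(off), 1,
               tolerance = 0.01)
  # empty band: curvature loss is exactly zero
  expect_equal(curvature_loss(matrix(5, 8, 8) + outer(1:8, 1:8, "+") / 100,
                              w), 0)
})

test_that("total loss combines the five terms with the lambda weights", {
  withr::with_seed(7, {
    H <- 12L; W <- 12L
    f <- embedding_fields(matrix(rnorm(H * W), H, W),
                          matrix(rnorm(H * W), H, W))
    ref <- make_ref(H, W)
    w0 <- loss_weights(lambda_kappa = 0, lambda_grad = 0)
    lb0 <- total_loss(f, ref, w0)
    expect_equal(lb0$L_total, lb0$L_CE)
    w <- loss_weights()
    lb <- total_loss(f, ref, w)
    expect_equal(lb$L_total,
                 lb$L_CE + 1e-4 * (lb$L_kappa_endo + lb$L_kappa_peri) +
                   1e-4 * (lb$L_grad_endo + lb$L_grad_peri))
    expect_true(all(unlist(lb) >= 0 | names(unlist(lb)) == "L_total"))
  })
})

test_that("ground-truth SDF embeddings of a phantom slice give near-pure CE", {
  ph <- generate_phantom(phantom_spec(n_slices = 4L, in_plane = 48L,
                                     outer_radius_mm = 1.1,
                                     cortical_thickness_mm = 0.45,
                                     pore_count = 0L, seed = 2L))
  z <- 2L
  f <- embedding_fields(ph$endo_sdf[z, , ], ph$peri_sdf[z, , ])
  lb <- total_loss(f, segmentation_slice(ph$truth, z), loss_weights())
  expect_lt(lb$L_kappa_endo + lb$L_kappa_peri, 1e-2)
  expect_lt(lb$L_grad_endo + lb$L_grad_peri, 1e-2)
  expect_equal(lb$L_total, lb$L_CE, tolerance = 1e-4)
  # CE itself is small: the SDF signs reproduce the masks
  expect_lt(lb$L_CE, 0.2)
})

test_that("analytic loss gradient matches finite differences", {
  withr::with_seed(11, {
    H <- 9L; W <- 9L
    e <- matrix(rnorm(H * W), H, W)
    p <- matrix(rnorm(H * W), H, W)
    ref <- make_ref(H, W, seed = 3)
    # inflated lambdas so the regularizer paths are exercised meaningfully
    w <- loss_weights(lambda_kappa = 1e-2, lambda_grad = 1e-2)
    fl <- function(e, p) total_loss(embedding_fields(e, p), ref, w)$L_total
    gr <- total_loss_gradient(embedding_fields(e, p), ref, w)
    h <- 1e-6
    for (i in sample(H * W, 10)) {
      e2 <- e; e2[i] <- e2[i] + h
      expect_equal((fl(e2, p) - fl(e, p)) / h, gr$endo[i], tolerance = 1e-3)
      p2 <- p; p2[i] <- p2[i] + h
      expect_equal((fl(e, p2) - fl(e, p)) / h, gr$peri[i], tolerance = 1e-3)
    }
  })
})

test_that("total loss is invariant to consistent orientation flips", {
  withr::with_seed(13, {
    H <- 10L; W <- 10L
    f <- embedding_fields(matrix(rnorm(H * W), H, W),
                          matrix(rnorm(H * W), H, W))
    ref <- make_ref(H, W, seed = 5)
    flip <- function(m) m[rev(seq_len(nrow(m))), ]
    f2 <- embedding_fields(flip(f$endo), flip(f$peri))
    ref2 <- list(trabecular = flip(ref$trabecular),
                 cortical = flip(ref$cortical))
    w <- loss_weights()
    expect_equal(unclass(total_loss(f, ref, w)),
                 unclass(total_loss(f2, ref2, w)), tolerance = 1e-12)
  })
})
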