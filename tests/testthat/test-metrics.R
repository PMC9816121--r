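test_that("overlap metrics count voxels and respect the Dice-Jaccard link", {
  d <- c(4, 10, 10)
  a <- array(FALSE, d); a[1, 1:10, 1:10] <- TRUE           # |A| = 100
  b <- array(FALSE, d); b[1, 1:10, 1:8] <- TRUE            # |B| = 80
  om <- overlap_metrics(a, b)
  expect_equal(om$dsc, 2 * 80 / 180)
  expect_equal(om$jsc, 80 / 100)
  expect_identical(overlap_metrics(a, a), structure(list(dsc = 1, jsc = 1),
                                                    class = "overlap_metrics"))
  disj <- array(FALSE, d); disj[2, , ] <- TRUE
  expect_equal(overlap_metrics(a, disj)$dsc, 0)
  empty <- array(FALSE, d)
  expect_equal(overlap_metrics(empty, empty)$dsc, 1)
  # dsc = 2 jsc / (1 + jsc) for random masks
  withr::with_seed(31, {
    for (i in 1:5) {
      x <- array(runif(prod(d)) < 0.4, d)
      y <- array(runif(prod(d)) < 0.4, d)
      m <- overlap_metrics(x, y)
      expect_equal(m$dsc, 2 * m$jsc / (1 + m$jsc))
    }
  })
  expect_error(overlap_metrics(a, array(FALSE, c(2, 2, 2))), "differ")
})

test_that("surface distances match a brute-force all-pairs oracle", {
  # identical masks
  m <- array(FALSE, c(6, 6, 6)); m[2:5, 2:5, 2:5] <- TRUE
  sm <- surface_distances(m, m, voxel_size_mm = 1)
  expect_equal(sm$assd_mm, 0)
  expect_equal(sm$hausdorff_mm, 0)
  # two 10^3 cubes offset by 3 voxels along one axis at 1 mm voxels
  a <- array(FALSE, c(16, 14, 14)); a[2:11, 3:12, 3:12] <- TRUE
  b <- array(FALSE, c(16, 14, 14)); b[5:14, 3:12, 3:12] <- TRUE
  sm2 <- surface_distances(a, b, voxel_size_mm = 1)
  expect_equal(sm2$hausdorff_mm, 3)
  # brute-force oracle on a small random pair
  withr::with_seed(32, {
    x <- array(FALSE, c(8, 8, 8)); x[2:6, 2:5, 3:7] <- TRUE
    y <- array(FALSE, c(8, 8, 8)); y[3:7, 3:7, 2:5] <- TRUE
    bx <- which(pqctseg:::boundary6(x), arr.ind = TRUE)
    by <- which(pqctseg:::boundary6(y), arr.ind = TRUE)
    cross <- function(p, q) {
      apply(p, 1, function(v)
        sqrt(min(colSums((t(q) - v)^2))))
    }
    dxy <- cross(bx, by); dyx <- cross(by, bx)
    sm3 <- surface_distances(x, y, voxel_size_mm = 0.25)
    expect_equal(sm3$assd_mm, mean(c(dxy, dyx)) * 0.25, tolerance = 1e-12)
    expect_equal(sm3$hausdorff_mm, max(c(dxy, dyx)) * 0.25,
                 tolerance = 1e-12)
  })
  # symmetry, ordering and the published voxel equivalence
  sw <- surface_distances(b, a, voxel_size_mm = 1)
  expect_equal(sw$assd_mm, sm2$assd_mm)
  expect_lte(sm2$assd_mm, sm2$hausdorff_mm)
  expect_equal(mm_to_voxels(0.91), 15, tolerance = 0.05)
  expect_error(surface_distances(a, array(FALSE, c(16, 14, 14))),
               "nonempty")
})

test_that("Bland-Altman bias and limits follow the 1.96 SD convention", {
  expect_equal(bland_altman(1:5, 1:5),
               list(bias = 0, loa_low = 0, loa_high = 0, sd_error = 0))
  ba <- bland_altman(c(9, 11), c(10, 10))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  off <- bland_altman(1:4 + 2.5, 1:4)
  expect_equal(off$bias, 2.5)
  expect_equal(off$loa_low, 2.5)
  expect_error(bland_altman(1:3, 1:4), "mismatch")
})

test_that("linear agreement reproduces closed-form least squares", {
  ref <- c(1, 2, 3, 4, 5)
  # suppress lm's perfect-fit chatter on the exact identity cases
  id <- suppressWarnings(linear_agreement(ref, ref))
  expect_equal(id$slope, 1)
  expect_equal(id$intercept, 0)
  expect_equal(id$r_squared, 1)
  expect_equal(suppressWarnings(linear_agreement(2 * ref, ref))$slope, 2)
  # worked 5-point set against hand OLS formulas
  pred <- c(2.1, 2.9, 4.3, 4.8, 6.2)
  fitd <- linear_agreement(pred, ref)
  sxx <- sum((ref - mean(ref))^2)
  slope <- sum((ref - mean(ref)) * (pred - mean(pred))) / sxx
  intercept <- mean(pred) - slope * mean(ref)
  resid <- pred - intercept - slope * ref
  se_slope <- sqrt(sum(resid^2) / 3 / sxx)
  expect_equal(fitd$slope, slope)
  expect_equal(fitd$intercept, intercept)
  expect_equal(fitd$slope_ci, slope + c(-1.96, 1.96) * se_slope)
  expect_error(linear_agreement(1:5, rep(2, 5)), "degenerate")
})

test_that("precision statistics follow the two-replicate formulas", {
  same <- cbind(c(100, 200), c(100, 200))
  ps0 <- precision_stats(same)
  expect_equal(ps0$rms_sd, 0)
  expect_equal(ps0$lsc, 0)
  one <- precision_stats(cbind(100, 102))
  expect_equal(one$rms_sd, sqrt(2), tolerance = 1e-6)
  expect_equal(one$rms_pct_cv, 100 * sqrt(2) / 101, tolerance = 1e-6)
  expect_equal(one$lsc, 2.77 * sqrt(2), tolerance = 1e-6)
  withr::with_seed(33, {
    tab <- cbind(runif(40, 80, 120), runif(40, 80, 120))
    ps <- precision_stats(tab)
    # brute force: RMS of the within-pair two-replicate SDs
    expect_equal(ps$rms_sd, sqrt(mean(apply(tab, 1, var))))
    # homogeneity: scaling values scales SD/LSC, leaves %CV unchanged
    ps2 <- precision_stats(3 * tab)
    expect_equal(ps2$rms_sd, 3 * ps$rms_sd)
    expect_equal(ps2$lsc, 3 * ps$lsc)
    expect_equal(ps2$rms_pct_cv, ps$rms_pct_cv)
  })
})

test_that("normality test matches the frozen reference values", {
  x <- c(3.137726, 4.253018, 2.755823, 2.467606, 4.618883, 2.63006,
         3.519008, 3.284229, 4.61612, 2.158831, 5.693376, 1.758897,
         3.67898, 3.387453, 1.633458, 3.892612, 2.28577, 1.219165,
         4.233188, 0.848705, 1.420013, 2.732837, 4.595686, 4.058639,
         3.102712)
  r <- dagostino_pearson(x)
  expect_equal(r$statistic, 0.32443704136, tolerance = 1e-9)
  expect_equal(r$p_value, 0.85025538585, tolerance = 1e-9)
  y <- c(-1.457156, -0.319671, -0.470373, -0.638878, -0.275142, 1.494941,
         -0.865831, 0.968278, -1.68287, -0.334885, 0.162753, 0.586222,
         0.711227, 0.793347, -0.348725, -0.462352, 0.857976, -0.191304,
         -1.275686, -1.133287, -0.919452, 0.497161, 0.142426, 0.690485,
         -0.427253)
  r2 <- dagostino_pearson(y)
  expect_equal(r2$statistic, 0.69613711787, tolerance = 1e-9)
  expect_equal(r2$p_value, 0.70605046849, tolerance = 1e-9)
  expect_error(dagostino_pearson(1:5), "at least 8")
})

test_that("signed-rank test handles zeros and ties like the Pratt method", {
  a <- c(1.0, 2.0, 3.0, 3.0, 5.0, 6.5, 7.0, 8.0, 2.5, 4.0, 9.0, 10.0)
  b <- c(1.0, 1.5, 3.5, 3.0, 4.0, 6.0, 7.5, 6.0, 2.5, 4.5, 8.0, 9.0)
  wt <- wilcoxon_signed_rank(a, b)       # frozen reference p-value
  expect_equal(wt$p_value, 0.14954135458, tolerance = 1e-9)
  expect_equal(wt$n_zero, 3)
  # all-zero differences: no evidence of a difference
  expect_equal(wilcoxon_signed_rank(1:10, 1:10)$p_value, 1)
  # one protocol strictly smaller for all of 20 pairs: clearly significant
  x1 <- seq(5, 24) + 0
  x2 <- x1 + seq(0.2, 1.0, length.out = 20)
  expect_lt(wilcoxon_signed_rank(x1, x2)$p_value, 1e-3)
})

test_that("precision comparison wires the component tests together", {
  withr::with_seed(34, {
    mu <- runif(24, 90, 110)
    ref <- cbind(mu + rnorm(24, sd = 3), mu + rnorm(24, sd = 3))
    prd <- cbind(mu + rnorm(24, sd = 0.5), mu + rnorm(24, sd = 0.5))
    cp <- compare_precision(prd, ref)
    expect_true(cp$significant)
    expect_lt(cp$pred$rms_sd, cp$ref$rms_sd)
    expect_true(all(is.finite(cp$normality_p)))
    ident <- compare_precision(ref, ref)
    expect_equal(ident$p_value, 1)
    expect_false(ident$significant)
    expect_warning(compare_precision(prd[1:3, ], ref[1:3, ]), "fewer than 5")
  })
})

test_that("compartment summaries report counts, densities and areas", {
  vol <- density_volume(array(500, c(2, 6, 6)), voxel_size_mm = 1)
  cort <- array(FALSE, c(2, 6, 6)); cort[1, 1:2, 1:5] <- TRUE  # 10 voxels
  trab <- array(FALSE, c(2, 6, 6))
  seg <- segmentation_pair(cort, trab, voxel_size_mm = 1)
  tab <- compartment_summaries(vol, seg)
  expect_equal(tab$voxel_count, c(10, 0))
  expect_equal(tab$mean_density[1], 500)
  expect_true(is.na(tab$mean_density[2]))
  expect_equal(tab$mean_area_mm2[1], 5)   # 10 voxels over 2 slices at 1 mm^2
})

test_that("quartile sub-groups select the intended tails", {
  v <- 1:100
  expect_equal(sum(quartile_subgroup(v, "bottom")), 25)
  expect_equal(sum(quartile_subgroup(v, "top")), 25)
  expect_true(all(which(quartile_subgroup(v, "top")) > 75))
})
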