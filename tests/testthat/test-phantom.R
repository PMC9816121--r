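test_that("phantom generation is seeded, disjoint and single-component", {
  spec <- phantom_spec(n_slices = 6L, in_plane = 48L, outer_radius_mm = 1.1,
                       cortical_thickness_mm = 0.45, seed = 41L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  tr <- a$truth$trabecular$voxels
  co <- a$truth$cortical$voxels
  expect_false(any(tr & co))
  expect_identical(attr(label_components(tr), "n"), 1L)
  expect_identical(attr(label_components(co), "n"), 1L)
  expect_true(all(a$volume$voxels >= -400 & a$volume$voxels <= 1400))
  expect_error(generate_phantom(phantom_spec(in_plane = 32L,
                                             outer_radius_mm = 2)),
               "exceeds")
})

test_that("cortical voxels average to the specified density", {
  spec <- phantom_spec(n_slices = 8L, in_plane = 64L, outer_radius_mm = 1.5,
                       cortical_thickness_mm = 0.6, pore_count = 0L,
                       noise_sd = 30, seed = 42L)
  ph <- generate_phantom(spec)
  cort <- ph$truth$cortical$voxels
  n <- sum(cort)
  se <- spec$noise_sd / sqrt(n)
  expect_lt(abs(mean(ph$volume$voxels[cort]) - spec$cortical_density),
            3 * se)
})

test_that("ground-truth embeddings are proper signed distance fields", {
  ph <- generate_phantom(phantom_spec(n_slices = 6L, in_plane = 64L,
                                      outer_radius_mm = 1.5,
                                      cortical_thickness_mm = 0.6,
                                      seed = 43L))
  # sign consistency with the masks
  expect_true(all((ph$endo_sdf < 0) == ph$truth$trabecular$voxels))
  expect_true(all(((ph$endo_sdf > 0) & (ph$peri_sdf < 0)) ==
                    ph$truth$cortical$voxels))
  # |grad phi| ~ 1 off the band for at least 99% of voxels
  for (fld in list(ph$endo_sdf, ph$peri_sdf)) {
    frac <- vapply(seq_len(dim(fld)[1]), function(z) {
      gm <- gradient_magnitude(fld[z, , ])
      band <- zero_crossing_mask(fld[z, , ])
      mean(abs(gm[!band] - 1) <= 0.1)
    }, numeric(1))
    expect_gt(min(frac), 0.99)
  }
  # curvature on the periosteal zero band ~ 1 / outer radius
  r_vox <- ph$spec$outer_radius_mm / ph$spec$voxel_size_mm
  z <- 3L
  band <- zero_crossing_mask(ph$peri_sdf[z, , ])
  k <- curvature(ph$peri_sdf[z, , ])
  expect_equal(mean(k[band]), 1 / r_vox, tolerance = 0.1)
})

test_that("repeat pairs share anatomy and reveal their true transform", {
  spec <- phantom_spec(n_slices = 6L, in_plane = 64L, outer_radius_mm = 1.2,
                       cortical_thickness_mm = 0.5, seed = 44L)
  # zero transform, same noise seed: identical volumes
  z1 <- generate_phantom(spec)
  z2 <- generate_phantom(spec, center_offset_mm = c(0, 0), rotation_deg = 0)
  expect_identical(z1$volume$voxels, z2$volume$voxels)
  # fresh noise only: identical ground truth
  z3 <- generate_phantom(spec, noise_seed = 999L)
  expect_identical(z1$truth$cortical$voxels, z3$truth$cortical$voxels)
  expect_false(identical(z1$volume$voxels, z3$volume$voxels))
  # a known 2-voxel shift is recovered by mask cross-correlation
  vs <- spec$voxel_size_mm
  sh <- generate_phantom(spec, center_offset_mm = c(2 * vs, 0))
  ov <- sapply(-4:4, function(dx) {
    m1 <- z1$truth$trabecular$voxels
    m2 <- sh$truth$trabecular$voxels
    n <- dim(m1)[2]
    if (dx >= 0) sum(m1[, seq_len(n - dx) + dx, ] & m2[, seq_len(n - dx), ])
    else sum(m1[, seq_len(n + dx), ] & m2[, seq_len(n + dx) - dx, ])
  })
  expect_equal((-4:4)[which.max(ov)], -2)
  # the pair generator records the applied transform
  pr <- generate_repeat_pair(spec, repositioning_mm = 0.3, rotation_deg = 4)
  expect_s3_class(pr, "phantom_pair")
  expect_equal(sqrt(sum(pr$transform$translation_mm^2)), 0.3)
  expect_error(generate_repeat_pair(spec, repositioning_mm = 5), "exceeds")
})

test_that("stratified split hits the 70/15/15 sizes and keeps participants whole", {
  withr::with_seed(45, {
    df <- data.frame(participant = rep(sprintf("P%03d", 1:100), each = 2),
                     study = "norm",
                     tt_bmd = rep(runif(100, 150, 400), each = 2) +
                       runif(200, 0, 5))
  })
  sp <- stratified_split(df, seed = 46L)
  expect_equal(nrow(sp), 100L)             # one row per participant
  expect_equal(anyDuplicated(sp$participant), 0L)
  expect_equal(unname(table(sp$subset)[c("train", "validation", "test")]),
               c(70L, 15L, 15L), ignore_attr = TRUE)
  expect_equal(unname(table(sp$bin)), rep(25L, 4), ignore_attr = TRUE)
  # deterministic under the seed
  expect_identical(sp, stratified_split(df, seed = 46L))
  map <- function(s) s$subset[order(s$participant)]
  expect_false(identical(map(sp), map(stratified_split(df, seed = 47L))))
  # multiple studies are stratified independently
  df2 <- df
  df2$study <- rep(c("norm", "fracture"), 100)
  df2$participant <- rep(sprintf("Q%03d", 1:100), each = 2)
  df2$study <- rep(rep(c("norm", "fracture"), c(60, 40)), each = 2)
  sp2 <- stratified_split(df2, seed = 48L)
  expect_equal(nrow(sp2), 100L)
  expect_error(stratified_split(df[0, ]), "empty")
  expect_error(stratified_split(df, fractions = c(a = 0.5, b = 0.4)),
               "sum to 1")
})
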