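test_that("ball erosion/dilation are voxel-exact against brute force", {
  withr::with_seed(21, {
    for (r in 1:3) {
      m <- array(runif(14^3) < 0.4, c(14, 14, 14))
      expect_identical(binary_dilate(m, r), bf_dilate(m, r))
      expect_identical(binary_erode(m, r), bf_erode(m, r, FALSE))
      expect_identical(binary_erode(m, r, border = "foreground"),
                       bf_erode(m, r, TRUE))
    }
  })
})

test_that("component selection matches the graph-based oracle", {
  withr::with_seed(22, {
    for (conn in c(6L, 26L)) {
      m <- array(runif(12^3) < 0.25, c(12, 12, 12))
      expect_identical(largest_component(m, conn),
                       bf_largest_component(m, conn))
    }
  })
  expect_identical(largest_component(array(FALSE, c(3, 3, 3))),
                   array(FALSE, c(3, 3, 3)))
})

test_that("iterative filter matches the brute-force reference voxel-exactly", {
  fx <- speck_cavity_fixture(n = 32L, ball_r = 11, cavity_r = 3)
  got <- iterative_binary_segmentation_filter(fx$mask, open_max = 2L,
                                              close_max = 3L)
  ref <- bf_iterative_filter(fx$mask, 2L, 3L)
  expect_identical(got, ref)
  expect_false(got[2, 2, 2])              # speck removed
  expect_true(all(got[fx$dist <= fx$cavity_r]))  # cavity filled
})

test_that("full-radius iterative filter cleans the fixture and keeps shape", {
  fx <- speck_cavity_fixture(n = 64L, ball_r = 30, cavity_r = 5)
  out <- iterative_binary_segmentation_filter(fx$mask, 5L, 15L)
  expect_false(out[2, 2, 2])
  expect_true(all(out[fx$dist <= fx$cavity_r]))
  ball <- fx$dist <= fx$ball_r
  expect_gt(overlap_metrics(out, ball)$dsc, 0.98)
  expect_identical(attr(label_components(out), "n"), 1L)
  # empty input passes through; vanishing masks warn
  empty <- array(FALSE, c(8, 8, 8))
  expect_identical(iterative_binary_segmentation_filter(empty, 2L, 2L),
                   empty)
  dot <- empty; dot[4, 4, 4] <- TRUE
  expect_warning(out2 <- iterative_binary_segmentation_filter(dot, 3L, 3L),
                 "vanished")
  expect_false(any(out2))
})

test_that("minimum cortical shell is the exact 8-voxel distance band", {
  trab <- array(FALSE, c(30, 40, 40))
  trab[8:22, 12:28, 12:28] <- TRUE
  sh <- minimum_cortical_shell_filter(trab, 8L)
  expect_false(any(sh & trab))
  d <- sqrt(pqctseg:::cpp_edt3_sq(!trab, dim(trab)))  # distance to trab
  expect_identical(sh, array(d > 0 & d <= 8, dim(trab)))
  # 8 voxels is ~0.5 mm at the scanner voxel size
  expect_lt(abs(voxels_to_mm(8) - 0.5), 0.015)
  expect_false(any(minimum_cortical_shell_filter(array(FALSE, c(4, 4, 4)),
                                                 8L)))
})

test_that("density-based bone mask recovers the whole primary bone", {
  expect_warning(
    empty <- morphological_bone_mask_filter(
      normalized_volume(array(-1, c(6, 24, 24)))),
    "empty")
  expect_false(any(empty$voxels))
  ph <- generate_phantom(phantom_spec(n_slices = 6L, in_plane = 96L,
                                      outer_radius_mm = 1.2,
                                      cortical_thickness_mm = 0.5,
                                      pore_count = 1L,
                                      secondary_bone = TRUE, seed = 23L))
  nv <- pad_in_plane(standardize(ph$volume))
  bone <- morphological_bone_mask_filter(nv)
  expect_identical(bone$label, "bone")
  expect_identical(attr(label_components(bone$voxels), "n"), 1L)
  truth_bone <- ph$truth$cortical$voxels | ph$truth$trabecular$voxels
  # covers annulus + interior (cavity filled by the close), one component
  expect_gt(overlap_metrics(bone$voxels, truth_bone)$dsc, 0.95)
  # secondary bone excluded by the largest-component rule: the mask stays
  # near the primary bone
  sec <- nv$voxels > -0.25 & !binary_dilate(truth_bone, 3)
  expect_false(any(bone$voxels & sec))
})

test_that("post-processing repairs corrupted raw masks to the ground truth", {
  ph <- generate_phantom(smoke_phantom_spec(24L))
  nv <- pad_in_plane(standardize(ph$volume))
  raw_c <- ph$truth$cortical$voxels
  raw_t <- ph$truth$trabecular$voxels
  withr::with_seed(25, {
    # inject specks in the background and holes inside the compartments
    speck <- array(runif(length(raw_c)) < 0.001, dim(raw_c)) &
      !(raw_c | raw_t)
    hole_t <- array(runif(length(raw_t)) < 0.02, dim(raw_t)) & raw_t
    hole_c <- array(runif(length(raw_c)) < 0.02, dim(raw_c)) & raw_c
    raw <- segmentation_pair(cortical = (raw_c & !hole_c),
                             trabecular = (raw_t & !hole_t) | speck)
  })
  seg <- postprocess_segmentation(nv, raw)
  expect_false(any(seg$cortical$voxels & seg$trabecular$voxels))
  expect_identical(attr(label_components(seg$cortical$voxels), "n"), 1L)
  expect_identical(attr(label_components(seg$trabecular$voxels), "n"), 1L)
  # all disagreements sit within a 2-voxel band of the true boundary
  for (comp in c("cortical", "trabecular")) {
    truth <- ph$truth[[comp]]$voxels
    diff <- xor(seg[[comp]]$voxels, truth)
    bnd <- pqctseg:::boundary6(truth)
    dist_to_bnd <- sqrt(pqctseg:::cpp_edt3_sq(!bnd, dim(bnd)))
    expect_lte(max(dist_to_bnd[diff]), 2)
  }
  # the minimum-shell guarantee: cortical contains the shell of trabecular
  shell <- binary_dilate(seg$trabecular$voxels, 8L) & !seg$trabecular$voxels
  expect_true(all(seg$cortical$voxels[shell]))
  # near-idempotence: reapplying changes under 1% of voxels
  seg2 <- postprocess_segmentation(nv, seg)
  changed <- mean(xor(seg2$cortical$voxels, seg$cortical$voxels) |
                    xor(seg2$trabecular$voxels, seg$trabecular$voxels))
  expect_lt(changed, 0.01)
})

test_that("secondary bone never reaches the final masks", {
  ph <- generate_phantom(phantom_spec(n_slices = 6L, in_plane = 96L,
                                      outer_radius_mm = 1.2,
                                      cortical_thickness_mm = 0.5,
                                      pore_count = 1L,
                                      secondary_bone = TRUE, seed = 26L))
  nv <- pad_in_plane(standardize(ph$volume))
  # raw masks from thresholding density (so the secondary bone is present)
  bone_raw <- nv$voxels > -0.25
  raw <- segmentation_pair(
    cortical = bone_raw & !ph$truth$trabecular$voxels,
    trabecular = ph$truth$trabecular$voxels)
  seg <- postprocess_segmentation(nv, raw)
  truth_bone <- ph$truth$cortical$voxels | ph$truth$trabecular$voxels
  outside <- !binary_dilate(truth_bone, 3)
  expect_false(any(seg$cortical$voxels & outside))
  expect_false(any(seg$trabecular$voxels & outside))
})
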