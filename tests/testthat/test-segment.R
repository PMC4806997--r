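test_that("thresholding recovers a bright cube exactly and rejects empty masks", {
  d <- c(12, 12, 12)
  x <- array(0, d); x[4:9, 4:9, 4:9] <- 10
  v <- volume_image(x, c(1, 1, 1))
  m <- body_mask(v, threshold = 5, erosion_iters = 0)
  expect_identical(m$mask, x >= 5)
  expect_error(body_mask(v, threshold = 11), "empty mask")
})

test_that("despeckling removes an isolated voxel but keeps the cube intact", {
  d <- c(14, 14, 14)
  x <- array(0, d); x[4:10, 4:10, 4:10] <- 10
  x[13, 13, 13] <- 10   # isolated bright speck
  v <- volume_image(x, c(1, 1, 1))
  m <- body_mask(v, threshold = 5, erosion_iters = 1)
  expected <- array(FALSE, d); expected[4:10, 4:10, 4:10] <- TRUE
  expect_identical(m$mask, expected)
  expect_equal(m$provenance$threshold, 5)
})

test_that("Otsu threshold separates a bimodal image", {
  set.seed(31)
  x <- c(rnorm(600, 1, 0.3), rnorm(400, 10, 0.6))
  thr <- otsu_threshold(x)
  expect_gt(thr, 2.5); expect_lt(thr, 9)
  expect_error(otsu_threshold(rep(3, 10)), "constant")
})

test_that("erosion and dilation follow the 6-connected structuring element", {
  d <- c(7, 7, 7)
  x <- array(FALSE, d); x[3:5, 3:5, 3:5] <- TRUE
  er <- binary_erode(x, 1L)
  # eroding a 3-cube with the cross leaves only the centre voxel
  expect_equal(sum(er), 1)
  expect_true(er[4, 4, 4])
  di <- binary_dilate(er, 1L)
  expect_true(all(which(di) %in% which(x)))  # cross fits inside the cube
  expect_equal(sum(di), 7)                   # centre + 6 face neighbours
})

test_that("largest connected component keeps the big blob", {
  d <- c(10, 10, 10)
  x <- array(FALSE, d)
  x[2:5, 2:5, 2:5] <- TRUE       # 64 voxels
  x[8:9, 8:9, 8:9] <- TRUE       # 8 voxels
  lc <- largest_component(x)
  expect_equal(sum(lc), 64)
  expect_true(all(lc[2:5, 2:5, 2:5]))
})

test_that("pectoral cut removes posterior voxels and the split is disjoint", {
  ph <- small_phantom(composition = list(type = "uniform", fraction = 0.5))
  full <- segmentation_mask(ph$labels != 0, ph$spacing_mm)
  cut <- ph$chest_wall_plane_index
  parts <- pectoral_cut_and_split(full, cut)
  # counting oracle on the label field: breast voxels anterior to the cut
  expect_equal(sum(parts$L$mask) + sum(parts$R$mask),
               sum(ph$labels %in% 1:2))
  expect_equal(sum(parts$L$mask & parts$R$mask), 0)
  expect_true(all((parts$L$mask | parts$R$mask) <= full$mask))
  # mirror-symmetric phantom: equal sides
  expect_equal(sum(parts$L$mask), sum(parts$R$mask))
  # cut beyond the posterior edge is a no-op
  noop <- pectoral_cut_and_split(full, dim(full$mask)[2] + 1L)
  expect_equal(sum(noop$L$mask) + sum(noop$R$mask), sum(full$mask))
  expect_error(pectoral_cut_and_split(full, 1L), "removed the whole mask")
})

test_that("mask volume arithmetic is spacing-aware", {
  m <- segmentation_mask(array(TRUE, c(10, 10, 10)), c(1, 1, 1))
  expect_equal(mask_volume_cm3(m), 1)
  m2 <- segmentation_mask(array(TRUE, c(10, 10, 10)), c(0.8, 0.8, 7))
  expect_equal(mask_volume_cm3(m2), 1000 * 0.8 * 0.8 * 7 / 1000)
})

test_that("segmentation of a noise-free phantom recovers the true breast voxels", {
  ph <- small_phantom(fraction = 0.4, seed = 9)
  ep <- simulate_dixon_acquisition(ph, tissues = tissues_single(),
                                   seq = "hr_gre_pd", noise_sd = 0)
  pair <- two_point_separation(ep)
  ipmag <- volume_image(pair$water$data + pair$fat$data, pair$water$spacing_mm)
  parts <- pectoral_cut_and_split(body_mask(ipmag), ph$chest_wall_plane_index)
  seg <- parts$L$mask | parts$R$mask
  truth <- ph$labels %in% 1:2
  dice <- 2 * sum(seg & truth) / (sum(seg) + sum(truth))
  expect_gte(dice, 0.99)
})

test_that("translation registration recovers identity and constructed shifts", {
  set.seed(33)
  base <- array(0, c(24, 24, 12))
  base[6:18, 6:18, 3:9] <- array(runif(13 * 13 * 7, 1, 2), c(13, 13, 7))
  sm <- volume_image(.5 * base + 1, c(1, 1, 1))
  expect_equal(as.numeric(register_translation(sm, sm, 3)), c(0, 0, 0),
               tolerance = 1e-9)
  # moving = fixed translated by exactly (3, 0, 0) voxels
  moved <- array(0, dim = dim(base))
  moved[4:21, , ] <- base[7:24, , ]   # content shifted by -3 along axis 1
  mv <- volume_image(moved, c(1, 1, 1))
  sh <- register_translation(volume_image(base, c(1, 1, 1)), mv, 5)
  expect_equal(as.numeric(sh)[1], 3, tolerance = 0.5)
  expect_equal(as.numeric(sh)[2:3], c(0, 0), tolerance = 0.5)
  # mutual information is invariant to monotone intensity remapping
  remapped <- volume_image(exp(moved), c(1, 1, 1))
  sh2 <- register_translation(volume_image(base, c(1, 1, 1)), remapped, 5)
  expect_equal(as.numeric(sh2)[1], 3, tolerance = 0.5)
  expect_error(register_translation(sm, const_volume(1, dim(base)), 2),
               "degenerate")
})

test_that("mask transfer preserves identity, counts and physical volume", {
  ph <- small_phantom(composition = list(type = "uniform", fraction = 0.5))
  full <- segmentation_mask((ph$labels == 1L) | (ph$labels == 2L), ph$spacing_mm,
                            posterior_cut_index = ph$chest_wall_plane_index)
  d <- dim(full$mask)
  same <- transfer_mask(full, c(0, 0, 0), d, ph$spacing_mm)
  expect_identical(same$mask, full$mask)
  expect_identical(same$posterior_cut_index, full$posterior_cut_index)
  # integer-voxel shift conserves the count away from the edge
  sh <- transfer_mask(full, c(2 * ph$spacing_mm[1], 0, 0), d, ph$spacing_mm)
  expect_equal(sum(sh$mask), sum(full$mask))
  # transfer onto the coarse grid conserves volume within one slice worth
  lr <- c(0.8, 0.8, 7.0)
  lrd <- as.integer(ceiling(d * ph$spacing_mm / lr))
  onto <- transfer_mask(full, c(0, 0, 0), lrd, lr)
  slice_cm3 <- sum(full$mask) / d[3] * voxel_volume_mm3(ph$spacing_mm) / 1000
  expect_lt(abs(mask_volume_cm3(onto) - mask_volume_cm3(full)), 2 * slice_cm3)
})
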