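make_pair <- function(w, f, spacing = c(1, 1, 1)) {
  dixon_pair(volume_image(w, spacing), volume_image(f, spacing))
}

test_that("ROI size follows the 30 mm extent in voxels", {
  d <- c(64, 64, 10)
  # left half water, right half fat, so every slice qualifies
  w <- array(0, d); w[1:32, , ] <- 1
  f <- array(0, d); f[33:64, , ] <- 1
  m <- segmentation_mask(array(TRUE, d), c(1, 1, 1))
  roi <- select_calibration_roi(make_pair(w, f), m)
  expect_identical(roi$half_size_vox, c(30L, 30L))
  # at 1.3 mm the ROI is 23 x 23 voxels (nearest integer)
  m13 <- segmentation_mask(array(TRUE, d), c(1.3, 1.3, 1))
  roi13 <- select_calibration_roi(make_pair(w, f, c(1.3, 1.3, 1)), m13)
  expect_identical(roi13$half_size_vox, c(23L, 23L))
  expect_equal(roi$f_max, 1); expect_equal(roi$w_max, 1)
})

test_that("an all-fat breast yields no calibration slice", {
  d <- c(48, 48, 8)
  w <- array(0, d); f <- array(1, d)
  m <- segmentation_mask(array(TRUE, d), c(1, 1, 1))
  expect_error(select_calibration_roi(make_pair(w, f), m),
               "both fat and water")
})

test_that("correction factor is the ratio of ROI maxima", {
  expect_equal(correction_factor(list(f_max = 3.0, w_max = 1.5))$c, 2.0)
  expect_equal(correction_factor(list(f_max = 1, w_max = 1))$c, 1)
  expect_error(correction_factor(list(f_max = 1, w_max = 0)), "w_max")
})

test_that("calibration on a noise-free phantom matches the signal-equation ratio", {
  # full-size phantom: the clinical 30 mm ROI must fit inside the breast
  ph <- generate_phantom(phantom_spec(composition = list(type = "blobs",
                                                         fraction = 0.4,
                                                         scale_mm = 8),
                                      noise_sd = 0, rng_seed = 13))
  # masks are drawn on the proton-density in-phase data (on the T1-weighted
  # image the dim water tissue would fall below an automatic threshold)
  ep_pd <- simulate_dixon_acquisition(ph, tissues = tissues_single(),
                                      seq = "hr_gre_pd", noise_sd = 0)
  pair_pd <- two_point_separation(ep_pd)
  parts <- pectoral_cut_and_split(
    body_mask(volume_image(pair_pd$water$data + pair_pd$fat$data, ph$spacing_mm)),
    ph$chest_wall_plane_index)
  for (preset in c("hr_gre_pd", "hr_gre_t1")) {
    ep <- simulate_dixon_acquisition(ph, tissues = tissues_single(),
                                     seq = preset, noise_sd = 0)
    pair <- two_point_separation(ep)
    cf <- correction_factor(select_calibration_roi(pair, parts$L))
    sq <- sequence_preset(preset)
    # after echo-amplitude compensation both channels carry the in-phase
    # echo's decay, so c is the pure-species signal ratio at TE_in
    analytic <- species_signal(sq, 1, 296, 53, sq$te_in_ms) /
      species_signal(sq, 1, 1266, 58, sq$te_in_ms)
    expect_equal(cf$c, analytic, tolerance = 0.01)
  }
})

test_that("water-fraction arithmetic handles the limiting cases", {
  d <- c(2, 2, 2)
  m <- segmentation_mask(array(TRUE, d), c(1, 1, 1))
  # W = 0 -> WF = 0 ; F = 0 -> WF = 1 ; c = 2, W = 1, F = 2 -> 0.5
  wf0 <- water_fraction_map(make_pair(array(0, d), array(3, d)), 1, m)
  expect_true(all(wf0$data == 0))
  wf1 <- water_fraction_map(make_pair(array(2, d), array(0, d)), 1, m)
  expect_true(all(wf1$data == 1))
  wf5 <- water_fraction_map(make_pair(array(1, d), array(2, d)), 2, m)
  expect_equal(as.numeric(wf5$data), rep(0.5, 8))
  # degenerate voxels are zeroed and counted
  wfd <- water_fraction_map(make_pair(array(0, d), array(0, d)), 1, m)
  expect_identical(attr(wfd, "degenerate_voxels"), 8L)
  expect_true(all(wfd$data == 0))
})

test_that("water fraction is monotone in c and scale invariant", {
  set.seed(41)
  d <- c(4, 4, 2)
  w <- array(runif(prod(d), 0.1, 1), d); f <- array(runif(prod(d), 0.1, 1), d)
  m <- segmentation_mask(array(TRUE, d), c(1, 1, 1))
  cs <- c(0.5, 1, 1.5, 2.5)
  maps <- lapply(cs, function(cc) water_fraction_map(make_pair(w, f), cc, m)$data)
  for (i in seq_len(length(cs) - 1))
    expect_true(all(maps[[i + 1]] > maps[[i]]))
  # multiplying both images by k > 0 changes nothing
  wfk <- water_fraction_map(make_pair(7.3 * w, 7.3 * f), 1.5, m)$data
  expect_equal(wfk, maps[[3]], tolerance = 1e-12)
})

test_that("FGT summary matches constant-field arithmetic and a brute-force sum", {
  d <- c(10, 10, 10)
  m <- segmentation_mask(array(TRUE, d), c(1, 1, 1))
  wf1 <- water_fraction_map(make_pair(array(1, d), array(0, d)), 1, m)
  s1 <- fgt_summary(wf1, m)
  expect_equal(s1$fgt_cm3, 1.000, tolerance = 1e-12)
  expect_equal(s1$pct_fgt, 100)
  # WF = 0.364 everywhere -> 36.4 %FGT
  wfc <- water_fraction_map(make_pair(array(0.364, d), array(0.636, d)), 1, m)
  expect_equal(fgt_summary(wfc, m)$pct_fgt, 36.4, tolerance = 1e-9)
  # random field vs voxel-list summation oracle
  set.seed(42)
  w <- array(runif(prod(d)), d); f <- array(runif(prod(d)), d)
  mask <- array(runif(prod(d)) > 0.4, d)
  mobj <- segmentation_mask(mask, c(1.3, 1.3, 1.0))
  wf <- water_fraction_map(make_pair(w, f, c(1.3, 1.3, 1.0)), 1.2, mobj)
  acc <- 0
  for (i in which(mask)) acc <- acc + 1.2 * w[i] / (1.2 * w[i] + f[i])
  expect_equal(fgt_summary(wf, mobj)$fgt_cm3,
               acc * 1.3 * 1.3 * 1.0 / 1000, tolerance = 1e-10)
  expect_error(fgt_summary(wf, segmentation_mask(array(FALSE, d), c(1, 1, 1))),
               "empty mask")
})

test_that("correction-factor sensitivity matches closed-form and recompute oracles", {
  d <- c(6, 6, 4)
  m <- segmentation_mask(array(TRUE, d), c(1, 1, 1))
  # uniform voxels with c = 1, W = F: +15% takes WF from 0.5 to 1.15/2.15
  pair <- make_pair(array(1, d), array(1, d))
  s <- sensitivity(pair, m, 1, 0.15)
  expect_equal(s$pct_fgt, 50, tolerance = 1e-9)
  expect_equal(s$delta_plus, 100 * (1.15 / 2.15) - 50, tolerance = 1e-9)
  expect_equal(s$delta_minus, 100 * (0.85 / 1.85) - 50, tolerance = 1e-9)
  # delta = 0 is a no-op
  s0 <- sensitivity(pair, m, 1, 0)
  expect_equal(s0$delta_plus, 0); expect_equal(s0$delta_minus, 0)
  # mixed voxels: positive then negative deltas, equal to recompute-from-scratch
  set.seed(43)
  w <- array(runif(prod(d), 0.05, 1), d); f <- array(runif(prod(d), 0.05, 1), d)
  pr <- make_pair(w, f)
  sr <- sensitivity(pr, m, 1.3, 0.15)
  expect_gt(sr$delta_plus, 0); expect_lt(sr$delta_minus, 0)
  manual <- function(cc) {
    wf <- 0
    for (i in seq_len(prod(d))) wf <- wf + cc * w[i] / (cc * w[i] + f[i])
    100 * wf / prod(d)
  }
  expect_equal(sr$pct_fgt_plus, manual(1.3 * 1.15), tolerance = 1e-9)
  expect_equal(sr$pct_fgt_minus, manual(1.3 * 0.85), tolerance = 1e-9)
})
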