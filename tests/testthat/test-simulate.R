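test_that("spoiled gradient-echo signal approaches proton density in the saturation limit", {
  sq <- sequence_params("GRE_SPGR", tr_ms = 1e7, te_in_ms = 4.77, te_out_ms = 2.39,
                        flip_angle_deg = 90)
  expect_equal(species_signal(sq, pd = 0.83, t1_ms = 1000, t2_ms = 1e9,
                              te_ms = 1e-9), 0.83, tolerance = 1e-6)
  expect_error(species_signal(sq, 1, -5, 50, 4.77), "positive")
})

test_that("a pure-water phantom gives equal echo magnitudes for the spin-echo preset", {
  ph <- small_phantom(composition = list(type = "uniform", fraction = 1))
  ep <- simulate_dixon_acquisition(ph, seq = "lr_se_t1", noise_sd = 0)
  breast <- ph$labels %in% 1:2  # the chest wall slab carries a fat component
  expect_equal(Mod(ep$in_phase$data[breast]), Mod(ep$out_of_phase$data[breast]),
               tolerance = 1e-12)
})

test_that("a 50/50 voxel cancels exactly at the opposed echo when species match", {
  # equal relaxation and proton density for both species, single fat peak,
  # opposed evolution time exactly half the fat-water period
  tis <- tissue_properties(water_t1_ms = 800, fat_t1_ms = 800,
                           water_t2_ms = 60, fat_t2_ms = 60,
                           fat_spectrum = fat_spectrum_single_peak())
  sq <- sequence_params("GRE_SPGR", tr_ms = 7.34, te_in_ms = 4.77,
                        te_out_ms = 4.77 / 2, flip_angle_deg = 4)
  ph <- small_phantom(composition = list(type = "uniform", fraction = 0.5))
  ep <- simulate_dixon_acquisition(ph, tissues = tis, seq = sq, noise_sd = 0)
  breast <- ph$labels %in% 1:2
  expect_lt(max(Mod(ep$out_of_phase$data[breast])), 1e-12)
  expect_gt(min(Mod(ep$in_phase$data[breast])), 0)
})

test_that("simulation is bit-deterministic given the seed", {
  ph <- small_phantom(noise_sd = 0.05)
  a <- simulate_dixon_acquisition(ph, seq = "hr_gre_pd", rng_seed = 7)
  b <- simulate_dixon_acquisition(ph, seq = "hr_gre_pd", rng_seed = 7)
  expect_identical(a$in_phase$data, b$in_phase$data)
  expect_identical(a$out_of_phase$data, b$out_of_phase$data)
  c <- simulate_dixon_acquisition(ph, seq = "hr_gre_pd", rng_seed = 8)
  expect_false(identical(a$in_phase$data, c$in_phase$data))
})

test_that("multi-peak fat raises the apparent water share more for spin echo than gradient echo", {
  ph <- small_phantom(composition = list(type = "uniform", fraction = 0))  # all fat
  breast <- ph$labels %in% 1:2
  apparent_wf <- function(preset) {
    ep <- simulate_dixon_acquisition(ph, tissues = tissues_multi(), seq = preset,
                                     noise_sd = 0)
    pair <- two_point_separation(ep)
    w <- pair$water$data[breast]; f <- pair$fat$data[breast]
    mean(w / (w + f))
  }
  wf_se <- apparent_wf("lr_se_t1")
  wf_gre <- apparent_wf("hr_gre_pd")
  expect_gt(wf_se, wf_gre)
  expect_gt(wf_se, 0.05)   # the spin-echo fat leak is substantial
  expect_lt(wf_gre, 0.05)  # the gradient-echo leak is modest
})

test_that("sequence presets carry the protocol parameters", {
  pd <- sequence_preset("hr_gre_pd")
  expect_equal(pd$tr_ms, 7.34); expect_equal(pd$te_in_ms, 4.77)
  expect_equal(pd$te_out_ms, 2.39); expect_equal(pd$flip_angle_deg, 4)
  t1 <- sequence_preset("hr_gre_t1")
  expect_equal(t1$flip_angle_deg, 25)
  se <- sequence_preset("lr_se_t1")
  expect_equal(se$tr_ms, 500); expect_equal(se$te_in_ms, 12)
  expect_equal(se$echo_train_length, 8); expect_equal(se$echo_spacing_ms, 12.2)
  expect_equal(se$acq_spacing_mm, c(0.8, 0.8, 7.0))
  expect_error(sequence_params("GRE_SPGR", tr_ms = 7, te_in_ms = 4, te_out_ms = 4,
                               flip_angle_deg = 5), "differ")
})

test_that("the fat spectrum validates and its phasor has unit modulus at tau 0", {
  sp6 <- fat_spectrum_six_peak()
  expect_equal(sum(sp6$amp), 1, tolerance = 1e-12)
  expect_equal(Mod(fat_phasor(sp6, 0)), 1, tolerance = 1e-12)
  expect_lt(Mod(fat_phasor(sp6, 4.77)), 1)
  expect_error(tissue_properties(fat_spectrum = data.frame(freq_hz = 0, amp = 0.5)),
               "sum to 1")
})

test_that("noise makes magnitudes Rician: background magnitude is positive", {
  ph <- small_phantom(noise_sd = 0.05)
  ep <- simulate_dixon_acquisition(ph, seq = "hr_gre_pd", rng_seed = 11)
  bg <- ph$labels == 0
  expect_true(all(Mod(ep$in_phase$data[bg]) > 0))
  expect_gt(ep$noise_sd_abs, 0)
})

test_that("a polynomial bias field modulates the signal smoothly", {
  d <- c(8L, 8L, 8L)
  b <- evaluate_bias_field(list(gx = 0.2), d)
  expect_equal(b[1, 1, 1], 0.8, tolerance = 1e-12)
  expect_equal(b[8, 1, 1], 1.2, tolerance = 1e-12)
  expect_equal(evaluate_bias_field("none", d), array(1, dim = d))
})
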