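test_that("trajectory generator is exact when noiseless and seed-reproducible", {
  sig <- list(L1 = 5.56, L2 = 5.61, t0 = 30, tau_s = 28.33)
  expo <- list(a = 5.93, k = 22.92)
  tr0 <- gen_trajectory(sig, expo, noise_sd = 0, seed = 1)
  expect_equal(tr0$d_pp_um,
               sigmoid_val(tr0$t_s, sig$L1, sig$L2, sig$t0, sig$tau_s),
               tolerance = 1e-12)
  expect_equal(tr0$d_cc_um, exp_val(tr0$t_s, expo$a, expo$k), tolerance = 1e-12)

  a <- gen_trajectory(sig, expo, noise_sd = 0.3, seed = 99)
  b <- gen_trajectory(sig, expo, noise_sd = 0.3, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, gen_trajectory(sig, expo, noise_sd = 0.3, seed = 100)))
  expect_error(gen_trajectory(sig, expo, noise_sd = -1, seed = 1), "noise_sd")

  # noisy fit round trip at the stated recovery tolerances
  fit <- fit_sigmoid(gen_trajectory(sig, expo, noise_sd = 0.2, seed = 12))
  expect_equal(fit$flpp, 11.17, tolerance = 0.05)
})

test_that("atlas reproduces the scaling dichotomy it was generated with", {
  atlas <- gen_atlas(seed = 2024)
  expect_equal(nrow(atlas$cells), 600)
  # 2-cell volumes sit at the 23-um scale used for the reference stages
  expect_equal(mean(atlas$cells$size_um[atlas$cells$stage == 2]), 22.9,
               tolerance = 0.02)

  cells <- quantify_cells(atlas$trajectories,
                          meta = atlas$cells[, c("cell_id", "volume_um3")])
  summ <- stage_summary(cells)
  spindle <- scaling_regression(summ, size_um, flpp_um_mean)
  chrom <- scaling_regression(summ, size_um, flcc_um_mean)

  # strong spindle scaling, weak chromosome scaling, each within 2 SD of its
  # generating exponent, and the spindle interval excludes the chromosome one
  expect_lt(abs(spindle$slope - 0.75), 2 * spindle$slope_sd + 0.02)
  expect_lt(abs(chrom$slope - 0.09), 2 * chrom$slope_sd + 0.02)
  expect_gt(spindle$conf_int[1], 0.09)

  # elongation-rate transition near the generating 12-um break
  pw <- piecewise_transition(cells, size_um, erpp_um_min)
  expect_equal(pw$breakpoint, 12, tolerance = 1.5)

  # null chromosome exponent is recovered as flat
  atlas0 <- gen_atlas(stages = c(2, 8, 64), cells_per_stage = 30,
                      chromosome_exponent = 0, seed = 5)
  cells0 <- quantify_cells(atlas0$trajectories,
                           meta = atlas0$cells[, c("cell_id", "volume_um3")])
  chrom0 <- scaling_regression(stage_summary(cells0), size_um, flcc_um_mean)
  expect_lt(abs(chrom0$slope), 2 * chrom0$slope_sd + 0.02)

  expect_error(gen_atlas(stages = integer(0), seed = 1), "stages")
  expect_identical(gen_atlas(stages = 8, cells_per_stage = 3, seed = 7),
                   gen_atlas(stages = 8, cells_per_stage = 3, seed = 7))
})

test_that("kymograph generator respects the field of view and its seed", {
  sig <- list(L1 = 5.56, L2 = 5.61, t0 = 30, tau_s = 28.33)
  expo <- list(a = 5.93, k = 22.92)
  tracks <- gen_kymo_tracks(sig, expo, n_frames = 8, center_um = 6.4)
  a <- gen_kymograph(tracks, snr = 10, seed = 3)
  b <- gen_kymograph(tracks, snr = 10, seed = 3)
  expect_identical(a$poles$intensity, b$poles$intensity)
  expect_true(all(a$poles$intensity >= 0))

  wide <- gen_kymo_tracks(list(L1 = 20, L2 = 10, t0 = 30, tau_s = 20),
                          expo, n_frames = 8, center_um = 6.4)
  expect_error(gen_kymograph(wide, n_px = 128, seed = 1), "field of view")
})

test_that("ablation and microtubule generators are pure functions of the seed", {
  expect_identical(gen_ablation(n_records = 3, seed = 8),
                   gen_ablation(n_records = 3, seed = 8))
  s1 <- gen_mt_set(n_interpolar = 10, n_mid = 5, n_other = 2, seed = 31)
  s2 <- gen_mt_set(n_interpolar = 10, n_mid = 5, n_other = 2, seed = 31)
  expect_identical(s1$traces, s2$traces)
})
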