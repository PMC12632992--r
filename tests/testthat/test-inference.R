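# inference tests run the simulator at reduced resolution (128-patch mesh,
# short horizons) to keep differential evolution affordable

test_that("the trajectory error is zero against a self-generated target", {
  target <- simulate_spindle(stage64(), n_patches = 128, t_end = 150)
  err <- trajectory_error(0.945, target, stage64(), n_patches = 128)
  expect_lt(err, 1e-4)
})

test_that("a constant offset contributes its closed-form sum of squares", {
  target <- simulate_spindle(stage64(), n_patches = 128, t_end = 150)
  target <- target[1:10, ]
  shifted <- dplyr::mutate(target, d_pp_um = d_pp_um + 0.1)
  err <- trajectory_error(0.945, shifted, stage64(), n_patches = 128)
  expect_equal(err, 10 * 0.01, tolerance = 1e-3)
})

test_that("the error profile has its minimum at the generating rate", {
  target <- simulate_spindle(stage64(), n_patches = 128, t_end = 150)
  grid <- c(0.75, 0.85, 0.945, 1.05, 1.1)
  errs <- vapply(grid, trajectory_error, numeric(1),
                 target = target, stage = stage64(), n_patches = 128,
                 t_end = 150)
  expect_equal(grid[which.min(errs)], 0.945)
})

test_that("target times beyond the simulated horizon are rejected", {
  target <- tibble::tibble(t_s = c(0, 500), d_pp_um = c(5.4, 10))
  expect_error(trajectory_error(0.5, target, stage64(), t_end = 300), "t_end")
})

test_that("differential evolution is deterministic given its seed and respects bounds", {
  target <- simulate_spindle(stage64(), n_patches = 128, t_end = 100)
  de <- de_config(population_size = 6, max_generations = 2, seed = 5)
  f1 <- fit_catastrophe_rate(target, stage64(), de = de, n_patches = 128,
                             refine_n_patches = 128)
  f2 <- fit_catastrophe_rate(target, stage64(), de = de, n_patches = 128,
                             refine_n_patches = 128)
  expect_identical(f1$lambda_hat, f2$lambda_hat)
  expect_gte(f1$lambda_hat, 0.001)
  expect_lte(f1$lambda_hat, 10)
  expect_gte(f1$error, 0)

  expect_error(de_config(population_size = 2, seed = 1))
  expect_error(de_config(bounds = c(0.0001, 10), seed = 1))
  expect_error(de_config(population_size = 10))
})

test_that("the optimizer is not beaten by the truth beyond interpolation error", {
  target <- simulate_spindle(stage64(), n_patches = 128, dt = 0.0125, t_end = 62)
  de <- de_config(population_size = 12, max_generations = 20,
                  bounds = c(0.001, 2), seed = 7)
  fit <- fit_catastrophe_rate(target, stage64(), de = de, n_patches = 128,
                              dt = 0.0125, refine_n_patches = 128,
                              refine_dt = 0.0125)
  err_truth <- trajectory_error(0.945, target, stage64(), n_patches = 128,
                                dt = 0.0125, t_end = 62)
  expect_lte(fit$error, err_truth + 1e-3)
})

test_that("each reference stage's catastrophe rate is recovered within 10%", {
  # scaled-down inference: 128-patch mesh, per-stage time steps at the
  # stability guard's margin (larger cells tolerate larger steps), horizons
  # covering each stage's elongation rise, and a catastrophe-rate search
  # interval plausible for astral microtubules
  st <- celegans_stages()
  dts <- c(0.1, 0.1, 0.05, 0.02, 0.02, 0.0125)
  tends <- c(155, 155, 124, 103, 82, 62)
  lam_hat <- vapply(seq_len(6), function(i) {
    target <- simulate_spindle(st[i, ], n_patches = 128, dt = dts[i],
                               t_end = tends[i])
    de <- de_config(population_size = 12, max_generations = 20,
                    bounds = c(0.001, 2), seed = 2026 + i)
    fit_catastrophe_rate(target, st[i, ], de = de, n_patches = 128,
                         dt = dts[i], refine_n_patches = 128,
                         refine_dt = dts[i])$lambda_hat
  }, numeric(1))
  expect_true(all(abs(lam_hat - st$lambda_s) / st$lambda_s < 0.10))
  # recovered sequence increases from the 2- to the 64-cell stage
  expect_true(all(diff(lam_hat) > 0))
})

test_that("batch inference labels stages and is order-independent", {
  st <- celegans_stages()
  targets <- list(
    "8" = simulate_spindle(st[3, ], n_patches = 128, t_end = 100),
    "64" = simulate_spindle(st[6, ], n_patches = 128, t_end = 100)
  )
  de <- de_config(population_size = 5, max_generations = 2, seed = 3)
  tab <- fit_all_stages(targets, de = de, n_patches = 128,
                        refine_n_patches = 128)
  expect_equal(tab$stage, c(8L, 64L))
  expect_equal(tab$cell_radius_um, c(14, 7.3))

  single <- fit_all_stages(targets["64"], de = de, n_patches = 128,
                           refine_n_patches = 128)
  expect_equal(nrow(single), 1)

  rev_tab <- fit_all_stages(rev(targets), de = de, n_patches = 128,
                            refine_n_patches = 128)
  expect_equal(rev_tab[order(rev_tab$stage), ]$lambda_hat,
               tab[order(tab$stage), ]$lambda_hat)

  expect_error(fit_all_stages(list("3" = targets[[1]]), de = de), "stage 3")
})
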