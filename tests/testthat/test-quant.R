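test_that("cell size is the cube root of volume", {
  expect_equal(cell_size_from_volume(1000), 10)
  expect_equal(cell_size_from_volume(12167), 23)
  expect_equal(cell_size_from_volume(8), 2)
  expect_error(cell_size_from_volume(0), "positive")
  expect_error(cell_size_from_volume(-5), "positive")
})

test_that("scaling regression recovers exact power laws", {
  sizes <- c(7.3, 9, 11, 14, 18, 23)
  d <- data.frame(size = sizes, len = sizes^0.75)
  # exact power law: lm warns about a perfect fit, which is the point here
  fit <- suppressWarnings(scaling_regression(d, size, len))
  expect_equal(fit$slope, 0.75, tolerance = 1e-10)
  expect_lt(fit$slope_sd, 1e-10)
  expect_true(fit$conf_int[1] <= fit$slope && fit$slope <= fit$conf_int[2])

  d$flat <- rep(6.2, 6)
  expect_equal(suppressWarnings(scaling_regression(d, size, flat))$slope, 0,
               tolerance = 1e-12)

  expect_error(scaling_regression(d[1:2, ], size, len), "3")
  lin <- suppressWarnings(scaling_regression(d, size, len, convention = "linear"))
  expect_identical(lin$convention, "linear")
})

test_that("piecewise fit recovers an exact 12-um breakpoint", {
  sizes <- c(6, 7.5, 8.5, 10, 11, 13, 15, 18, 21, 23)
  rates <- ifelse(sizes >= 12, 3, 3 + 0.25 * (sizes - 12))
  fit <- piecewise_transition(data.frame(s = sizes, r = rates), s, r)
  expect_equal(fit$breakpoint, 12, tolerance = 0.01)
  expect_equal(fit$plateau, 3, tolerance = 1e-6)
  expect_equal(fit$slope_below, 0.25, tolerance = 1e-4)
  expect_false(fit$degenerate)
})

test_that("flat rate data is flagged degenerate", {
  d <- data.frame(s = seq(6, 23, length.out = 10), r = rep(3, 10))
  fit <- piecewise_transition(d, s, r)
  expect_true(fit$degenerate)
  expect_equal(fit$slope_below, 0, tolerance = 1e-8)
})

test_that("breakpoint recovery is robust to noise", {
  err <- withr::with_seed(11, {
    vapply(1:50, function(i) {
      sizes <- runif(30, 6, 23)
      rates <- ifelse(sizes >= 12, 3, 3 * sizes / 12) + rnorm(30, 0, 0.3)
      fit <- piecewise_transition(data.frame(s = sizes, r = rates), s, r)
      fit$breakpoint - 12
    }, numeric(1))
  })
  expect_lt(mean(abs(err)), 1.5)
})

test_that("one-way F statistic matches the hand example and the aov oracle", {
  expect_equal(as.numeric(anova_f(list(c(1, 2, 3), c(2, 3, 4)))), 1.5)
  expect_equal(as.numeric(anova_f(list(c(2, 5, 9), c(2, 5, 9)))), 0)

  withr::with_seed(3, {
    for (rep in 1:10) {
      groups <- lapply(sample(3:6, 3, replace = TRUE),
                       function(n) rnorm(n, mean = runif(1, 0, 3)))
      f <- anova_f(groups)
      dat <- data.frame(y = unlist(groups),
                        g = factor(rep(seq_along(groups),
                                       vapply(groups, length, integer(1)))))
      oracle <- summary(stats::aov(y ~ g, data = dat))[[1]]$`F value`[1]
      expect_equal(as.numeric(f), oracle, tolerance = 1e-10)
      expect_equal(unname(attr(f, "df")),
                   summary(stats::aov(y ~ g, data = dat))[[1]]$Df)
    }
  })

  expect_identical(as.numeric(anova_f(list(c(1, 1), c(2, 2)))), Inf)
  expect_error(anova_f(list(c(1, 2))), "2")
})

test_that("stage averaging interpolates to a common grid", {
  t <- seq(0, 103, by = 10.3)
  traj <- dplyr::bind_rows(
    tibble::tibble(cell_id = "a", t_s = t, d_pp_um = rep(4, length(t))),
    tibble::tibble(cell_id = "b", t_s = t, d_pp_um = rep(6, length(t)))
  )
  avg <- stage_average(traj)
  expect_true(all(avg$mean == 5))
  expect_true(all(abs(avg$sd - sqrt(2)) < 1e-12))
  expect_true(all(avg$n_cells == 2))

  # identical trajectories: mean equals input, sd 0
  one <- tibble::tibble(cell_id = "a", t_s = t, d_pp_um = sin(t / 30) + 2)
  avg1 <- stage_average(dplyr::bind_rows(one, dplyr::mutate(one, cell_id = "b")))
  expect_equal(avg1$mean, one$d_pp_um)
  expect_true(all(avg1$sd == 0))

  # the grid covers only the overlapping range
  short <- dplyr::filter(one, t_s <= 60)
  avg2 <- stage_average(dplyr::bind_rows(one, dplyr::mutate(short, cell_id = "b")))
  expect_lte(max(avg2$t_s), 60)
  expect_error(stage_average(tibble::tibble(cell_id = character(),
                                            t_s = numeric(),
                                            d_pp_um = numeric())))
})

test_that("per-cell quantification joins sizes and feeds stage summaries", {
  atlas <- gen_atlas(stages = c(8, 32), cells_per_stage = 4, noise_sd = 0.05,
                     seed = 5)
  cells <- quantify_cells(atlas$trajectories,
                          meta = atlas$cells[, c("cell_id", "volume_um3")])
  expect_equal(nrow(cells), 8)
  expect_true(all(c("flpp_um", "erpp_um_min", "flcc_um", "srcc_um_min",
                    "size_um") %in% names(cells)))
  expect_true(all(cells$sigmoid_ok))
  summ <- stage_summary(cells)
  expect_equal(summ$stage, c(8, 32))
  expect_true(all(summ$flpp_um_sd >= 0))
})
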