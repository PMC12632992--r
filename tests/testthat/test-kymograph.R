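make_profile <- function(centers, n = 100, a = 100, c = 3, d = 10) {
  x <- seq(0, n - 1)
  d + Reduce(`+`, lapply(centers, function(b) a * exp(-((x - b) / c)^2)))
}

test_that("the two most prominent peaks are detected", {
  p <- make_profile(c(20, 80))
  centers <- detect_pole_peaks(p)
  expect_false(attr(centers, "flagged"))
  expect_equal(as.numeric(centers), c(20, 80), tolerance = 1)

  # a faint third peak is ignored
  p3 <- make_profile(c(20, 80)) + 20 * exp(-((seq(0, 99) - 50) / 3)^2)
  centers3 <- detect_pole_peaks(p3)
  expect_equal(as.numeric(centers3), c(20, 80), tolerance = 1)

  flat <- rep(5, 64)
  expect_true(attr(detect_pole_peaks(flat), "flagged"))
  expect_error(detect_pole_peaks(p[1:10]), "16")
})

test_that("gaussian refinement recovers sub-pixel centers", {
  x <- seq(0, 49)
  y <- 100 * exp(-((x - 25.4) / 3)^2) + 10
  fit <- refine_peak_gaussian(y, 25, window = 6)
  expect_false(fit$flagged)
  expect_equal(fit$b, 25.4, tolerance = 1e-6)
  expect_equal(fit$a, 100, tolerance = 1e-5)

  # window clipped at the profile edge still fits, flagged as clipped
  y_edge <- 100 * exp(-((x - 3) / 3)^2) + 10
  fit_edge <- refine_peak_gaussian(y_edge, 3, window = 6)
  expect_true(fit_edge$clipped)
})

test_that("refined centers stay accurate under Poisson-like noise", {
  errs <- withr::with_seed(21, {
    vapply(1:100, function(i) {
      x <- seq(0, 49)
      mu <- 100 * exp(-((x - 25.4) / 3)^2) + 10
      y <- pmax(mu + rnorm(50, 0, sqrt(mu * 100) / 10), 0)  # SNR 10 at the peak
      refine_peak_gaussian(y, 25, window = 8)$b - 25.4
    }, numeric(1))
  })
  expect_lt(median(abs(errs)), 0.1)
})

test_that("track extraction round-trips a synthetic kymograph", {
  sig <- list(L1 = 5.56, L2 = 5.61, t0 = 30, tau_s = 28.33)
  expo <- list(a = 5.93, k = 22.92)
  tracks <- gen_kymo_tracks(sig, expo, n_frames = 18, center_um = 6.4)
  kym <- gen_kymograph(tracks, n_px = 128, snr = Inf, seed = 1)
  out <- extract_tracks(kym$poles, kym$chromosomes)
  expect_equal(nrow(out), 18)
  expect_true(all(!out$flagged))
  d_pp_true <- tracks$pole2_um - tracks$pole1_um
  expect_lt(max(abs(out$d_pp_um - d_pp_true)), 0.05 * 0.1) # 0.05 px
  d_cc_true <- tracks$chrom2_um - tracks$chrom1_um
  # frames with clearly separated plates must match the generating track
  sep <- d_cc_true > 1
  expect_lt(max(abs(out$d_cc_um[sep] - d_cc_true[sep])), 0.05)

  # full round trip through the trajectory fits at SNR 10
  noisy <- gen_kymograph(tracks, n_px = 128, snr = 10, seed = 33)
  outn <- extract_tracks(noisy$poles, noisy$chromosomes)
  expect_lt(sqrt(mean((outn$d_pp_um - d_pp_true)^2, na.rm = TRUE)), 0.1)
  fit <- fit_sigmoid(outn)
  expect_equal(fit$flpp, sig$L1 + sig$L2, tolerance = 0.03)
  fite <- fit_exponential(outn)
  expect_equal(fite$flcc, expo$a, tolerance = 0.03)
})

test_that("corrupted frames are flagged, never fabricated", {
  sig <- list(L1 = 5.56, L2 = 5.61, t0 = 30, tau_s = 28.33)
  expo <- list(a = 5.93, k = 22.92)
  tracks <- gen_kymo_tracks(sig, expo, n_frames = 6, center_um = 6.4)
  kym <- gen_kymograph(tracks, n_px = 128, snr = Inf, seed = 1)
  kym$poles$intensity[3, ] <- 10  # flat pole frame: no detectable peaks
  out <- extract_tracks(kym$poles, kym$chromosomes)
  expect_true(out$flagged[3])
  expect_true(is.na(out$d_pp_um[3]))
  expect_false(any(out$flagged[-3]))

  # single-frame kymograph yields a single-row trajectory
  one <- extract_tracks(
    kymograph(kym$poles$intensity[1, , drop = FALSE], "poles"),
    kymograph(kym$chromosomes$intensity[1, , drop = FALSE], "chromosomes"))
  expect_equal(nrow(one), 1)

  expect_error(extract_tracks(kym$poles,
                              kymograph(kym$chromosomes$intensity, "chromosomes",
                                        pixel_um = 0.2)),
               "calibration")
})

test_that("anisotropic voxel distances follow the calibrated euclidean form", {
  expect_equal(euclidean_distance(c(10, 10, 5), c(13, 14, 5)), 0.5)
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(1, 2, 3), c(4, 0, 1)),
               euclidean_distance(c(4, 0, 1), c(1, 2, 3)))
  expect_error(euclidean_distance(c(1, NA, 3), c(0, 0, 0)), "finite")
})

test_that("anaphase onset is the last frame before a sustained rise", {
  series <- c(rep(0.1, 12), rep(4, 8))        # rise at frame 12 (0-based)
  expect_identical(as.integer(detect_anaphase_onset(series)), 11L)

  flat <- rep(0.3, 20)
  expect_true(attr(detect_anaphase_onset(flat), "flagged"))

  early <- c(0.1, rep(4, 7))                  # separation right at the start
  expect_identical(as.integer(detect_anaphase_onset(early)), 0L)
})
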