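#' Synthetic single-cell trajectory
#'
#' Samples a sigmoid pole-to-pole trace and an exponential
#' chromosome-to-chromosome trace at the acquisition interval, with additive
#' i.i.d. Gaussian measurement noise. Chromosome separation is exactly zero
#' before anaphase onset (t < 0). Pure function of its arguments and the
#' seed.
#'
#' @param sigmoid Named list `L1`, `L2`, `t0`, `tau_s` (um, um, s, s).
#' @param expo Named list `a`, `k` (um, s).
#' @param noise_sd Measurement noise SD (um); >= 0. Default 0.2.
#' @param t_start,t_end,interval Sampling grid (s). Defaults 0, 250, 10.3.
#' @param seed Mandatory integer seed.
#' @param cell_id,stage,lineage Metadata stamped on the rows.
#'
#' @return Trajectory tibble (shared schema).
#' @export
gen_trajectory <- function(sigmoid, expo, noise_sd = 0.2,
                           t_start = 0, t_end = 250, interval = 10.3,
                           seed, cell_id = "synth", stage = NA_integer_,
                           lineage = NA_character_) {
  stopifnot(all(c("L1", "L2", "t0", "tau_s") %in% names(sigmoid)),
            all(c("a", "k") %in% names(expo)))
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (missing(seed)) abort("`seed` is mandatory.")
  t <- seq(t_start, t_end, by = interval)
  withr::with_seed(seed, {
    d_pp <- sigmoid$L1 + sigmoid$L2 / (1 + exp(-(t - sigmoid$t0) / sigmoid$tau_s)) +
      rnorm(length(t), 0, noise_sd)
    d_cc <- ifelse(t < 0, 0,
                   expo$a * (1 - exp(-pmax(t, 0) / expo$k)) +
                     rnorm(length(t), 0, noise_sd) * (t >= 0))
    tibble::tibble(cell_id = cell_id, stage = stage, lineage = lineage,
                   t_s = t, d_pp_um = pmax(d_pp, 0), d_cc_um = pmax(d_cc, 0),
                   d_pc_um = pmax((d_pp - d_cc) / 2, 0))
  })
}

#' Synthetic developmental atlas of spindle trajectories
#'
#' Emulates the statistical structure of a lineage-resolved spindle atlas:
#' cell volumes halve at each division of an ellipsoidal embryo
#' (length x width x width), final spindle length follows a strong power law
#' of cell size while chromosome dynamics follow a weak one, and the
#' elongation rate is flat above a transition size and declines linearly
#' below it. Anchors: final spindle length 11.17 um and final chromosome
#' separation 6.2 um at the 14-um (8-cell) scale; elongation-rate plateau
#' 2.97 um/min.
#'
#' @param stages Subset of `c(2, 4, 8, 16, 32, 64)`.
#' @param cells_per_stage Cells simulated per stage. Default 100.
#' @param embryo_length_um,embryo_width_um Ellipsoid axes (um). Defaults 51
#'   (wild-type length; use 62 or 37 for the size-perturbed conditions) and
#'   30.
#' @param spindle_exponent Power-law exponent of final spindle length vs cell
#'   size. Default 0.75.
#' @param chromosome_exponent Exponent of final chromosome separation vs cell
#'   size. Default 0.09.
#' @param law [chromosome_law()] supplying the chromosome time constant.
#' @param transition_size_um Cell size below which the elongation rate
#'   declines. Default 12.
#' @param erpp_plateau Elongation-rate plateau (um/min). Default 2.97.
#' @param noise_sd Measurement noise SD on distances (um). Default 0.2.
#' @param param_cv Cell-to-cell coefficient of variation on volumes and fit
#'   parameters. Default 0.05.
#' @param interval,t_end Sampling grid (s). Defaults 10.3 and 250.
#' @param seed Mandatory integer seed.
#'
#' @return List with `trajectories` (bound trajectory tibble) and `cells`
#'   (per-cell metadata: `cell_id`, `stage`, `lineage`, `volume_um3`,
#'   `size_um`, and the generating `flpp_true`, `erpp_true`, `flcc_true`).
#' @export
gen_atlas <- function(stages = c(2, 4, 8, 16, 32, 64), cells_per_stage = 100,
                      embryo_length_um = 51, embryo_width_um = 30,
                      spindle_exponent = 0.75, chromosome_exponent = 0.09,
                      law = chromosome_law(), transition_size_um = 12,
                      erpp_plateau = 2.97, noise_sd = 0.2, param_cv = 0.05,
                      interval = 10.3, t_end = 250, seed) {
  if (length(stages) == 0) abort("`stages` must not be empty.")
  stopifnot(all(stages %in% c(2, 4, 8, 16, 32, 64)), cells_per_stage >= 1,
            noise_sd >= 0)
  if (missing(seed)) abort("`seed` is mandatory.")
  size_ref <- 14    # 8-cell scale, where the anchors are defined
  flpp_ref <- 11.17
  flcc_ref <- law$c_f

  embryo_vol <- (4 / 3) * pi * (embryo_length_um / 2) * (embryo_width_um / 2)^2

  withr::with_seed(seed, {
    cells <- purrr::map_dfr(stages, function(st) {
      vol <- (embryo_vol / st) * exp(rnorm(cells_per_stage, 0, param_cv))
      size <- cell_size_from_volume(vol)
      flpp <- flpp_ref * (size / size_ref)^spindle_exponent *
        exp(rnorm(cells_per_stage, 0, param_cv))
      erpp <- ifelse(size >= transition_size_um, erpp_plateau,
                     erpp_plateau * size / transition_size_um) *
        exp(rnorm(cells_per_stage, 0, param_cv))
      flcc <- flcc_ref * (size / size_ref)^chromosome_exponent *
        exp(rnorm(cells_per_stage, 0, param_cv))
      tibble::tibble(
        cell_id = sprintf("s%02d_c%03d", st, seq_len(cells_per_stage)),
        stage = st, lineage = NA_character_,
        volume_um3 = vol, size_um = size,
        flpp_true = flpp, erpp_true = erpp, flcc_true = flcc,
        k_true = law$tau_c * exp(rnorm(cells_per_stage, 0, param_cv))
      )
    })
    trajectories <- purrr::pmap_dfr(
      cells[, c("cell_id", "stage", "flpp_true", "erpp_true", "flcc_true", "k_true")],
      function(cell_id, stage, flpp_true, erpp_true, flcc_true, k_true) {
        L2 <- flpp_true / 2
        t <- seq(0, t_end, by = interval)
        tau_s <- (L2 / (4 * erpp_true)) * 60
        d_pp <- flpp_true - L2 + L2 / (1 + exp(-(t - 30) / tau_s)) +
          rnorm(length(t), 0, noise_sd)
        d_cc <- flcc_true * (1 - exp(-t / k_true)) + rnorm(length(t), 0, noise_sd)
        tibble::tibble(cell_id = cell_id, stage = stage,
                       lineage = NA_character_, t_s = t,
                       d_pp_um = pmax(d_pp, 0), d_cc_um = pmax(d_cc, 0),
                       d_pc_um = pmax((d_pp - d_cc) / 2, 0))
      })
    list(trajectories = trajectories, cells = cells)
  })
}

#' Synthetic two-channel kymograph pair
#'
#' Renders Gaussian peaks (`a * exp(-((x - b)/c)^2) + background`) at the
#' pole and chromosome positions of a per-frame track table, with
#' Poisson-like noise (variance proportional to the mean, scaled so the
#' peak-amplitude SNR equals `snr`).
#'
#' @param tracks Tibble with per-frame positions (um along the axis):
#'   `pole1_um`, `pole2_um`, `chrom1_um`, `chrom2_um`.
#' @param n_px Field of view width (pixels). Default 128.
#' @param pixel_um,frame_s Calibration. Defaults 0.1 um and 10.3 s.
#' @param width_px Gaussian width parameter c (px). Default 3.
#' @param amplitude,background Peak amplitude and offset. Defaults 100, 10.
#' @param snr Peak amplitude over noise SD at the peak; `Inf` for noiseless.
#' @param seed Mandatory integer seed.
#'
#' @return List with `poles` and `chromosomes` [kymograph()] objects.
#' @export
gen_kymograph <- function(tracks, n_px = 128, pixel_um = 0.1, frame_s = 10.3,
                          width_px = 3, amplitude = 100, background = 10,
                          snr = Inf, seed) {
  stopifnot(all(c("pole1_um", "pole2_um", "chrom1_um", "chrom2_um") %in% names(tracks)))
  if (missing(seed)) abort("`seed` is mandatory.")
  margin <- 2 * width_px * pixel_um
  pos <- as.matrix(tracks[, c("pole1_um", "pole2_um", "chrom1_um", "chrom2_um")])
  if (any(pos < margin) || any(pos > (n_px - 1) * pixel_um - margin)) {
    abort("track leaves the kymograph field of view; enlarge `n_px` or recenter the track.")
  }
  x <- seq(0, n_px - 1)
  render <- function(centers_um) {
    t(apply(centers_um, 1, function(b_um) {
      b <- b_um / pixel_um
      background +
        amplitude * exp(-((x - b[1]) / width_px)^2) +
        amplitude * exp(-((x - b[2]) / width_px)^2)
    }))
  }
  withr::with_seed(seed, {
    noisify <- function(img) {
      if (!is.finite(snr)) return(img)
      sdm <- sqrt(img * amplitude) / snr
      pmax(img + rnorm(length(img), 0, 1) * sdm, 0)
    }
    list(
      poles = kymograph(noisify(render(pos[, 1:2, drop = FALSE])),
                        "poles", pixel_um, frame_s),
      chromosomes = kymograph(noisify(render(pos[, 3:4, drop = FALSE])),
                              "chromosomes", pixel_um, frame_s)
    )
  })
}

#' Per-frame track table from trajectory fit parameters
#'
#' Convenience builder for [gen_kymograph()]: poles at
#' `center +/- sigmoid(t)/2`, chromosome plates at `center +/- expo(t)/2`.
#'
#' @inheritParams gen_trajectory
#' @param n_frames Number of frames.
#' @param frame_s Frame interval (s).
#' @param center_um Spindle center position in the field (um).
#' @return Tibble with `t_s`, `pole1_um`, `pole2_um`, `chrom1_um`,
#'   `chrom2_um`.
#' @export
gen_kymo_tracks <- function(sigmoid, expo, n_frames = 20, frame_s = 10.3,
                            center_um = 6.4) {
  t <- (seq_len(n_frames) - 1) * frame_s
  d_pp <- sigmoid$L1 + sigmoid$L2 / (1 + exp(-(t - sigmoid$t0) / sigmoid$tau_s))
  d_cc <- expo$a * (1 - exp(-t / expo$k))
  tibble::tibble(t_s = t,
                 pole1_um = center_um - d_pp / 2, pole2_um = center_um + d_pp / 2,
                 chrom1_um = center_um - d_cc / 2, chrom2_um = center_um + d_cc / 2)
}

#' Synthetic laser-ablation cohort
#'
#' Ablated records have a pole-to-pole separation velocity that jumps by
#' `pp_multiplier` at the ablation (t = 0) and reverts after `recovery_s`;
#' the chromosome-to-chromosome velocity is invariant (multiplied by
#' `cc_multiplier`, default 1, i.e. unaffected). Control records share the
#' pre-ablation slopes with no jump. Small Gaussian tracking noise is added
#' to all distances.
#'
#' @param n_records Ablated records (and as many controls). Default 20.
#' @param v_pp_pre Pre-ablation pole separation velocity (um/s). Default
#'   0.04.
#' @param v_cc_pre Chromosome separation velocity (um/s). Default 0.12.
#' @param pp_multiplier Post-ablation pole velocity multiplier. Default 1.4
#'   (a >30% elongation-rate increase).
#' @param cc_multiplier Post-ablation chromosome velocity multiplier.
#'   Default 1 (chromosome segregation unaffected).
#' @param recovery_s Time after which the pole velocity reverts (s). Default
#'   15.
#' @param times Sampling times (s; 0 = ablation). Default `seq(-10, 30)`.
#' @param noise_sd Tracking noise SD (um). Default 0.02.
#' @param jitter_cv Record-to-record CV on the velocities. Default 0.1.
#' @param seed Mandatory integer seed.
#'
#' @return Tibble with `record_id`, `condition` (`"ablated"`/`"control"`),
#'   `t_s`, `d_pp_um`, `d_pc_um`, `d_cc_um`.
#' @export
gen_ablation <- function(n_records = 20, v_pp_pre = 0.04, v_cc_pre = 0.12,
                         pp_multiplier = 1.4, cc_multiplier = 1,
                         recovery_s = 15, times = seq(-10, 30, by = 1),
                         noise_sd = 0.02, jitter_cv = 0.1, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  stopifnot(n_records >= 1, noise_sd >= 0)
  d_pp0 <- 8
  d_cc0 <- 2
  piecewise_dist <- function(d0, v, mult) {
    ifelse(times <= 0, d0 + v * times,
           ifelse(times <= recovery_s, d0 + v * mult * times,
                  d0 + v * mult * recovery_s + v * (times - recovery_s)))
  }
  withr::with_seed(seed, {
    one <- function(id, condition) {
      v_pp <- v_pp_pre * exp(rnorm(1, 0, jitter_cv))
      v_cc <- v_cc_pre * exp(rnorm(1, 0, jitter_cv))
      m_pp <- if (condition == "ablated") pp_multiplier else 1
      m_cc <- if (condition == "ablated") cc_multiplier else 1
      d_pp <- piecewise_dist(d_pp0, v_pp, m_pp) + rnorm(length(times), 0, noise_sd)
      d_cc <- piecewise_dist(d_cc0, v_cc, m_cc) + rnorm(length(times), 0, noise_sd)
      tibble::tibble(record_id = sprintf("%s_%02d", condition, id),
                     condition = condition, t_s = times,
                     d_pp_um = d_pp, d_pc_um = (d_pp - d_cc) / 2, d_cc_um = d_cc)
    }
    dplyr::bind_rows(
      purrr::map_dfr(seq_len(n_records), one, condition = "ablated"),
      purrr::map_dfr(seq_len(n_records), one, condition = "control")
    )
  })
}

#' Synthetic electron-tomography microtubule trace set
#'
#' Constructs straight 3-point traces with known class membership around a
#' spindle geometry: interpolar traces have one end inside the pole-proximal
#' ball, mid-spindle traces have both ends strictly between the
#' chromosome-plate planes and away from the poles, and "other" traces have
#' both ends beyond the plates and away from the poles. Counts are exact by
#' construction.
#'
#' @param n_interpolar,n_mid,n_other Requested counts. Defaults 150, 30, 20.
#' @param geom [spindle_geometry()]; default centrioles at x = -2.5 and
#'   x = +2.5 um with plates at x = -0.8 and +0.8 um.
#' @param pole_radius Pole-proximity threshold used in construction (um).
#'   Default 0.5.
#' @param seed Mandatory integer seed.
#'
#' @return List with `traces` (tidy trace table) and `geometry`.
#' @export
gen_mt_set <- function(n_interpolar = 150, n_mid = 30, n_other = 20,
                       geom = NULL, pole_radius = 0.5, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  if (is.null(geom)) {
    geom <- spindle_geometry(
      centrioles = rbind(c(-2.5, 0, 0), c(2.5, 0, 0)),
      plate_centroids = rbind(c(-0.8, 0, 0), c(0.8, 0, 0)))
  }
  axis <- geom$axis
  # orthonormal frame around the axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  origin <- colMeans(geom$plate_centroids)
  lo <- geom$plate_proj[1] - sum(origin * axis)
  hi <- geom$plate_proj[2] - sum(origin * axis)
  slab_pt <- function(frac_lo, frac_hi, r_max = 1) {
    u <- runif(1, lo + frac_lo * (hi - lo), lo + frac_hi * (hi - lo))
    r <- r_max * sqrt(runif(1))
    th <- runif(1, 0, 2 * pi)
    origin + u * axis + r * cos(th) * e1 + r * sin(th) * e2
  }
  trace_pts <- function(p, q) rbind(p, (p + q) / 2, q)

  withr::with_seed(seed, {
    traces <- list()
    for (i in seq_len(n_interpolar)) {
      side <- sample(1:2, 1)
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      p <- geom$centrioles[side, ] + runif(1, 0.05, 0.9 * pole_radius) * dir
      q <- slab_pt(0.1, 0.9)
      traces[[length(traces) + 1]] <- trace_pts(p, q)
    }
    for (i in seq_len(n_mid)) {
      traces[[length(traces) + 1]] <- trace_pts(slab_pt(0.1, 0.45), slab_pt(0.55, 0.9))
    }
    half_gap <- min(sqrt(sum((geom$centrioles[1, ] - origin - lo * axis)^2)),
                    sqrt(sum((geom$centrioles[2, ] - origin - hi * axis)^2)))
    for (i in seq_len(n_other)) {
      # both ends beyond one plate, kept well clear of the centriole
      sgn <- sample(c(-1, 1), 1)
      edge <- if (sgn > 0) hi else lo
      mk <- function() {
        u <- edge + sgn * runif(1, 0.1, max(0.2, 0.4 * half_gap))
        r <- runif(1, 0.2, 1)
        th <- runif(1, 0, 2 * pi)
        origin + u * axis + r * cos(th) * e1 + r * sin(th) * e2
      }
      repeat {
        p <- mk()
        q <- mk()
        d_min <- min(apply(rbind(p, q), 1, function(e)
          min(sqrt(rowSums(sweep(geom$centrioles, 2, e)^2)))))
        if (d_min > 1.5 * pole_radius) break
      }
      traces[[length(traces) + 1]] <- trace_pts(p, q)
    }
    names(traces) <- sprintf("mt_%04d", seq_along(traces))
    tidy <- tibble::tibble(trace_id = character(), point_index = integer(),
                           x_um = numeric(), y_um = numeric(), z_um = numeric())
    if (length(traces) > 0) {
      tidy <- purrr::imap_dfr(traces, function(m, id) {
        tibble::tibble(trace_id = id, point_index = seq_len(nrow(m)),
                       x_um = m[, 1], y_um = m[, 2], z_um = m[, 3])
      })
    }
    list(traces = tidy, geometry = geom)
  })
}
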