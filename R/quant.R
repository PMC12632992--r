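#' Cell size from cell volume
#'
#' Cell size is defined throughout as the cube root of cell volume, the
#' scaling covariate against which spindle and chromosome quantities are
#' regressed.
#'
#' @param volume Cell volume (um^3); > 0. Vectorized.
#' @return Cell size (um).
#' @examples
#' cell_size_from_volume(12167) # 23, the 2-cell scale
#' @export
cell_size_from_volume <- function(volume) {
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    abort("`volume` must be positive and finite.")
  }
  volume^(1 / 3)
}

#' Per-cell trajectory quantification
#'
#' Fits the sigmoid model to each cell's pole-to-pole trace and the
#' exponential model to its chromosome-to-chromosome trace, returning the
#' derived final lengths and rates per cell.
#'
#' @param traj Trajectory tibble (shared CSV schema: `cell_id`, `stage`,
#'   `t_s`, `d_pp_um`, `d_cc_um`, ...).
#' @param meta Optional per-cell metadata with `cell_id` and `volume_um3`;
#'   when given, a `size_um` column (cube root of volume) is joined on.
#'
#' @return Tibble with one row per cell: `cell_id`, `stage`, fit-derived
#'   `flpp_um`, `erpp_um_min`, `flcc_um`, `srcc_um_min`, convergence flags,
#'   and `size_um` if `meta` was supplied.
#' @export
quantify_cells <- function(traj, meta = NULL) {
  stopifnot(is.data.frame(traj))
  out <- traj |>
    dplyr::group_by(.data$cell_id, .data$stage) |>
    dplyr::group_modify(function(d, key) {
      sf <- fit_sigmoid(d)
      ef <- fit_exponential(d)
      tibble::tibble(flpp_um = sf$flpp, erpp_um_min = sf$erpp,
                     flcc_um = ef$flcc, srcc_um_min = ef$srcc,
                     sigmoid_ok = sf$converged, exp_ok = ef$converged)
    }) |>
    dplyr::ungroup()
  if (!is.null(meta)) {
    stopifnot(all(c("cell_id", "volume_um3") %in% names(meta)))
    meta <- dplyr::mutate(meta, size_um = cell_size_from_volume(.data$volume_um3))
    out <- dplyr::left_join(out, dplyr::select(meta, "cell_id", "size_um"),
                            by = "cell_id")
  }
  out
}

#' Stage-level summary of per-cell quantities
#'
#' @param cells Per-cell tibble from [quantify_cells()] (needs `stage`,
#'   `size_um`, and the fitted quantities).
#' @return Tibble with one row per stage: mean `size_um` and mean and SD of
#'   FLPP, ERPP, FLCC, SRCC across cells, plus the cell count.
#' @export
stage_summary <- function(cells) {
  stopifnot(is.data.frame(cells), "size_um" %in% names(cells))
  cells |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      size_um = mean(.data$size_um),
      dplyr::across(c("flpp_um", "erpp_um_min", "flcc_um", "srcc_um_min"),
                    list(mean = mean, sd = sd)),
      .groups = "drop"
    )
}

#' Power-law scaling regression against cell size
#'
#' Ordinary least squares of a quantity on cell size. The default log-log
#' convention estimates the power-law exponent `b` in `q = C * size^b`: the
#' reading under which a ~2-fold final-length change over a ~3-fold size
#' change gives an exponent near 0.75. A linear-axes option is exposed and
#' the convention is recorded in the result.
#'
#' @param data Data frame of stage summaries (or any per-unit table).
#' @param size,quantity Columns (tidy-eval) holding cell size (um) and the
#'   quantity to regress.
#' @param convention `"loglog"` (default) or `"linear"`.
#' @param level Confidence level for the slope interval. Default 0.95.
#'
#' @return Object of class `scaling_fit`: `slope`, `slope_sd` (regression
#'   standard error), `intercept`, `conf_int`, `convention`, `n`, `r_squared`
#'   and the underlying `lm` fit.
#' @examples
#' d <- data.frame(size = c(7.3, 9, 11, 14, 18, 23))
#' d$len <- d$size^0.75
#' scaling_regression(d, size, len)$slope
#' @export
scaling_regression <- function(data, size, quantity,
                               convention = c("loglog", "linear"),
                               level = 0.95) {
  convention <- match.arg(convention)
  dat <- extract_xy(data, {{ size }}, {{ quantity }})
  if (length(dat$x) < 3) abort("scaling regression needs at least 3 points.")
  if (convention == "loglog") {
    if (any(dat$x <= 0) || any(dat$y <= 0)) {
      abort("log-log scaling needs strictly positive sizes and quantities.")
    }
    df <- data.frame(x = log(dat$x), y = log(dat$y))
  } else {
    df <- data.frame(x = dat$x, y = dat$y)
  }
  fit <- lm(y ~ x, data = df)
  sm <- summary(fit)
  ci <- confint(fit, "x", level = level)
  structure(
    list(slope = unname(coef(fit)[2]), slope_sd = sm$coefficients["x", "Std. Error"],
         intercept = unname(coef(fit)[1]), conf_int = unname(ci[1, ]),
         level = level, convention = convention, n = length(dat$x),
         r_squared = sm$r.squared, fit = fit,
         data = tibble::tibble(size = dat$x, quantity = dat$y)),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<scaling_fit> %s slope = %.4f +/- %.4f (SE), %d%% CI [%.4f, %.4f], n = %d, R^2 = %.3f\n",
    x$convention, x$slope, x$slope_sd, round(100 * x$level),
    x$conf_int[1], x$conf_int[2], x$n, x$r_squared))
  invisible(x)
}

#' @rdname scaling_regression
#' @param x A `scaling_fit`.
#' @param ... Unused.
#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(NA_real_, x$slope_sd),
                 conf.low = c(NA_real_, x$conf_int[1]),
                 conf.high = c(NA_real_, x$conf_int[2]))
}

#' @rdname scaling_regression
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, slope_sd = x$slope_sd,
                 conf.low = x$conf_int[1], conf.high = x$conf_int[2],
                 r.squared = x$r_squared, n = x$n, convention = x$convention)
}

#' Piecewise-linear transition of elongation rate with cell size
#'
#' Continuous two-segment fit of rate versus size: flat at a plateau for
#' sizes at or above the breakpoint `s*`, linear below it. For each candidate
#' breakpoint the remaining parameters are linear, so the profile over `s*`
#' is solved exactly (candidate grid plus the observed sizes, then local
#' refinement by golden-section search) and the residual sum of squares is
#' minimized.
#'
#' @param data Data frame of (size, rate) observations.
#' @param size,rate Columns (tidy-eval); um and um/min.
#' @param grid_n Number of candidate breakpoints across the interior of the
#'   observed size range. Default 101.
#'
#' @return Object of class `piecewise_fit`: `breakpoint` (um), `plateau`,
#'   `slope_below`, `rss`, `n`, `degenerate` (`TRUE` when the two-segment
#'   model does not improve on a flat fit, e.g. purely flat data).
#' @export
piecewise_transition <- function(data, size, rate, grid_n = 101) {
  dat <- extract_xy(data, {{ size }}, {{ rate }})
  s <- dat$x
  y <- dat$y
  if (length(s) < 6) abort("piecewise fit needs at least 6 (size, rate) points spanning both regimes.")

  rss_at <- function(brk) {
    z <- pmin(s - brk, 0)
    fit <- lm(y ~ z)
    sum(fit$residuals^2)
  }
  lo <- min(s)
  hi <- max(s)
  cand <- sort(unique(c(seq(lo, hi, length.out = grid_n), s)))
  cand <- cand[cand > lo & cand < hi]
  if (length(cand) == 0) abort("no interior breakpoint candidates in the size range.")
  rss <- vapply(cand, rss_at, numeric(1))
  best <- which.min(rss)
  # refine between the neighbouring candidates
  span <- c(cand[max(1, best - 1)], cand[min(length(cand), best + 1)])
  opt <- stats::optimize(rss_at, interval = span)
  brk <- if (opt$objective < rss[best]) opt$minimum else cand[best]

  z <- pmin(s - brk, 0)
  fit <- lm(y ~ z)
  rss_best <- sum(fit$residuals^2)
  rss_flat <- sum((y - mean(y))^2)
  degenerate <- !(rss_best < rss_flat * (1 - 1e-8))
  structure(
    list(breakpoint = brk, plateau = unname(coef(fit)[1]),
         slope_below = unname(coef(fit)[2]), rss = rss_best, n = length(s),
         degenerate = degenerate,
         data = tibble::tibble(size = s, rate = y)),
    class = "piecewise_fit"
  )
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf(
    "<piecewise_fit> breakpoint s* = %.2f um  plateau = %.3f  slope below = %.4f  (rss %.4g, n %d%s)\n",
    x$breakpoint, x$plateau, x$slope_below, x$rss, x$n,
    if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @rdname piecewise_transition
#' @param x A `piecewise_fit`.
#' @param ... Unused.
#' @export
glance.piecewise_fit <- function(x, ...) {
  tibble::tibble(breakpoint_um = x$breakpoint, plateau = x$plateau,
                 slope_below = x$slope_below, rss = x$rss, n = x$n,
                 degenerate = x$degenerate)
}

#' One-way ANOVA F statistic
#'
#' `F = MS_between / MS_within` with the standard degrees of freedom
#' (`k - 1` between, `N - k` within): the ratio of between-group to
#' within-group variability.
#'
#' @param groups List of numeric vectors, one per group; at least 2 groups
#'   with at least 2 values each.
#' @return The F statistic, with attribute `df = c(between, within)`. Zero
#'   within-group variance with distinct group means yields `Inf`.
#' @examples
#' anova_f(list(c(1, 2, 3), c(2, 3, 4))) # 1.5
#' @export
anova_f <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    abort("each group needs at least 2 values.")
  }
  all_x <- unlist(groups)
  grand <- mean(all_x)
  n_j <- vapply(groups, length, numeric(1))
  m_j <- vapply(groups, mean, numeric(1))
  ss_between <- sum(n_j * (m_j - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_b <- length(groups) - 1
  df_w <- length(all_x) - length(groups)
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  f <- if (ms_w == 0) {
    if (ms_b == 0) 0 else Inf
  } else {
    ms_b / ms_w
  }
  structure(f, df = c(between = df_b, within = df_w))
}

#' Pointwise average trajectory across cells
#'
#' Linearly interpolates every cell's trace onto a common grid covering the
#' overlapping time range of all cells (at the given spacing, anchored at the
#' latest common start) and returns the pointwise mean and sample SD.
#'
#' @param traj Trajectory tibble with `cell_id`, `t_s`, and the `value`
#'   column; all cells aligned to anaphase onset.
#' @param value Column to average (tidy-eval). Default `d_pp_um`.
#' @param by Grid spacing (s). Default 10.3.
#'
#' @return Tibble with `t_s`, `mean`, `sd`, `n_cells`.
#' @export
stage_average <- function(traj, value = d_pp_um, by = 10.3) {
  stopifnot(is.data.frame(traj), nrow(traj) > 0)
  cells <- split(traj, traj$cell_id)
  lo <- max(vapply(cells, function(d) min(d$t_s), numeric(1)))
  hi <- min(vapply(cells, function(d) max(d$t_s), numeric(1)))
  if (hi <= lo) abort("cells have no overlapping time range to average over.")
  grid <- seq(lo, hi, by = by)
  vals <- vapply(cells, function(d) {
    y <- dplyr::pull(d, {{ value }})
    ok <- is.finite(d$t_s) & is.finite(y)
    approx(d$t_s[ok], y[ok], xout = grid)$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  tibble::tibble(
    t_s = grid,
    mean = rowMeans(vals),
    sd = apply(vals, 1, sd),
    n_cells = ncol(vals)
  )
}
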