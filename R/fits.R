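#' Sigmoid fit of a pole-to-pole trajectory
#'
#' Least-squares fit of
#' \deqn{f(t) = L_1 + \frac{L_2}{1 + e^{-(t - t_0)/\tau_s}}}
#' to pole-to-pole distance versus time. `L1` is the initial spindle length,
#' `L2` the total length change, `t0` the inflection time, and `tau_s` the
#' sigmoid time constant. The derived quantities are the final pole-to-pole
#' length `FLPP = L1 + L2` and the elongation rate at the inflection point,
#' `ERPP = (L2 / (4 tau_s)) * 60` in um/min.
#'
#' Starting values: `L1` = first sample, `L2` = range, `t0` = half-range
#' crossing time, `tau_s` = range / (4 * max finite-difference slope); on
#' non-convergence a deterministic multi-start over +/-50% perturbations of
#' `L2`, `t0`, `tau_s` is tried. Inputs with (numerically) no rise return a
#' flat fit (`L2 = 0`) flagged as degenerate.
#'
#' @param traj Data frame with time and distance columns.
#' @param time,value Column names (tidy-eval) for time (s) and distance (um).
#'   Defaults `t_s`, `d_pp_um`.
#'
#' @return Object of class `sigmoid_fit`: parameters `L1`, `L2`, `t0`,
#'   `tau_s`, derived `flpp`, `erpp`, plus `rss`, `n`, `converged`,
#'   `degenerate`, and the data used.
#' @examples
#' t <- seq(0, 150, by = 10.3)
#' d <- 5.56 + 5.61 / (1 + exp(-(t - 30) / 28.33))
#' fit <- fit_sigmoid(data.frame(t_s = t, d_pp_um = d))
#' glance(fit)
#' @export
fit_sigmoid <- function(traj, time = t_s, value = d_pp_um) {
  dat <- extract_xy(traj, {{ time }}, {{ value }})
  t <- dat$x
  y <- dat$y
  if (length(t) < 6) abort("sigmoid fit needs at least 6 samples spanning the rise.")

  rng <- diff(range(y))
  if (rng < 1e-9 * max(1, abs(mean(y)))) {
    return(new_sigmoid_fit(L1 = mean(y), L2 = 0, t0 = mean(t),
                           tau_s = diff(range(t)) / 4, t = t, y = y,
                           converged = FALSE, degenerate = TRUE))
  }

  slopes <- diff(y) / diff(t)
  max_slope <- max(abs(slopes[is.finite(slopes)]), 1e-12)
  start0 <- list(
    L1 = y[1], L2 = rng,
    t0 = t[which.min(abs(y - (min(y) + rng / 2)))],
    tau_s = rng / (4 * max_slope)
  )
  perturb <- expand.grid(fL2 = c(1, 0.5, 1.5), ft0 = c(1, 0.5, 1.5),
                         ftau = c(1, 0.5, 1.5))
  fit <- NULL
  for (i in seq_len(nrow(perturb))) {
    st <- list(L1 = start0$L1, L2 = start0$L2 * perturb$fL2[i],
               t0 = start0$t0 * perturb$ft0[i],
               tau_s = max(start0$tau_s * perturb$ftau[i], 1e-3))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ L1 + L2 / (1 + exp(-(t - t0) / tau_s)),
        data = data.frame(t = t, y = y), start = st,
        lower = c(-Inf, -Inf, -Inf, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(new_sigmoid_fit(L1 = start0$L1, L2 = start0$L2, t0 = start0$t0,
                           tau_s = start0$tau_s, t = t, y = y,
                           converged = FALSE, degenerate = FALSE))
  }
  p <- as.list(coef(fit))
  new_sigmoid_fit(L1 = p$L1, L2 = p$L2, t0 = p$t0, tau_s = p$tau_s,
                  t = t, y = y, converged = TRUE, degenerate = FALSE)
}

new_sigmoid_fit <- function(L1, L2, t0, tau_s, t, y, converged, degenerate) {
  pred <- L1 + L2 / (1 + exp(-(t - t0) / tau_s))
  structure(
    list(L1 = L1, L2 = L2, t0 = t0, tau_s = tau_s,
         flpp = L1 + L2, erpp = (L2 / (4 * tau_s)) * 60,
         rss = sum((y - pred)^2), n = length(y),
         converged = converged, degenerate = degenerate,
         data = tibble::tibble(t_s = t, d_um = y, fitted = pred)),
    class = "sigmoid_fit"
  )
}

#' Exponential fit of a chromosome-to-chromosome trajectory
#'
#' Least-squares fit of `f(t) = a * (1 - exp(-t / k))` to post-onset
#' chromosome separation versus time (samples at `t < 0` are dropped).
#' Derived quantities: final chromosome separation `FLCC = a` (um) and the
#' segregation rate at anaphase onset `SRCC = (a / k) * 60` (um/min).
#'
#' @inheritParams fit_sigmoid
#' @param value Distance column; default `d_cc_um`.
#'
#' @return Object of class `exp_fit` with `a`, `k`, derived `flcc`, `srcc`,
#'   plus `rss`, `n`, `converged`, `degenerate`.
#' @examples
#' t <- seq(0, 120, by = 10.3)
#' fit <- fit_exponential(data.frame(t_s = t, d_cc_um = 5.93 * (1 - exp(-t / 22.92))))
#' glance(fit)
#' @export
fit_exponential <- function(traj, time = t_s, value = d_cc_um) {
  dat <- extract_xy(traj, {{ time }}, {{ value }})
  keep <- dat$x >= 0
  t <- dat$x[keep]
  y <- dat$y[keep]
  if (length(t) < 5) abort("exponential fit needs at least 5 post-onset samples.")

  a0 <- y[length(y)]
  if (max(abs(y)) < 1e-9) {
    return(new_exp_fit(a = 0, k = max(diff(range(t)) / 4, 1e-3), t = t, y = y,
                       converged = FALSE, degenerate = TRUE))
  }
  cross <- which(y >= a0 * (1 - exp(-1)))[1]
  k0 <- if (!is.na(cross) && t[cross] > 0) t[cross] else max(t) / 4
  fit <- NULL
  for (fk in c(1, 0.5, 1.5, 0.25, 3)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * (1 - exp(-t / k)),
        data = data.frame(t = t, y = y),
        start = list(a = a0, k = max(k0 * fk, 1e-3)),
        lower = c(-Inf, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(new_exp_fit(a = a0, k = k0, t = t, y = y,
                       converged = FALSE, degenerate = FALSE))
  }
  p <- as.list(coef(fit))
  new_exp_fit(a = p$a, k = p$k, t = t, y = y, converged = TRUE,
              degenerate = FALSE)
}

new_exp_fit <- function(a, k, t, y, converged, degenerate) {
  pred <- a * (1 - exp(-t / k))
  structure(
    list(a = a, k = k, flcc = a, srcc = (a / k) * 60,
         rss = sum((y - pred)^2), n = length(y),
         converged = converged, degenerate = degenerate,
         data = tibble::tibble(t_s = t, d_um = y, fitted = pred)),
    class = "exp_fit"
  )
}

extract_xy <- function(df, time, value) {
  stopifnot(is.data.frame(df))
  x <- dplyr::pull(df, {{ time }})
  y <- dplyr::pull(df, {{ value }})
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  ord <- order(x)
  list(x = x[ord], y = y[ord])
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> L1 = %.3f um  L2 = %.3f um  t0 = %.2f s  tau_s = %.2f s\n  FLPP = %.3f um  ERPP = %.3f um/min  (rss %.4g, n %d%s)\n",
    x$L1, x$L2, x$t0, x$tau_s, x$flpp, x$erpp, x$rss, x$n,
    if (x$degenerate) ", degenerate" else if (!x$converged) ", NOT converged" else ""))
  invisible(x)
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_fit> a = %.3f um  k = %.2f s\n  FLCC = %.3f um  SRCC = %.3f um/min  (rss %.4g, n %d%s)\n",
    x$a, x$k, x$flcc, x$srcc, x$rss, x$n,
    if (x$degenerate) ", degenerate" else if (!x$converged) ", NOT converged" else ""))
  invisible(x)
}

#' @rdname fit_sigmoid
#' @param x A `sigmoid_fit`.
#' @param ... Unused.
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(term = c("L1", "L2", "t0", "tau_s"),
                 estimate = c(x$L1, x$L2, x$t0, x$tau_s))
}

#' @rdname fit_sigmoid
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(flpp_um = x$flpp, erpp_um_min = x$erpp, rss = x$rss,
                 n = x$n, converged = x$converged, degenerate = x$degenerate)
}

#' @rdname fit_exponential
#' @param x An `exp_fit`.
#' @param ... Unused.
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "k"), estimate = c(x$a, x$k))
}

#' @rdname fit_exponential
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(flcc_um = x$flcc, srcc_um_min = x$srcc, rss = x$rss,
                 n = x$n, converged = x$converged, degenerate = x$degenerate)
}
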