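#' Microtubule dynamics parameters
#'
#' Parameters of the astral microtubule population nucleated at each
#' centrosome. Microtubules nucleate at rate `n_mt * lambda` (the steady-state
#' nucleation flux), grow at `v_g`, and undergo catastrophe at `lambda`, so
#' the mean microtubule length is `v_g / lambda`.
#'
#' @param n_mt Number of microtubules per aster (count). Default 5000.
#' @param v_g Microtubule growth velocity (um/s). Default 1.
#' @param lambda Catastrophe rate (1/s). The one stage-dependent parameter;
#'   no default, supply it or infer it with [fit_catastrophe_rate()].
#'
#' @return An object of class `mt_params`: a named list with fields `n_mt`,
#'   `v_g`, `lambda`, and the derived nucleation rate `n_dot = n_mt * lambda`.
#' @examples
#' mt_params(lambda = 0.038)
#' @export
mt_params <- function(n_mt = 5000, v_g = 1, lambda) {
  stopifnot(is.numeric(n_mt), n_mt > 0, is.numeric(v_g), v_g > 0)
  if (missing(lambda) || !is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    abort("`lambda` (catastrophe rate, 1/s) must be a single positive number.")
  }
  structure(
    list(n_mt = n_mt, v_g = v_g, lambda = lambda, n_dot = n_mt * lambda),
    class = "mt_params"
  )
}

#' Cortical motor parameters
#'
#' Minus-end-directed motors anchored uniformly on the cell surface. Binding
#' is stoichiometric (one motor, one microtubule); a bound motor pulls the
#' centrosome with force `f0` along the microtubule and detaches at `kappa`.
#' The motor count enters the force only through the prefactor `M * f0 / A`
#' with `M = round(rho * A)` and `A` the cell area.
#'
#' @param rho Motor surface density (1/um^2). Default 0.12.
#' @param r Motor size, i.e. capture radius for microtubule impingement (um).
#'   Default 1.5.
#' @param kappa Motor detachment rate (1/s). Default 1/20.
#' @param f0 Force exerted by one bound motor (pN). Default 5.
#'
#' @return An object of class `motor_params`.
#' @examples
#' motor_params()
#' @export
motor_params <- function(rho = 0.12, r = 1.5, kappa = 1 / 20, f0 = 5) {
  stopifnot(rho > 0, r > 0, kappa > 0, f0 > 0)
  structure(list(rho = rho, r = r, kappa = kappa, f0 = f0),
            class = "motor_params")
}

#' Motor count for a cell of given radius
#'
#' @param motors A [motor_params()] object.
#' @param radius Cell radius (um).
#' @return Integer motor count `M = round(rho * 4 pi R^2)`, at least 1.
#' @export
motor_count <- function(motors, radius) {
  stopifnot(inherits(motors, "motor_params"), radius > 0)
  max(1L, as.integer(round(motors$rho * 4 * pi * radius^2)))
}

#' Drag and viscous-coupling coefficients
#'
#' @param eta Cytoplasmic drag coefficient on each pole (pN s/um). Default 450.
#' @param nu Viscous coupling between a pole and its chromosome plate along
#'   the spindle axis (pN s/um). Default 50. `nu = 0` decouples the plates
#'   and recovers the pole-only model `eta * dx/dt = F`.
#'
#' @return An object of class `drag_params`.
#' @export
drag_params <- function(eta = 450, nu = 50) {
  stopifnot(eta > 0, nu >= 0)
  structure(list(eta = eta, nu = nu), class = "drag_params")
}

#' Imposed chromosome separation law
#'
#' Chromosome-to-chromosome separation is not modeled mechanistically; it is
#' imposed as `Dc(t) = c_f * (1 - exp(-t / tau_c))`, the exponential form
#' that describes measured segregation and is nearly invariant with cell size.
#'
#' @param c_f Final separation (um). Default 6.2.
#' @param tau_c Time constant (s). Default 29.
#'
#' @return An object of class `chromosome_law`.
#' @export
chromosome_law <- function(c_f = 6.2, tau_c = 29) {
  stopifnot(c_f > 0, tau_c > 0)
  structure(list(c_f = c_f, tau_c = tau_c), class = "chromosome_law")
}

#' One developmental-stage configuration
#'
#' @param stage Cell count of the stage (2--64).
#' @param cell_radius Cell radius (um), the cube root of mean cell volume.
#' @param initial_d_pp Pole-to-pole distance at anaphase onset (um); must be
#'   smaller than the cell diameter.
#' @param lambda Microtubule catastrophe rate (1/s), or `NULL` until inferred.
#'
#' @return An object of class `stage_config`.
#' @examples
#' stage_config(2, cell_radius = 23, initial_d_pp = 13, lambda = 0.038)
#' @export
stage_config <- function(stage, cell_radius, initial_d_pp, lambda = NULL) {
  stopifnot(cell_radius > 0, initial_d_pp > 0)
  if (initial_d_pp >= 2 * cell_radius) {
    abort("`initial_d_pp` must be smaller than the cell diameter 2 * cell_radius.")
  }
  if (!is.null(lambda)) stopifnot(lambda > 0)
  structure(list(stage = stage, cell_radius = cell_radius,
                 initial_d_pp = initial_d_pp, lambda = lambda),
            class = "stage_config")
}

#' Reference stage table for early C. elegans development
#'
#' Per-stage cell radius, pole-to-pole distance at anaphase onset, and the
#' inferred microtubule catastrophe rate, for the 2- through 64-cell stages.
#' Radii are cube roots of measured mean cell volumes; all other model
#' parameters are held fixed across stages (see [mt_params()],
#' [motor_params()], [drag_params()]).
#'
#' @return A tibble with columns `stage`, `cell_radius_um`,
#'   `initial_d_pp_um`, `lambda_s` (1/s).
#' @examples
#' celegans_stages()
#' @export
celegans_stages <- function() {
  tibble::tibble(
    stage = c(2L, 4L, 8L, 16L, 32L, 64L),
    cell_radius_um = c(23, 18, 14, 11, 9, 7.3),
    initial_d_pp_um = c(13, 11.2, 9, 7.5, 6.4, 5.4),
    lambda_s = c(0.038, 0.086, 0.164, 0.332, 0.615, 0.945)
  )
}

#' @export
print.mt_params <- function(x, ...) {
  cat("<mt_params> n_mt:", x$n_mt, " v_g:", x$v_g, "um/s  lambda:", x$lambda,
      "1/s  n_dot:", x$n_dot, "1/s\n")
  invisible(x)
}

#' @export
print.stage_config <- function(x, ...) {
  cat("<stage_config>", x$stage, "-cell  R:", x$cell_radius,
      "um  initial D_P-P:", x$initial_d_pp, "um  lambda:",
      if (is.null(x$lambda)) "(not set)" else paste(x$lambda, "1/s"), "\n")
  invisible(x)
}

# row of celegans_stages() (or compatible tibble) -> stage_config
as_stage_config <- function(row) {
  stage_config(row$stage, row$cell_radius_um, row$initial_d_pp_um,
               lambda = if (!is.null(row$lambda_s)) row$lambda_s else NULL)
}
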