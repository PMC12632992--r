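#' Microtubule impingement rate on a cortical point
#'
#' Rate at which growing microtubules from one aster hit a motor of capture
#' cross-section `pi r^2` at distance `d` from the centrosome:
#' \deqn{\Omega(d) = N_T \lambda \frac{r^2}{4 d^2} e^{-\lambda d / V_g}.}
#' Nucleation supplies `N_T * lambda` microtubules per second, an isotropic
#' emitter puts fraction `pi r^2 / (4 pi d^2)` of them on the motor's cross
#' section, and a microtubule survives to length `d` with probability
#' `exp(-lambda d / V_g)`. This closed form is the single place to swap in an
#' alternative impingement kernel.
#'
#' @param d Distance from the centrosome to the cortical point (um); > 0.
#' @param mt [mt_params()].
#' @param motors [motor_params()] (supplies the capture radius `r`).
#'
#' @return Impingement rate (1/s), vectorized over `d`.
#' @examples
#' impingement_rate(10, mt_params(lambda = 0.038), motor_params())
#' @export
impingement_rate <- function(d, mt, motors) {
  stopifnot(inherits(mt, "mt_params"), inherits(motors, "motor_params"))
  if (any(d <= 0)) abort("`d` must be > 0: a pole on the cortex is outside the model's domain.")
  mt$n_mt * mt$lambda * (motors$r^2 / (4 * d^2)) * exp(-mt$lambda * d / mt$v_g)
}

#' Imposed chromosome separation at time t
#'
#' @param t Time since anaphase onset (s); >= 0. Vectorized.
#' @param law [chromosome_law()].
#' @return Separation `c_f * (1 - exp(-t / tau_c))` (um); monotone
#'   non-decreasing, bounded by `c_f`.
#' @examples
#' imposed_separation(29, chromosome_law()) # c_f * (1 - 1/e)
#' @export
imposed_separation <- function(t, law = chromosome_law()) {
  stopifnot(inherits(law, "chromosome_law"))
  if (any(t < 0)) abort("`t` must be >= 0 (time since anaphase onset).")
  law$c_f * (1 - exp(-t / law$tau_c))
}

# analytic time derivative of the imposed law (um/s)
separation_rate <- function(t, law) (law$c_f / law$tau_c) * exp(-t / law$tau_c)

#' Spindle state at one time point
#'
#' @param t Time since anaphase onset (s).
#' @param x1,x2 Pole positions (3-vectors, um); must be distinct and strictly
#'   inside the cell if used with [cortical_force()].
#' @param law [chromosome_law()] used to place the chromosome plates on the
#'   pole midpoint, separated by `imposed_separation(t)` along the spindle
#'   axis.
#' @return An object of class `spindle_state` with fields `t`, `x1`, `x2`,
#'   `c1`, `c2`, and the spindle axis unit vector `s_hat = (x1 - x2)/|x1 - x2|`.
#' @export
spindle_state <- function(t, x1, x2, law = chromosome_law()) {
  stopifnot(length(x1) == 3, length(x2) == 3, t >= 0)
  d <- sqrt(sum((x1 - x2)^2))
  if (d <= 0) abort("poles coincide: spindle axis undefined.")
  s_hat <- (x1 - x2) / d
  mid <- (x1 + x2) / 2
  dc <- imposed_separation(t, law)
  structure(
    list(t = t, x1 = x1, x2 = x2,
         c1 = mid + (dc / 2) * s_hat, c2 = mid - (dc / 2) * s_hat,
         s_hat = s_hat),
    class = "spindle_state"
  )
}

#' Motor-binding probability field
#'
#' Coarse-grained per-patch probabilities that a motor at that patch is bound
#' to a microtubule from aster 1 or aster 2. Stoichiometry requires
#' `0 <= P1, 0 <= P2, P1 + P2 <= 1` everywhere.
#'
#' @param mesh [build_cell_mesh()] the field lives on.
#' @param P1,P2 Optional initial per-patch probabilities (default all zero).
#' @return An object of class `motor_field`.
#' @export
motor_field <- function(mesh, P1 = NULL, P2 = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- nrow(mesh$centers)
  P1 <- if (is.null(P1)) rep(0, n) else P1
  P2 <- if (is.null(P2)) rep(0, n) else P2
  stopifnot(length(P1) == n, length(P2) == n)
  if (any(P1 < 0) || any(P2 < 0) || any(P1 + P2 > 1 + 1e-12)) {
    abort("motor_field invariant violated: need 0 <= P1, 0 <= P2, P1 + P2 <= 1 at every patch.")
  }
  structure(list(P1 = P1, P2 = P2), class = "motor_field")
}

#' One explicit step of the motor-field dynamics
#'
#' Updates the bound-motor probability field by the stoichiometric binding
#' equation: `dP_i/dt = Omega_i * (1 - P1 - P2) - kappa * P_i`, with the
#' impingement rates evaluated from the current pole positions.
#'
#' @param field [motor_field()].
#' @param mesh [build_cell_mesh()].
#' @param state [spindle_state()] supplying the pole positions.
#' @param mt [mt_params()].
#' @param motors [motor_params()].
#' @param dt Time step (s); must satisfy `dt * (max Omega + kappa) < 1` for
#'   the explicit update to be stable.
#'
#' @return The updated `motor_field`.
#' @export
evolve_motor_field <- function(field, mesh, state, mt, motors, dt) {
  stopifnot(inherits(field, "motor_field"), inherits(mesh, "surface_mesh"),
            inherits(state, "spindle_state"), dt > 0)
  d1 <- sqrt(rowSums(sweep(mesh$centers, 2, state$x1)^2))
  d2 <- sqrt(rowSums(sweep(mesh$centers, 2, state$x2)^2))
  O1 <- impingement_rate(d1, mt, motors)
  O2 <- impingement_rate(d2, mt, motors)
  stab <- dt * (max(O1, O2) + motors$kappa)
  if (stab >= 1) {
    abort(sprintf(
      "explicit field update unstable: dt = %g gives dt*(max Omega + kappa) = %.3f >= 1; reduce dt.",
      dt, stab))
  }
  free <- 1 - field$P1 - field$P2
  motor_field(mesh,
              P1 = field$P1 + dt * (O1 * free - motors$kappa * field$P1),
              P2 = field$P2 + dt * (O2 * free - motors$kappa * field$P2))
}

#' Cortical pulling force on one pole
#'
#' Surface-quadrature evaluation of
#' \deqn{F_i = \frac{M f_0}{A} \int P_i(Y) \,\hat\xi(x_i, Y)\, dA,}
#' where `xi_hat` is the unit vector from the pole to the surface point, `M`
#' the motor count and `A` the cell area.
#'
#' @param field [motor_field()].
#' @param mesh [build_cell_mesh()].
#' @param pole_position Pole position (3-vector, um), strictly inside the
#'   sphere.
#' @param which_aster 1 or 2: which aster's bound probabilities to integrate.
#' @param motors [motor_params()].
#'
#' @return Force 3-vector (pN).
#' @export
cortical_force <- function(field, mesh, pole_position, which_aster, motors) {
  stopifnot(inherits(field, "motor_field"), inherits(mesh, "surface_mesh"),
            length(pole_position) == 3, which_aster %in% c(1, 2))
  if (sqrt(sum(pole_position^2)) >= mesh$radius) {
    abort("pole lies on or outside the cell surface; cortical force undefined.")
  }
  P <- if (which_aster == 1) field$P1 else field$P2
  xi <- sweep(mesh$centers, 2, pole_position)
  d <- sqrt(rowSums(xi^2))
  area <- 4 * pi * mesh$radius^2
  prefactor <- motor_count(motors, mesh$radius) * motors$f0 / area
  prefactor * colSums(P * mesh$areas * xi / d)
}

#' Advance poles and chromosome plates by one time step
#'
#' Solves the force balance
#' `eta * dx_i/dt + nu * ((dx_i/dt - dc_i/dt) . s_hat) s_hat = F_i`
#' by decomposition along the spindle axis: parallel component
#' `(F_par + nu * cdot_par) / (eta + nu)`, perpendicular component
#' `F_perp / eta`. The chromosome-plate velocity along the axis is the
#' analytic derivative of the imposed separation law, split evenly between
#' the plates (`+/- dDc/dt / 2`). After the pole move, the axis is recomputed
#' and the plates are re-seated on the new pole midpoint.
#'
#' @param state [spindle_state()].
#' @param F1,F2 Forces on pole 1 and pole 2 (pN 3-vectors).
#' @param drags [drag_params()].
#' @param law [chromosome_law()].
#' @param dt Time step (s).
#'
#' @return The advanced `spindle_state` at `t + dt`.
#' @export
step_state <- function(state, F1, F2, drags, law, dt) {
  stopifnot(inherits(state, "spindle_state"), inherits(drags, "drag_params"),
            inherits(law, "chromosome_law"), dt > 0)
  s <- state$s_hat
  dc_dot <- separation_rate(state$t, law)
  eta <- drags$eta
  nu <- drags$nu

  upd <- function(x, F_vec, c_par) {
    f_par <- sum(F_vec * s)
    v <- (F_vec - f_par * s) / eta + ((f_par + nu * c_par) / (eta + nu)) * s
    x + dt * v
  }
  x1 <- upd(state$x1, F1, +dc_dot / 2)
  x2 <- upd(state$x2, F2, -dc_dot / 2)
  spindle_state(state$t + dt, x1, x2, law)
}
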