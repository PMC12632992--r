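#' Simulate spindle elongation at one developmental stage
#'
#' Integrates the stoichiometric cortical-pulling model in a spherical cell:
#' poles start at the cell center offset by half the initial pole-to-pole
#' distance along a fixed axis, the chromosome plates start coincident at the
#' center, and the motor-binding field starts empty. The chromosome
#' separation follows the imposed exponential law, with the plates riding the
#' instantaneous pole midpoint. Pole-to-pole and chromosome-to-chromosome
#' distances are sampled at the acquisition interval.
#'
#' @param stage A [stage_config()] with `lambda` set, or one row of
#'   [celegans_stages()].
#' @param mt [mt_params()]; default uses the reference parameter set with the
#'   stage's catastrophe rate.
#' @param motors [motor_params()].
#' @param drags [drag_params()].
#' @param law [chromosome_law()].
#' @param t_end Simulated duration (s). Default 300, which covers the
#'   elongation plateau at every stage (about 10 chromosome time constants).
#' @param dt Integration step (s). Default 0.01, which keeps the explicit
#'   update inside its stability bound `dt * (max Omega + kappa) < 1` at all
#'   reference stages (impingement rates grow steeply as a pole nears the
#'   cortex).
#' @param sample_every Sampling interval of the output (s). Default 10.3, the
#'   light-sheet acquisition interval.
#' @param n_patches Surface mesh size. Default 2000.
#' @param engine `"cpp"` (compiled loop, the default) or `"r"` (reference
#'   loop built from [evolve_motor_field()], [cortical_force()] and
#'   [step_state()]; identical update order, used for cross-checking).
#'
#' @return A trajectory tibble with columns `cell_id`, `stage`, `lineage`,
#'   `t_s`, `d_pp_um`, `d_cc_um`, `d_pc_um`. Attribute `"sim"` carries the
#'   final motor field, sampled pole positions, and the minimum free-motor
#'   fraction observed over all steps (for invariant checking).
#' @examples
#' cfg <- stage_config(64, cell_radius = 7.3, initial_d_pp = 5.4, lambda = 0.945)
#' traj <- simulate_spindle(cfg, n_patches = 256, dt = 0.01, t_end = 50)
#' @export
simulate_spindle <- function(stage, mt = NULL, motors = motor_params(),
                             drags = drag_params(), law = chromosome_law(),
                             t_end = 300, dt = 0.01, sample_every = 10.3,
                             n_patches = 2000, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.data.frame(stage)) stage <- as_stage_config(stage)
  stopifnot(inherits(stage, "stage_config"))
  if (is.null(mt)) {
    if (is.null(stage$lambda)) {
      abort("`stage$lambda` is not set and no `mt` was supplied; the catastrophe rate is required.")
    }
    mt <- mt_params(lambda = stage$lambda)
  }
  stopifnot(inherits(mt, "mt_params"), inherits(motors, "motor_params"),
            inherits(drags, "drag_params"), inherits(law, "chromosome_law"),
            t_end > 0, dt > 0, sample_every > 0)

  mesh <- build_cell_mesh(stage$cell_radius, n_patches)
  half <- stage$initial_d_pp / 2
  x1 <- c(0, 0, +half)
  x2 <- c(0, 0, -half)
  area <- 4 * pi * stage$cell_radius^2
  prefactor <- motor_count(motors, stage$cell_radius) * motors$f0 / area

  if (engine == "cpp") {
    res <- cpp_simulate_spindle(
      mesh$centers, mesh$areas[1], stage$cell_radius, x1, x2,
      mt$n_mt, mt$v_g, mt$lambda, motors$r, prefactor, motors$kappa,
      drags$eta, drags$nu, law$c_f, law$tau_c, dt, t_end, sample_every)
    sim <- list(field = motor_field(mesh, res$P1, res$P2),
                x1 = res$x1, x2 = res$x2,
                min_free = res$min_free, min_p = res$min_p, mesh = mesh)
    times <- res$t_s
    d_pp <- res$d_pp_um
    d_cc <- res$d_cc_um
  } else {
    res <- simulate_spindle_r(mesh, stage, mt, motors, drags, law,
                              t_end, dt, sample_every)
    sim <- res$sim
    times <- res$t_s
    d_pp <- res$d_pp_um
    d_cc <- res$d_cc_um
  }

  out <- tibble::tibble(
    cell_id = paste0("sim_", stage$stage, "cell"),
    stage = stage$stage,
    lineage = NA_character_,
    t_s = times,
    d_pp_um = d_pp,
    d_cc_um = d_cc,
    d_pc_um = (d_pp - d_cc) / 2
  )
  attr(out, "sim") <- sim
  out
}

# pure-R reference loop; mirrors the compiled engine step for step
simulate_spindle_r <- function(mesh, stage, mt, motors, drags, law,
                               t_end, dt, sample_every) {
  state <- spindle_state(0, c(0, 0, stage$initial_d_pp / 2),
                         c(0, 0, -stage$initial_d_pp / 2), law)
  field <- motor_field(mesh)
  n_steps <- round(t_end / dt)
  times <- d_pp <- d_cc <- numeric(0)
  x1s <- x2s <- NULL
  next_sample <- 0
  min_free <- 1

  for (step in 0:n_steps) {
    t <- step * dt
    dpp <- sqrt(sum((state$x1 - state$x2)^2))
    if (t + 1e-9 >= next_sample) {
      times <- c(times, t)
      d_pp <- c(d_pp, dpp)
      d_cc <- c(d_cc, imposed_separation(t, law))
      x1s <- rbind(x1s, state$x1)
      x2s <- rbind(x2s, state$x2)
      next_sample <- next_sample + sample_every
    }
    if (step == n_steps) break
    field <- evolve_motor_field(field, mesh, state, mt, motors, dt)
    min_free <- min(min_free, 1 - field$P1 - field$P2)
    F1 <- cortical_force(field, mesh, state$x1, 1, motors)
    F2 <- cortical_force(field, mesh, state$x2, 2, motors)
    state <- step_state(state, F1, F2, drags, law, dt)
    r_max <- max(sqrt(sum(state$x1^2)), sqrt(sum(state$x2^2)))
    if (r_max >= mesh$radius) {
      abort(sprintf("pole escaped the cell at t = %g s (parameter pathology).", t + dt))
    }
  }
  list(t_s = times, d_pp_um = d_pp, d_cc_um = d_cc,
       sim = list(field = field, x1 = x1s, x2 = x2s,
                  min_free = min_free, min_p = min(field$P1, field$P2, 0),
                  mesh = mesh))
}

#' Simulate every stage of a stage table
#'
#' @param stages Tibble like [celegans_stages()] (columns `stage`,
#'   `cell_radius_um`, `initial_d_pp_um`, `lambda_s`).
#' @param ... Passed to [simulate_spindle()].
#' @return One bound trajectory tibble with all stages.
#' @export
simulate_stages <- function(stages = celegans_stages(), ...) {
  purrr::map_dfr(seq_len(nrow(stages)),
                 function(i) simulate_spindle(stages[i, ], ...))
}
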