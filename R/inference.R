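#' Differential-evolution settings for catastrophe-rate inference
#'
#' @param population_size Candidates per generation (>= 4). Default 50, i.e.
#'   50 simulations per generation.
#' @param max_generations Generation cap. Default 25.
#' @param bounds Search interval for the catastrophe rate (1/s); must lie
#'   within \[0.001, 10\]. Default the full interval.
#' @param tol Convergence tolerance: stop when the population spread of
#'   lambda falls below `tol`. Default 1e-3.
#' @param seed Mandatory integer seed; inference is deterministic given it.
#' @param mutation,crossover DE rand/1/bin control parameters. Defaults 0.7
#'   and 0.9.
#'
#' @return An object of class `de_config`.
#' @export
de_config <- function(population_size = 50, max_generations = 25,
                      bounds = c(0.001, 10), tol = 1e-3, seed,
                      mutation = 0.7, crossover = 0.9) {
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is mandatory for reproducible inference.")
  stopifnot(population_size >= 4, max_generations >= 1,
            length(bounds) == 2, bounds[1] < bounds[2],
            bounds[1] >= 0.001, bounds[2] <= 10, tol > 0)
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 bounds = bounds, tol = tol, seed = as.integer(seed),
                 mutation = mutation, crossover = crossover),
            class = "de_config")
}

#' Squared-error objective between a simulated and a target trajectory
#'
#' Runs the spindle simulation at the given catastrophe rate and evaluates
#' \deqn{\mathcal{E}(\lambda) = \sum_i (L_i^{exp} - L_i^{sim}(\lambda))^2}
#' over the target's time points, with the simulated pole-to-pole distance
#' linearly interpolated to the target times.
#'
#' @param lambda Catastrophe rate (1/s).
#' @param target Trajectory tibble (columns `t_s`, `d_pp_um`).
#' @param stage [stage_config()] (its `lambda`, if any, is ignored).
#' @param motors,drags,law Model parameters held fixed.
#' @param n_patches,dt Simulation resolution for the objective evaluation;
#'   the reduced defaults (256 patches, dt 0.01 s) keep a differential
#'   evolution run affordable.
#' @param t_end Simulated duration; defaults to the last target time. Target
#'   times beyond `t_end` are an error.
#'
#' @return Sum of squared residuals (um^2).
#' @export
trajectory_error <- function(lambda, target, stage,
                             motors = motor_params(), drags = drag_params(),
                             law = chromosome_law(),
                             n_patches = 256, dt = 0.01, t_end = NULL) {
  stopifnot(is.data.frame(target), nrow(target) > 0)
  if (is.data.frame(stage)) stage <- as_stage_config(stage)
  if (is.null(t_end)) t_end <- max(target$t_s)
  if (max(target$t_s) > t_end + 1e-9) {
    abort("target times exceed the simulated duration `t_end`.")
  }
  sim <- simulate_spindle(stage, mt = mt_params(lambda = lambda),
                          motors = motors, drags = drags, law = law,
                          t_end = t_end, dt = dt, sample_every = dt,
                          n_patches = n_patches)
  l_sim <- approx(sim$t_s, sim$d_pp_um, xout = target$t_s, rule = 2)$y
  sum((target$d_pp_um - l_sim)^2)
}

#' Infer the microtubule catastrophe rate from a pole-to-pole trajectory
#'
#' Minimizes [trajectory_error()] over the catastrophe rate with
#' differential evolution (rand/1/bin), the global derivative-free search
#' used because the objective is a simulation output with no useful
#' gradient. All other model parameters are held fixed. The DE loop runs at
#' a reduced resolution (`n_patches`, `dt`); the reported error is
#' re-evaluated with a final full-resolution simulation.
#'
#' @param target Trajectory tibble (columns `t_s`, `d_pp_um`).
#' @param stage [stage_config()] or a one-row stage table.
#' @param motors,drags,law Fixed model parameters.
#' @param de [de_config()] (carries the mandatory seed).
#' @param n_patches,dt Resolution used inside the DE loop. Defaults 256
#'   patches and 0.01 s. Candidates whose simulation fails (pole driven into
#'   the cortex, stability-guard violation) are scored as infinitely bad and
#'   rejected.
#' @param refine_n_patches,refine_dt Resolution of the final refinement
#'   simulation used for the reported error. Defaults 2000 and 0.01 s.
#'
#' @return An object of class `catastrophe_fit`: `lambda_hat` (1/s), `error`
#'   (um^2, at refinement resolution), `generations`, `converged`, `seed`,
#'   `de`, `stage`.
#' @export
fit_catastrophe_rate <- function(target, stage,
                                 motors = motor_params(), drags = drag_params(),
                                 law = chromosome_law(), de,
                                 n_patches = 256, dt = 0.01,
                                 refine_n_patches = 2000, refine_dt = 0.01) {
  stopifnot(inherits(de, "de_config"))
  if (is.data.frame(stage)) stage <- as_stage_config(stage)
  obj <- function(lambda) {
    tryCatch(
      trajectory_error(lambda, target, stage, motors = motors, drags = drags,
                       law = law, n_patches = n_patches, dt = dt),
      error = function(e) Inf)
  }
  lo <- de$bounds[1]
  hi <- de$bounds[2]
  np <- de$population_size

  res <- withr::with_seed(de$seed, {
    pop <- runif(np, lo, hi)
    err <- vapply(pop, obj, numeric(1))
    if (all(!is.finite(err))) abort("non-finite objective at every initial candidate.")
    gen <- 0L
    converged <- FALSE
    for (gen in seq_len(de$max_generations)) {
      for (i in seq_len(np)) {
        idx <- sample(setdiff(seq_len(np), i), 3)
        trial <- pop[idx[1]] + de$mutation * (pop[idx[2]] - pop[idx[3]])
        # bin crossover on a single gene always inherits the mutant
        trial <- min(max(trial, lo), hi)
        e_trial <- obj(trial)
        if (is.finite(e_trial) && e_trial <= err[i]) {
          pop[i] <- trial
          err[i] <- e_trial
        }
      }
      if (diff(range(pop)) < de$tol) {
        converged <- TRUE
        break
      }
    }
    best <- which.min(err)
    list(lambda = pop[best], gen = gen, converged = converged)
  })

  refined_error <- trajectory_error(res$lambda, target, stage, motors = motors,
                                    drags = drags, law = law,
                                    n_patches = refine_n_patches, dt = refine_dt)
  structure(
    list(lambda_hat = res$lambda, error = refined_error,
         generations = res$gen, converged = res$converged,
         seed = de$seed, de = de, stage = stage),
    class = "catastrophe_fit"
  )
}

#' Infer the catastrophe rate for every stage of a batch
#'
#' @param targets Named list of trajectory tibbles, one per stage; names are
#'   the stage cell counts (e.g. `"2"`, `"64"`).
#' @param configs Stage table like [celegans_stages()]; the `lambda_s` column
#'   (if present) is ignored by the fit.
#' @param de [de_config()]; each stage uses a sub-seed derived from it.
#' @param ... Passed to [fit_catastrophe_rate()].
#'
#' @return Tibble with one row per input target, in input order: `stage`,
#'   `cell_radius_um`, `lambda_hat`, `error`, `generations`, `converged`.
#' @export
fit_all_stages <- function(targets, configs = celegans_stages(), de, ...) {
  stopifnot(inherits(de, "de_config"), length(targets) >= 1,
            !is.null(names(targets)))
  purrr::map_dfr(names(targets), function(nm) {
    row <- configs[configs$stage == as.integer(nm), ]
    if (nrow(row) != 1) abort(sprintf("stage %s: no matching row in `configs`.", nm))
    de_i <- de
    de_i$seed <- (de$seed + as.integer(nm)) %% .Machine$integer.max
    fit <- tryCatch(
      fit_catastrophe_rate(targets[[nm]], row, de = de_i, ...),
      error = function(e) abort(sprintf("stage %s: %s", nm, conditionMessage(e)))
    )
    tibble::tibble(stage = as.integer(nm), cell_radius_um = row$cell_radius_um,
                   lambda_hat = fit$lambda_hat, error = fit$error,
                   generations = fit$generations, converged = fit$converged)
  })
}

#' @export
print.catastrophe_fit <- function(x, ...) {
  cat(sprintf(
    "<catastrophe_fit> stage %s: lambda_hat = %.4f 1/s  error = %.4g um^2  (%d generations%s, seed %d)\n",
    x$stage$stage, x$lambda_hat, x$error, x$generations,
    if (x$converged) ", converged" else "", x$seed))
  invisible(x)
}

#' @rdname fit_catastrophe_rate
#' @param x A `catastrophe_fit`.
#' @param ... Unused.
#' @export
tidy.catastrophe_fit <- function(x, ...) {
  tibble::tibble(term = "lambda", estimate = x$lambda_hat,
                 lower = x$de$bounds[1], upper = x$de$bounds[2])
}

#' @rdname fit_catastrophe_rate
#' @export
glance.catastrophe_fit <- function(x, ...) {
  tibble::tibble(lambda_hat = x$lambda_hat, error = x$error,
                 generations = x$generations, converged = x$converged,
                 seed = x$seed)
}
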