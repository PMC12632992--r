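#' Read a trajectory CSV
#'
#' Shared trajectory schema: columns `cell_id`, `stage`, `lineage`, `t_s`,
#' `d_pp_um`, `d_cc_um`, `d_pc_um` (the last may be blank), one row per
#' sample, time zero at anaphase onset. Units are carried in the column
#' names (s, um).
#'
#' @param path CSV path.
#' @return Trajectory tibble. Missing required columns or malformed rows
#'   raise errors naming the offending columns / line numbers.
#' @export
read_trajectory_csv <- function(path) {
  required <- c("cell_id", "stage", "lineage", "t_s", "d_pp_um", "d_cc_um")
  out <- suppressWarnings(readr::read_csv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      cell_id = readr::col_character(), stage = readr::col_integer(),
      lineage = readr::col_character(), t_s = readr::col_double(),
      d_pp_um = readr::col_double(), d_cc_um = readr::col_double(),
      d_pc_um = readr::col_double(), .default = readr::col_guess())))
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols) > 0) {
    abort(paste0("trajectory CSV is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(paste0("malformed trajectory rows at line(s) ",
                 paste(utils::head(probs$row, 10), collapse = ", "),
                 " (column(s) ", paste(unique(probs$col), collapse = ", "), ")."))
  }
  if (!"d_pc_um" %in% names(out)) out$d_pc_um <- NA_real_
  out
}

#' Write a trajectory CSV
#'
#' @param traj Trajectory tibble (shared schema).
#' @param path Output path.
#' @param force Overwrite an existing file. Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, force = FALSE) {
  stopifnot(is.data.frame(traj))
  required <- c("cell_id", "stage", "lineage", "t_s", "d_pp_um", "d_cc_um")
  missing_cols <- setdiff(required, names(traj))
  if (length(missing_cols) > 0) {
    abort(paste0("trajectory is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (file.exists(path) && !force) {
    abort(paste0("`", path, "` exists; pass force = TRUE to overwrite."))
  }
  if (!"d_pc_um" %in% names(traj)) traj$d_pc_um <- NA_real_
  readr::write_csv(traj[, c(required, "d_pc_um")], path)
  invisible(path)
}

#' Load a model/run configuration from YAML
#'
#' Parses the documented parameter blocks (`mt_params`, `motor_params`,
#' `drag_params`, `chromosome_law`, `stages`, `sim`) into the package's
#' parameter objects, filling unspecified fields with the reference
#' defaults. Unknown keys in a block are an error (typo guard).
#'
#' @param path YAML path.
#' @return A list of class `run_config` with elements `mt` (a list: `n_mt`,
#'   `v_g`, optional `lambda`), `motors`, `drags`, `law`, `stages`
#'   (tibble), `sim` (list with `dt`, `t_end`, `n_patches`, `sample_every`,
#'   `seed`).
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pick <- function(block, fields, defaults) {
    b <- cfg[[block]]
    if (is.null(b)) b <- list()
    extra <- setdiff(names(b), fields)
    if (length(extra) > 0) {
      abort(paste0("unknown key(s) in `", block, "`: ", paste(extra, collapse = ", ")))
    }
    utils::modifyList(defaults, b)
  }
  mt <- pick("mt_params", c("n_mt", "v_g", "lambda"),
             list(n_mt = 5000, v_g = 1, lambda = NULL))
  motors_l <- pick("motor_params", c("rho", "r", "kappa", "f0"),
                   list(rho = 0.12, r = 1.5, kappa = 1 / 20, f0 = 5))
  drags_l <- pick("drag_params", c("eta", "nu"), list(eta = 450, nu = 50))
  law_l <- pick("chromosome_law", c("c_f", "tau_c"), list(c_f = 6.2, tau_c = 29))
  sim <- pick("sim", c("dt", "t_end", "n_patches", "sample_every", "seed"),
              list(dt = 0.05, t_end = 300, n_patches = 2000,
                   sample_every = 10.3, seed = NULL))
  stages <- if (is.null(cfg$stages)) {
    celegans_stages()
  } else {
    purrr::map_dfr(cfg$stages, function(s) {
      tibble::tibble(stage = as.integer(s$stage),
                     cell_radius_um = s$cell_radius_um,
                     initial_d_pp_um = s$initial_d_pp_um,
                     lambda_s = if (is.null(s$lambda_s)) NA_real_ else s$lambda_s)
    })
  }
  structure(
    list(mt = mt,
         motors = motor_params(motors_l$rho, motors_l$r, motors_l$kappa, motors_l$f0),
         drags = drag_params(drags_l$eta, drags_l$nu),
         law = chromosome_law(law_l$c_f, law_l$tau_c),
         stages = stages, sim = sim),
    class = "run_config"
  )
}
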