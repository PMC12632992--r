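#' Velocity from a windowed linear fit
#'
#' Ordinary least-squares slope of distance versus time over the samples in
#' the open interval `(t_lo, t_hi)`. Both endpoints are excluded, matching
#' the analysis windows used around an ablation event; the 0--4 s severing
#' and recoil transient sits between the standard windows and is excluded by
#' construction.
#'
#' @param times Time stamps (s; 0 = ablation).
#' @param dists Distances (um), same length.
#' @param window `c(t_lo, t_hi)` (s).
#' @return Slope (um/s), or `NA` with attribute `flagged = TRUE` when fewer
#'   than 3 finite samples fall inside the window.
#' @examples
#' t <- seq(-10, 15)
#' window_velocity(t, 8 + 0.05 * t, c(-8, 0)) # 0.05
#' @export
window_velocity <- function(times, dists, window) {
  stopifnot(length(times) == length(dists), length(window) == 2,
            window[1] < window[2])
  sel <- times > window[1] & times < window[2] & is.finite(times) & is.finite(dists)
  if (sum(sel) < 3) return(structure(NA_real_, flagged = TRUE))
  x <- times[sel]
  y <- dists[sel]
  structure(sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2),
            flagged = FALSE)
}

#' Pole and chromosome velocity response to spindle severing
#'
#' Before/after separation velocities from windowed linear fits: the
#' pre-ablation window `(-8, 0)` s and the post-ablation window `(4, 12)` s
#' for both the pole-to-pole and the chromosome-to-chromosome distance.
#' Deltas are after minus before; the relative pole response is the percent
#' change of the pole-to-pole elongation rate.
#'
#' @param record Data frame with `t_s` (0 = ablation), `d_pp_um`, `d_cc_um`,
#'   and optionally `condition`; must cover both analysis windows.
#' @param before,after Window bounds (s). Defaults `c(-8, 0)` and `c(4, 12)`.
#'
#' @return One-row tibble of class `ablation_response`: `v_pp_before`,
#'   `v_pp_after`, `v_cc_before`, `v_cc_after` (um/s), `delta_pp`,
#'   `delta_cc`, `pct_change_pp`, `flagged`. Window failures propagate as
#'   `NA` per quantity.
#' @export
ablation_response <- function(record, before = c(-8, 0), after = c(4, 12)) {
  stopifnot(is.data.frame(record),
            all(c("t_s", "d_pp_um", "d_cc_um") %in% names(record)))
  v_pp_b <- window_velocity(record$t_s, record$d_pp_um, before)
  v_pp_a <- window_velocity(record$t_s, record$d_pp_um, after)
  v_cc_b <- window_velocity(record$t_s, record$d_cc_um, before)
  v_cc_a <- window_velocity(record$t_s, record$d_cc_um, after)
  out <- tibble::tibble(
    condition = if ("condition" %in% names(record)) record$condition[1] else NA_character_,
    v_pp_before = as.numeric(v_pp_b), v_pp_after = as.numeric(v_pp_a),
    v_cc_before = as.numeric(v_cc_b), v_cc_after = as.numeric(v_cc_a),
    delta_pp = as.numeric(v_pp_a) - as.numeric(v_pp_b),
    delta_cc = as.numeric(v_cc_a) - as.numeric(v_cc_b),
    pct_change_pp = 100 * (as.numeric(v_pp_a) - as.numeric(v_pp_b)) / as.numeric(v_pp_b),
    flagged = any(vapply(list(v_pp_b, v_pp_a, v_cc_b, v_cc_a),
                         function(v) isTRUE(attr(v, "flagged")), logical(1)))
  )
  class(out) <- c("ablation_response", class(out))
  out
}

#' Ablation responses for a cohort of records
#'
#' @param records Data frame with a `record_id` column plus the
#'   [ablation_response()] schema, or a list of record data frames.
#' @param ... Passed to [ablation_response()].
#' @return Tibble with one response row per record.
#' @export
ablation_cohort <- function(records, ...) {
  if (is.data.frame(records)) {
    stopifnot("record_id" %in% names(records))
    records <- split(records, records$record_id)
  }
  purrr::imap_dfr(records, function(rec, id) {
    dplyr::bind_cols(tibble::tibble(record_id = as.character(id)),
                     ablation_response(rec, ...))
  })
}
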