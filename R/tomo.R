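#' Spindle geometry for microtubule classification
#'
#' Reference geometry from an electron tomogram: the two centriole positions
#' (markers for the spindle poles) and the two chromosome-plate planes, each
#' given by its centroid and sharing the spindle-axis normal.
#'
#' @param centrioles 2 x 3 matrix of centriole positions (um).
#' @param plate_centroids 2 x 3 matrix of chromosome-plate centroids (um);
#'   their projections on the axis must be distinct.
#' @param axis Optional spindle-axis vector; default the unit vector from
#'   centriole 1 to centriole 2. Normalized internally.
#'
#' @return Object of class `spindle_geometry`.
#' @export
spindle_geometry <- function(centrioles, plate_centroids, axis = NULL) {
  centrioles <- as.matrix(centrioles)
  plate_centroids <- as.matrix(plate_centroids)
  stopifnot(all(dim(centrioles) == c(2, 3)), all(dim(plate_centroids) == c(2, 3)),
            all(is.finite(centrioles)), all(is.finite(plate_centroids)))
  if (is.null(axis)) axis <- centrioles[2, ] - centrioles[1, ]
  nrm <- sqrt(sum(axis^2))
  if (nrm <= 0) abort("degenerate geometry: zero-length spindle axis.")
  axis <- axis / nrm
  proj <- as.numeric(plate_centroids %*% axis)
  if (abs(diff(proj)) < 1e-9) {
    abort("degenerate geometry: chromosome-plate planes coincide along the spindle axis.")
  }
  structure(list(centrioles = centrioles, plate_centroids = plate_centroids,
                 axis = axis, plate_proj = sort(proj)),
            class = "spindle_geometry")
}

#' Classify one traced microtubule by end-point geometry
#'
#' A trace is *interpolar* when either end lies within `pole_radius` of a
#' centriole (this takes precedence, so a microtubule running from a pole
#' past the nearer plate toward the other plate is interpolar);
#' *mid-spindle* when both ends fall strictly inside the open slab bounded
#' by the two chromosome-plate planes and neither end is pole-proximal;
#' *other* otherwise.
#'
#' @param trace Matrix or data frame of ordered 3-D points (um), >= 2 rows;
#'   the first and last rows are the end points.
#' @param geom [spindle_geometry()].
#' @param pole_radius Distance threshold for "near a centriole" (um).
#'   Default 0.5.
#'
#' @return One of `"interpolar"`, `"mid_spindle"`, `"other"`.
#' @export
classify_microtubule <- function(trace, geom, pole_radius = 0.5) {
  stopifnot(inherits(geom, "spindle_geometry"), pole_radius > 0)
  pts <- as.matrix(trace)
  stopifnot(ncol(pts) == 3, nrow(pts) >= 2, all(is.finite(pts)))
  ends <- pts[c(1, nrow(pts)), , drop = FALSE]

  dist_to_centriole <- function(e) {
    min(sqrt(rowSums(sweep(geom$centrioles, 2, e)^2)))
  }
  d_end <- apply(ends, 1, dist_to_centriole)
  if (any(d_end <= pole_radius)) return("interpolar")

  proj <- as.numeric(ends %*% geom$axis)
  between <- proj > geom$plate_proj[1] & proj < geom$plate_proj[2]
  if (all(between)) return("mid_spindle")
  "other"
}

#' Classify every trace of a trace table
#'
#' @param traces Tidy trace table with columns `trace_id`, `point_index`,
#'   `x_um`, `y_um`, `z_um` (points ordered within trace), or a list of
#'   point matrices.
#' @inheritParams classify_microtubule
#' @return Tibble with `trace_id` and `class`.
#' @export
classify_microtubules <- function(traces, geom, pole_radius = 0.5) {
  if (is.data.frame(traces)) {
    if (nrow(traces) == 0) abort("empty trace set.")
    stopifnot(all(c("trace_id", "point_index", "x_um", "y_um", "z_um") %in% names(traces)))
    traces <- traces |>
      dplyr::arrange(.data$trace_id, .data$point_index) |>
      (\(d) split(d[, c("x_um", "y_um", "z_um")], d$trace_id))()
    traces <- purrr::map(traces, as.matrix)
  }
  if (length(traces) == 0) abort("empty trace set.")
  purrr::imap_dfr(traces, function(m, id) {
    tibble::tibble(trace_id = as.character(id),
                   class = classify_microtubule(m, geom, pole_radius))
  })
}

#' Population counts per microtubule class
#'
#' @inheritParams classify_microtubules
#' @return Tibble with one row per class (`interpolar`, `mid_spindle`,
#'   `other`), columns `class`, `n`, and the attribute-checked `total`
#'   column repeated per row; counts always sum to the number of traces.
#' @export
summarize_population <- function(traces, geom, pole_radius = 0.5) {
  cls <- classify_microtubules(traces, geom, pole_radius)
  counts <- tibble::tibble(class = c("interpolar", "mid_spindle", "other")) |>
    dplyr::left_join(dplyr::count(cls, .data$class), by = "class") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L), total = nrow(cls))
  counts
}
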