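#' Kymograph container
#'
#' A spindle-axis kymograph: an intensity matrix with rows as time frames
#' and columns as position along the spindle axis, plus calibration. Pixel
#' positions are 0-based; sub-pixel centers are continuous.
#'
#' @param intensity Non-negative numeric matrix (frames x positions).
#' @param channel `"poles"` or `"chromosomes"`.
#' @param pixel_um Pixel size along the axis (um); > 0.
#' @param frame_s Frame interval (s); > 0.
#'
#' @return Object of class `kymograph`.
#' @export
kymograph <- function(intensity, channel = c("poles", "chromosomes"),
                      pixel_um = 0.1, frame_s = 10.3) {
  channel <- match.arg(channel)
  stopifnot(is.matrix(intensity), is.numeric(intensity), pixel_um > 0, frame_s > 0)
  if (any(intensity < 0)) abort("kymograph intensities must be non-negative.")
  structure(list(intensity = intensity, channel = channel,
                 pixel_um = pixel_um, frame_s = frame_s),
            class = "kymograph")
}

#' Read a kymograph from a TIFF or CSV matrix file
#'
#' A single-channel image file holding the time-by-position intensity
#' matrix: `.tif`/`.tiff` (requires the `tiff` package) or a headerless
#' `.csv` with one row per frame. Calibration is supplied alongside, as in
#' [kymograph()].
#'
#' @param path File path.
#' @inheritParams kymograph
#' @return A [kymograph()] object.
#' @export
read_kymograph <- function(path, channel = c("poles", "chromosomes"),
                           pixel_um = 0.1, frame_s = 10.3) {
  ext <- tolower(tools::file_ext(path))
  intensity <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("reading TIFF kymographs requires the `tiff` package.")
    }
    img <- tiff::readTIFF(path)
    if (length(dim(img)) > 2) img <- img[, , 1]
    img
  } else {
    as.matrix(utils::read.csv(path, header = FALSE))
  }
  storage.mode(intensity) <- "double"
  dimnames(intensity) <- NULL
  kymograph(intensity, channel = channel, pixel_um = pixel_um,
            frame_s = frame_s)
}

#' @export
print.kymograph <- function(x, ...) {
  cat("<kymograph>", x$channel, ":", nrow(x$intensity), "frames x",
      ncol(x$intensity), "px  (", x$pixel_um, "um/px,", x$frame_s, "s/frame )\n")
  invisible(x)
}

# topographic prominence of local maxima in a 1-D profile
local_peaks <- function(p) {
  n <- length(p)
  idx <- which(diff(sign(diff(p))) < 0) + 1L
  if (length(idx) == 0) return(tibble::tibble(index = integer(), prominence = numeric()))
  prom <- vapply(idx, function(i) {
    left <- p[seq_len(i - 1)]
    right <- p[seq(i + 1, n)]
    higher_l <- which(left >= p[i])
    higher_r <- which(right >= p[i])
    base_l <- min(p[seq(if (length(higher_l)) max(higher_l) else 1, i)])
    base_r <- min(p[seq(i, if (length(higher_r)) i + min(higher_r) else n)])
    p[i] - max(base_l, base_r)
  }, numeric(1))
  tibble::tibble(index = idx, prominence = prom)
}

#' Initial spindle-pole positions from an intensity profile
#'
#' Locates the two most prominent local maxima of a single-frame intensity
#' profile, the starting points for sub-pixel Gaussian refinement. Peaks must
#' exceed a prominence floor of 3x the robust noise estimate (median absolute
#' deviation) of the profile; prominence ties are broken by proximity to the
#' profile center.
#'
#' @param profile Numeric intensity vector, length >= 16.
#' @param prominence_floor Optional explicit floor; default `3 * mad(profile)`.
#'
#' @return Sorted numeric vector of the two peak positions (0-based pixels),
#'   or `c(NA, NA)` with attribute `flagged = TRUE` when fewer than two peaks
#'   clear the floor.
#' @export
detect_pole_peaks <- function(profile, prominence_floor = NULL) {
  stopifnot(is.numeric(profile))
  if (length(profile) < 16) abort("profile must have at least 16 samples.")
  floor_ <- if (is.null(prominence_floor)) 3 * mad(profile) else prominence_floor
  pk <- local_peaks(profile)
  pk <- pk[pk$prominence > floor_, ]
  if (nrow(pk) < 2) {
    return(structure(c(NA_real_, NA_real_), flagged = TRUE))
  }
  center <- (length(profile) - 1) / 2
  pk <- pk[order(-pk$prominence, abs(pk$index - 1 - center)), ]
  structure(sort(pk$index[1:2] - 1), flagged = FALSE)
}

#' Sub-pixel peak refinement by Gaussian fitting
#'
#' Least-squares fit of `f(x) = a * exp(-((x - b) / c)^2) + d` to the
#' profile in a window around an initial peak position, returning the
#' sub-pixel center `b`. Note the width convention: the exponent carries no
#' factor 2, so `c` is sqrt(2) times the usual Gaussian sigma.
#'
#' @param profile Intensity vector.
#' @param center Initial center (0-based pixel).
#' @param window Half-width of the fit window (pixels). Default 5; the
#'   window must retain at least 7 samples after clipping at the profile
#'   edges (clipping is flagged).
#' @param pixel_um Optional pixel size; when given, `center_um` is filled in.
#'
#' @return Object of class `peak_fit` with `a`, `b`, `c`, `d`, `center_px`,
#'   `center_um`, `flagged` (non-convergence: falls back to the initial
#'   center), `clipped`.
#' @export
refine_peak_gaussian <- function(profile, center, window = 5, pixel_um = NULL) {
  stopifnot(is.numeric(profile), is.finite(center), window >= 3)
  n <- length(profile)
  i_lo <- max(0, round(center) - window)
  i_hi <- min(n - 1, round(center) + window)
  clipped <- (i_hi - i_lo) < 2 * window
  x <- seq(i_lo, i_hi)
  y <- profile[x + 1]
  if (length(x) < 7) {
    return(new_peak_fit(NA, center, NA, NA, center, pixel_um,
                        flagged = TRUE, clipped = TRUE))
  }
  st <- list(a = max(y) - min(y), b = center,
             c = max(window / 2, 1), d = min(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-((x - b) / c)^2) + d,
                      data = data.frame(x = x, y = y), start = st,
                      lower = c(0, i_lo, 1e-3, -Inf),
                      upper = c(Inf, i_hi, Inf, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_peak_fit(st$a, center, st$c, st$d, center, pixel_um,
                        flagged = TRUE, clipped = clipped))
  }
  p <- as.list(coef(fit))
  new_peak_fit(p$a, p$b, p$c, p$d, p$b, pixel_um,
               flagged = FALSE, clipped = clipped)
}

new_peak_fit <- function(a, b, c, d, center_px, pixel_um, flagged, clipped) {
  structure(list(a = a, b = b, c = c, d = d, center_px = center_px,
                 center_um = if (is.null(pixel_um)) NA_real_ else center_px * pixel_um,
                 flagged = flagged, clipped = clipped),
            class = "peak_fit")
}

#' Extract calibrated distance trajectories from a kymograph pair
#'
#' Per frame: detect and refine the two spindle-pole peaks in the pole
#' channel, then detect and refine the chromosome-plate peaks within the
#' interval bounded by the poles. Before plate separation the chromosome
#' signal is a single merged peak; such frames carry `d_cc_um = 0` from the
#' single center. Frames with failed detections carry `NA`, never fabricated
#' positions.
#'
#' @param kymo_poles,kymo_chrom [kymograph()] objects with matching frame
#'   counts and calibration.
#' @param window Gaussian refinement half-width (px). Default 5.
#'
#' @return Trajectory tibble with `frame` (0-based), `t_s`, `d_pp_um`,
#'   `d_cc_um`, `d_pc_um` (mean pole-to-nearest-plate distance), `flagged`.
#' @export
extract_tracks <- function(kymo_poles, kymo_chrom, window = 5) {
  stopifnot(inherits(kymo_poles, "kymograph"), inherits(kymo_chrom, "kymograph"))
  if (nrow(kymo_poles$intensity) != nrow(kymo_chrom$intensity) ||
      kymo_poles$pixel_um != kymo_chrom$pixel_um ||
      kymo_poles$frame_s != kymo_chrom$frame_s) {
    abort("pole and chromosome kymographs must have matching frame counts and calibration.")
  }
  px <- kymo_poles$pixel_um
  n_frames <- nrow(kymo_poles$intensity)

  purrr::map_dfr(seq_len(n_frames), function(f) {
    row <- tibble::tibble(frame = f - 1L, t_s = (f - 1) * kymo_poles$frame_s,
                          d_pp_um = NA_real_, d_cc_um = NA_real_,
                          d_pc_um = NA_real_, flagged = TRUE)
    pp <- kymo_poles$intensity[f, ]
    init <- detect_pole_peaks(pp)
    if (any(is.na(init))) return(row)
    f1 <- refine_peak_gaussian(pp, init[1], window)
    f2 <- refine_peak_gaussian(pp, init[2], window)
    if (f1$flagged || f2$flagged) return(row)
    poles <- sort(c(f1$center_px, f2$center_px))
    row$d_pp_um <- diff(poles) * px

    cp <- kymo_chrom$intensity[f, ]
    j_lo <- max(0L, ceiling(poles[1]))
    j_hi <- min(length(cp) - 1L, floor(poles[2]))
    if (j_hi - j_lo + 1 < 16) return(row)
    sub <- cp[(j_lo:j_hi) + 1]
    cinit <- suppressWarnings(detect_pole_peaks(sub))
    if (any(is.na(cinit))) {
      # single merged peak before plate separation
      pk <- local_peaks(sub)
      pk <- pk[pk$prominence > 3 * mad(sub), ]
      if (nrow(pk) < 1) return(row)
      cinit <- rep(pk$index[which.max(pk$prominence)] - 1, 2)
    }
    g1 <- refine_peak_gaussian(cp, j_lo + cinit[1], window)
    g2 <- refine_peak_gaussian(cp, j_lo + cinit[2], window)
    if (g1$flagged || g2$flagged) return(row)
    chrom <- sort(c(g1$center_px, g2$center_px))
    if (chrom[1] < poles[1] || chrom[2] > poles[2]) return(row)
    row$d_cc_um <- diff(chrom) * px
    row$d_pc_um <- mean(c(chrom[1] - poles[1], poles[2] - chrom[2])) * px
    row$flagged <- FALSE
    row
  })
}

#' Anisotropic Euclidean distance between voxel coordinates
#'
#' @param p1,p2 Voxel-coordinate triples (finite).
#' @param voxel_size Physical voxel size per axis (um). Default
#'   `c(0.1, 0.1, 0.5)`.
#' @return Distance in um: `sqrt(sum(((p1 - p2) * voxel_size)^2))`.
#' @examples
#' euclidean_distance(c(10, 10, 5), c(13, 14, 5)) # 0.5
#' @export
euclidean_distance <- function(p1, p2, voxel_size = c(0.1, 0.1, 0.5)) {
  stopifnot(length(p1) == length(p2), length(p1) == length(voxel_size))
  if (any(!is.finite(c(p1, p2)))) abort("coordinates must be finite.")
  sqrt(sum(((p1 - p2) * voxel_size)^2))
}

#' Detect anaphase onset from a chromosome-separation series
#'
#' Anaphase onset (AO) is the last time point before the chromosome plates
#' separate. The pre-rise baseline is taken from frames before the series
#' first exceeds a quarter of its range; AO is the last frame before the
#' series exceeds `median(baseline) + 3 * mad(baseline)` for at least two
#' consecutive frames.
#'
#' @param d_cc Numeric chromosome-to-chromosome distance series.
#' @return 0-based frame index of AO, or `NA` with attribute `flagged = TRUE`
#'   when no sustained rise exists.
#' @export
detect_anaphase_onset <- function(d_cc) {
  stopifnot(is.numeric(d_cc), length(d_cc) >= 3)
  rng <- diff(range(d_cc, na.rm = TRUE))
  if (!is.finite(rng) || rng <= 1e-12 * max(1, abs(mean(d_cc, na.rm = TRUE)))) {
    return(structure(NA_integer_, flagged = TRUE))
  }
  first_up <- which(d_cc > min(d_cc, na.rm = TRUE) + 0.25 * rng)[1]
  if (is.na(first_up)) return(structure(NA_integer_, flagged = TRUE))
  if (first_up == 1) return(structure(0L, flagged = FALSE))
  base <- d_cc[seq_len(first_up - 1)]
  thr <- median(base) + 3 * mad(base)
  above <- d_cc > thr
  sustained <- which(above & c(above[-1], FALSE))
  if (length(sustained) == 0) return(structure(NA_integer_, flagged = TRUE))
  structure(as.integer(sustained[1] - 2L), flagged = FALSE)
}
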