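#' Near-equal-area spherical surface mesh
#'
#' Deterministic generative-spiral (Fibonacci) lattice on the sphere, used as
#' the quadrature rule for the cortical force integral. The lattice is
#' antipodally symmetrized (half the patches are spiral points, half their
#' antipodes) so that mirror-symmetric pole configurations experience exactly
#' mirror-symmetric forces. Every patch carries the same area
#' `4 pi R^2 / n`, so the total area is exact and refinement is controlled
#' purely by `n_patches`.
#'
#' @param radius Cell radius R (um).
#' @param n_patches Number of surface patches (rounded up to even); at least
#'   128 (coarser meshes make the force quadrature unreliable). Default 2000.
#'
#' @return An object of class `surface_mesh`: list with `centers` (n x 3
#'   matrix of patch centers on the sphere, um), `areas` (length-n vector,
#'   um^2), and `radius`.
#' @examples
#' mesh <- build_cell_mesh(23)
#' sum(mesh$areas) / (4 * pi * 23^2) # 1 by construction
#' @export
build_cell_mesh <- function(radius, n_patches = 2000) {
  stopifnot(is.numeric(radius), length(radius) == 1, radius > 0)
  if (!is.numeric(n_patches) || n_patches < 128) {
    abort("`n_patches` must be >= 128: coarser meshes are too crude for the cortical force quadrature.")
  }
  n <- as.integer(n_patches)
  if (n %% 2 == 1) n <- n + 1L
  half <- n %/% 2L
  i <- seq_len(half) - 1L
  z <- 1 - (2 * i + 1) / half
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  spiral <- radius * cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
  centers <- rbind(spiral, -spiral)
  structure(
    list(centers = centers,
         areas = rep(4 * pi * radius^2 / n, n),
         radius = radius),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> R:", x$radius, "um ", nrow(x$centers), "patches, total area",
      format(sum(x$areas), digits = 6), "um^2\n")
  invisible(x)
}
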