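# Reciprocal-space intensity volumes and real-space density volumes.

#' Reciprocal-space intensity volume
#'
#' A cubic grid of nonnegative intensities `I(q)` with voxel size `voxel_size`
#' (Angstrom^-1). EMC reconstruction grids must have an odd edge so the
#' forward-scattering voxel sits exactly at the grid midpoint; even edges
#' (half-integer center) are accepted for phasing-stage arrays produced by
#' trimming and binning.
#'
#' @param values 3D numeric array (cube).
#' @param voxel_size Voxel edge in Angstrom^-1.
#' @param mask Optional logical array, `TRUE` for voxels excluded from
#'   likelihoods/metrics (beamstop/missing).
#' @param metadata Free-form provenance list (prefactor, seeds, ...).
#' @return Object of class `intensity_volume`.
#' @export
intensity_volume <- function(values, voxel_size, mask = NULL, metadata = list()) {
  d <- dim(values)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop("'values' must be a cubic 3D array")
  if (!is.numeric(voxel_size) || voxel_size <= 0)
    stop("'voxel_size' must be a positive Angstrom^-1 value")
  if (any(values < 0, na.rm = TRUE))
    stop("intensities must be nonnegative")
  if (!is.null(mask) && !identical(dim(mask), d))
    stop("'mask' must match the grid shape")
  # center at the FFT zero-frequency bin: the midpoint voxel for odd edges
  v <- list(values = values, voxel_size = voxel_size,
            edge = d[1], center = floor(d[1] / 2) + 1,
            mask = mask, metadata = metadata)
  class(v) <- "intensity_volume"
  v
}

#' @exportS3Method base::print
print.intensity_volume <- function(x, ...) {
  cat(sprintf("intensity_volume: %d^3 voxels, dq = %.6g A^-1 (q_max %.4g A^-1)\n",
              x$edge, x$voxel_size, (x$edge - 1) / 2 * x$voxel_size))
  invisible(x)
}

#' Radial voxel distances from the volume center
#' @param volume An [intensity_volume()].
#' @return Array of voxel distances from the center bin, in voxels.
#' @export
voxel_radii <- function(volume) {
  n <- volume$edge; c0 <- volume$center
  x <- (1:n) - c0
  r2 <- outer(outer(x^2, x^2, `+`), x^2, `+`)
  sqrt(r2)
}

#' Scattering-vector magnitude per voxel
#' @param volume An [intensity_volume()].
#' @return Array of `|q|` values in Angstrom^-1.
#' @export
voxel_q <- function(volume) voxel_radii(volume) * volume$voxel_size

#' Friedel-symmetrize a volume in place
#'
#' Intensities of a real electron density are centrosymmetric; averaging a
#' volume with its point reflection enforces that exactly on an odd grid.
#'
#' @param volume An [intensity_volume()] with odd edge.
#' @return The symmetrized volume.
#' @export
friedel_symmetrize <- function(volume) {
  n <- volume$edge
  if (n %% 2 == 0L) stop("Friedel symmetrization requires an odd grid edge")
  v <- volume$values
  volume$values <- (v + v[n:1, n:1, n:1]) / 2
  volume
}

#' Real-space electron-density volume
#'
#' @param density 3D numeric array, electrons per voxel after conversion.
#' @param voxel_size Real-space voxel edge in nanometres.
#' @param support Optional logical array marking the support.
#' @param metadata Provenance list.
#' @return Object of class `real_space_volume`.
#' @export
real_space_volume <- function(density, voxel_size, support = NULL,
                              metadata = list()) {
  d <- dim(density)
  if (length(d) != 3L) stop("'density' must be a 3D array")
  if (!is.null(support) && !identical(dim(support), d))
    stop("'support' must match the density shape")
  v <- list(density = density, voxel_size = voxel_size, support = support,
            metadata = metadata)
  class(v) <- "real_space_volume"
  v
}

#' @exportS3Method base::print
print.real_space_volume <- function(x, ...) {
  cat(sprintf("real_space_volume: %s voxels, %.3g nm/voxel, total %.4g e-\n",
              paste(dim(x$density), collapse = "x"), x$voxel_size,
              sum(x$density)))
  invisible(x)
}
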