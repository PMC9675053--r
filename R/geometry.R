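# Detector/beam geometry: per-pixel scattering vectors on the Ewald sphere,
# solid angles, Thomson factors, and the fluence/oversampling/resolution
# arithmetic of a small-angle diffraction camera.

# conversion constant lambda[A] = HC_KEV_A / E[keV]; documented so derived
# quantities are bit-stable
.HC_KEV_A <- 12.3984
# classical electron radius in cm
.RE_CM <- 2.8179403262e-13
# one keV in joule
.KEV_J <- 1.602176634e-16

#' Detector geometry
#'
#' Describes a flat square-pixel detector facing the beam, with the beam
#' center at the array midpoint (pixel centers at integer coordinates, so an
#' even array has a half-integer center) and an optional circular beamstop.
#'
#' @param sdd Sample-to-detector distance in metres.
#' @param pixel_size Pixel pitch in metres.
#' @param shape Integer vector `c(rows, cols)`.
#' @param photon_energy Photon energy in keV.
#' @param beamstop_radius Beamstop radius in pixels (0 disables).
#' @param beam_center Optional beam center `c(row, col)` in 1-based pixel
#'   coordinates; defaults to the array midpoint.
#' @return An object of class `detector_geometry` with the derived
#'   wavelength (in Angstrom) attached.
#' @export
detector_geometry <- function(sdd, pixel_size, shape = c(550L, 550L),
                              photon_energy = 6, beamstop_radius = 0,
                              beam_center = NULL) {
  if (!is.numeric(sdd) || length(sdd) != 1L || !is.finite(sdd) || sdd <= 0)
    stop("invalid geometry: 'sdd' must be a positive length in metres")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("invalid geometry: 'pixel_size' must be a positive length in metres")
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- c(shape, shape)
  if (any(shape < 1L)) stop("invalid geometry: 'shape' must be positive")
  if (photon_energy <= 0) stop("invalid geometry: 'photon_energy' must be > 0 keV")
  if (beamstop_radius < 0) stop("invalid geometry: 'beamstop_radius' must be >= 0")
  if (is.null(beam_center)) beam_center <- (shape + 1) / 2
  g <- list(sdd = sdd, pixel_size = pixel_size, shape = shape,
            beam_center = beam_center, photon_energy = photon_energy,
            wavelength = .HC_KEV_A / photon_energy,
            beamstop_radius = beamstop_radius)
  class(g) <- "detector_geometry"
  g
}

#' @exportS3Method base::print
print.detector_geometry <- function(x, ...) {
  cat(sprintf("detector_geometry: %d x %d px, pitch %.0f um, SDD %.3f m\n",
              x$shape[1], x$shape[2], x$pixel_size * 1e6, x$sdd))
  cat(sprintf("  photon energy %.3f keV (lambda %.4f A), beamstop %.1f px\n",
              x$photon_energy, x$wavelength, x$beamstop_radius))
  invisible(x)
}

#' Beam parameters and fluence
#'
#' The pulse is characterised by its energy, the optics transmission and a
#' flat-top focus rectangle given by the two FWHM values; the fluence is the
#' photon count divided by the FWHM rectangle area.
#'
#' @param pulse_energy Pulse energy in joules.
#' @param optics_efficiency Transmission of the optics, in (0, 1].
#' @param focus_fwhm Focus FWHM `c(x, y)` in metres.
#' @param photon_energy Photon energy in keV.
#' @return An object of class `beam_parameters` with `fluence` (photons/cm^2)
#'   and `n_photons` (photons per pulse) attached.
#' @export
beam_parameters <- function(pulse_energy, optics_efficiency, focus_fwhm,
                            photon_energy = 6) {
  if (photon_energy <= 0) stop("'photon_energy' must be > 0 keV")
  if (pulse_energy < 0) stop("'pulse_energy' must be >= 0")
  if (optics_efficiency <= 0 || optics_efficiency > 1)
    stop("'optics_efficiency' must be in (0, 1]")
  if (length(focus_fwhm) != 2L || any(focus_fwhm <= 0))
    stop("'focus_fwhm' must be two positive lengths in metres")
  n_ph <- pulse_energy * optics_efficiency / (photon_energy * .KEV_J)
  area_cm2 <- prod(focus_fwhm * 100)
  b <- list(pulse_energy = pulse_energy, optics_efficiency = optics_efficiency,
            focus_fwhm = focus_fwhm, photon_energy = photon_energy,
            n_photons = n_ph, fluence = n_ph / area_cm2)
  class(b) <- "beam_parameters"
  b
}

#' @exportS3Method base::print
print.beam_parameters <- function(x, ...) {
  cat(sprintf("beam_parameters: %.2f mJ, %.0f%% optics, %.0f x %.0f nm^2 FWHM focus\n",
              x$pulse_energy * 1e3, x$optics_efficiency * 100,
              x$focus_fwhm[1] * 1e9, x$focus_fwhm[2] * 1e9))
  cat(sprintf("  %.3g photons/pulse on sample, fluence %.3g photons/cm^2\n",
              x$n_photons, x$fluence))
  invisible(x)
}

#' Fluence on the sample
#'
#' @param beam A [beam_parameters()] object.
#' @return Fluence in photons/cm^2.
#' @export
fluence <- function(beam) {
  stopifnot(inherits(beam, "beam_parameters"))
  beam$fluence
}

# exact solid angle of an axis-aligned rectangle [x1,x2]x[y1,y2] at normal
# distance d (sum of four right-pyramid corner terms)
.rect_solid_angle <- function(x1, x2, y1, y2, d) {
  f <- function(x, y) atan2(x * y, d * sqrt(x^2 + y^2 + d^2))
  f(x2, y2) - f(x1, y2) - f(x2, y1) + f(x1, y1)
}

#' Per-pixel scattering-vector map
#'
#' Computes, for every pixel, the scattering vector `q` on the Ewald sphere
#' (`|q| = 4 pi sin(theta) / lambda`, Angstrom^-1), the exact solid angle
#' subtended by the pixel, and the differential Thomson cross section
#' (cm^2/sr) including the polarization factor.
#'
#' @param geometry A [detector_geometry()].
#' @param polarization One of `"horizontal"` (default; factor
#'   `1 - (sin(2 theta) cos(phi))^2`), `"vertical"`, or `"unpolarized"`
#'   (`(1 + cos^2(2 theta))/2`).
#' @return An object of class `qmap` holding `q_vectors` (npix x 3 matrix,
#'   pixels in column-major order), `q_magnitudes`, `solid_angles`,
#'   `thomson_factors` (rows x cols matrices), and the geometry.
#' @export
build_qmap <- function(geometry,
                       polarization = c("horizontal", "vertical", "unpolarized")) {
  stopifnot(inherits(geometry, "detector_geometry"))
  polarization <- match.arg(polarization)
  rows <- geometry$shape[1]; cols <- geometry$shape[2]
  px <- geometry$pixel_size; d <- geometry$sdd
  # lab coordinates: beam along +z, detector rows along y, columns along x
  ix <- rep(seq_len(rows), times = cols)
  jx <- rep(seq_len(cols), each = rows)
  y <- (ix - geometry$beam_center[1]) * px
  x <- (jx - geometry$beam_center[2]) * px
  r <- sqrt(x^2 + y^2)
  rr <- sqrt(r^2 + d^2)
  two_theta <- atan2(r, d)
  lambda <- geometry$wavelength
  k <- 2 * pi / lambda                       # A^-1
  # q = k_out - k_in on the Ewald sphere
  qx <- k * x / rr
  qy <- k * y / rr
  qz <- k * (d / rr - 1)
  qmag <- sqrt(qx^2 + qy^2 + qz^2)
  omega <- .rect_solid_angle(x - px / 2, x + px / 2, y - px / 2, y + px / 2, d)
  phi <- atan2(y, x)
  pol <- switch(polarization,
    horizontal  = 1 - (sin(two_theta) * cos(phi))^2,
    vertical    = 1 - (sin(two_theta) * sin(phi))^2,
    unpolarized = (1 + cos(two_theta)^2) / 2)
  qm <- list(
    q_vectors = cbind(qx, qy, qz, deparse.level = 0),
    q_magnitudes = matrix(qmag, rows, cols),
    solid_angles = matrix(omega, rows, cols),
    thomson_factors = matrix(.RE_CM^2 * pol, rows, cols),
    two_theta = matrix(two_theta, rows, cols),
    polarization = polarization,
    geometry = geometry)
  class(qm) <- "qmap"
  qm
}

#' Beamstop mask
#'
#' @param geometry A [detector_geometry()].
#' @return Logical rows x cols matrix, `TRUE` where the beamstop blocks the
#'   pixel (pixel-center distance from the beam center below the beamstop
#'   radius).
#' @export
beamstop_mask <- function(geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  rows <- geometry$shape[1]; cols <- geometry$shape[2]
  i <- matrix(seq_len(rows), rows, cols)
  j <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  r <- sqrt((i - geometry$beam_center[1])^2 + (j - geometry$beam_center[2])^2)
  r <= geometry$beamstop_radius
}

#' One-dimensional oversampling ratio
#'
#' `SDD * lambda / (pixel_size * L)`: the linear sampling rate of the
#' continuous diffraction pattern relative to the particle's Nyquist rate;
#' must exceed 2 for phase retrieval to be well posed.
#'
#' @param geometry A [detector_geometry()].
#' @param particle_size Particle size L in nanometres.
#' @return Unitless ratio.
#' @export
oversampling_ratio <- function(geometry, particle_size) {
  stopifnot(inherits(geometry, "detector_geometry"))
  if (!is.numeric(particle_size) || particle_size <= 0)
    stop("'particle_size' must be a positive length in nm")
  lambda_m <- geometry$wavelength * 1e-10
  geometry$sdd * lambda_m / (geometry$pixel_size * particle_size * 1e-9)
}

#' Full-period resolution at the detector edge
#'
#' Reports `D = 2 pi / |q|` at the midpoint of the detector edge and at the
#' corner. The two values bracket the conventions in use for quoting "edge
#' resolution" (the corner lies on the diagonal of the array).
#'
#' @param geometry A [detector_geometry()].
#' @return List with `edge_nm` (edge midpoint) and `corner_nm`.
#' @export
edge_resolution <- function(geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  # distance from the beam center to the physical array edge/corner
  r_edge <- min(geometry$shape) / 2 * geometry$pixel_size
  r_corner <- sqrt(sum((geometry$shape / 2)^2)) * geometry$pixel_size
  q_at <- function(r) {
    theta <- atan2(r, geometry$sdd) / 2
    4 * pi * sin(theta) / geometry$wavelength   # A^-1
  }
  list(edge_nm = 2 * pi / q_at(r_edge) / 10,
       corner_nm = 2 * pi / q_at(r_corner) / 10)
}

#' Beamstop physical diameter
#'
#' @param geometry A [detector_geometry()].
#' @return Beamstop diameter in millimetres (`2 * radius_px * pixel_size`).
#' @export
beamstop_diameter_mm <- function(geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  2 * geometry$beamstop_radius * geometry$pixel_size * 1e3
}
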