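# YAML configuration files: instrument blocks (geometry/beam/noise) and
# noise-model files, so studies can be described outside R code.

#' Read an instrument configuration
#'
#' Reads a YAML file with `geometry`, `beam` and optional `noise` blocks:
#'
#' ```yaml
#' geometry: {sdd_m: 0.25, pixel_um: 200, shape: [550, 550],
#'            photon_keV: 6, beamstop_px: 5}
#' beam:     {pulse_mJ: 4, efficiency: 0.38, focus_fwhm_nm: [250, 150]}
#' noise:    standard   # or low_noise, or a noise-model file path
#' ```
#'
#' @param path YAML file path.
#' @return List with `geometry` ([detector_geometry()]), `beam`
#'   ([beam_parameters()]), and `noise` (a [noise_model()] or
#'   `"poisson_only"`).
#' @export
read_instrument_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$geometry
  if (is.null(g)) stop("config lacks a 'geometry' block")
  geometry <- detector_geometry(
    sdd = g$sdd_m, pixel_size = g$pixel_um * 1e-6,
    shape = unlist(g$shape), photon_energy = g$photon_keV,
    beamstop_radius = if (is.null(g$beamstop_px)) 0 else g$beamstop_px)
  b <- cfg$beam
  if (is.null(b)) stop("config lacks a 'beam' block")
  beam <- beam_parameters(
    pulse_energy = b$pulse_mJ * 1e-3, optics_efficiency = b$efficiency,
    focus_fwhm = unlist(b$focus_fwhm_nm) * 1e-9,
    photon_energy = g$photon_keV)
  noise <- cfg$noise
  if (is.null(noise)) {
    noise <- "poisson_only"
  } else if (noise %in% c("standard", "low_noise")) {
    noise <- agipd_noise_model(noise, photon_energy = g$photon_keV)
  } else if (!identical(noise, "poisson_only")) {
    noise <- read_noise_model(noise)
  }
  list(geometry = geometry, beam = beam, noise = noise)
}

#' Write a noise model to a YAML file
#'
#' @param noise A [noise_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_noise_model <- function(noise, path) {
  stopifnot(inherits(noise, "noise_model"))
  yaml::write_yaml(list(peaks_keV = noise$peaks_keV,
                        sigmas_keV = noise$sigmas_keV,
                        sigma_avg_keV = noise$sigma_avg,
                        photon_keV = noise$photon_energy,
                        label = noise$label), path)
  invisible(path)
}

#' Read a noise model from a YAML file
#'
#' @param path File written by [write_noise_model()] (or hand-authored with
#'   `peaks_keV`, `sigmas_keV`, `photon_keV`, `label`).
#' @return A [noise_model()].
#' @export
read_noise_model <- function(path) {
  y <- yaml::read_yaml(path)
  noise_model(unlist(y$peaks_keV), unlist(y$sigmas_keV),
              photon_energy = y$photon_keV,
              label = if (is.null(y$label)) "file" else y$label)
}
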