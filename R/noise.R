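# Parametric integrating-detector noise: Gaussian photon peaks measured from
# single-pixel calibration histograms, photon-energy scaling, corruption of
# photon maps, and threshold photonization back to integers.

#' Detector noise model
#'
#' Photon-count peak positions and Gaussian widths of an integrating pixel
#' detector at low occupancy. Peaks at k = 0, 1, 2 photons are measured;
#' beyond k = 2 the position is extrapolated with the last measured interval
#' and sigma follows the linear fit `sigma(k) = sigma_intercept +
#' sigma_slope * k` through the measured widths.
#'
#' @param peaks_keV Peak positions in keV for k = 0, 1, 2, ...
#' @param sigmas_keV Gaussian widths in keV, same length as `peaks_keV`.
#' @param photon_energy Photon energy (keV) the peak positions refer to.
#' @param label Optional configuration label.
#' @return Object of class `noise_model` with `sigma_slope`,
#'   `sigma_intercept` and `sigma_avg` attached.
#' @export
noise_model <- function(peaks_keV, sigmas_keV, photon_energy, label = "custom") {
  if (length(peaks_keV) != length(sigmas_keV) || length(peaks_keV) < 2L)
    stop("need matching peak/sigma vectors for at least k = 0, 1")
  if (any(sigmas_keV <= 0)) stop("all sigma values must be positive")
  if (photon_energy <= 0) stop("'photon_energy' must be > 0 keV")
  k <- seq_along(peaks_keV) - 1
  fit <- stats::lm(sigmas_keV ~ k)
  nm <- list(peaks_keV = peaks_keV, sigmas_keV = sigmas_keV,
             sigma_intercept = unname(stats::coef(fit)[1]),
             sigma_slope = unname(stats::coef(fit)[2]),
             sigma_avg = mean(sigmas_keV),
             photon_energy = photon_energy, label = label)
  class(nm) <- "noise_model"
  nm
}

#' @exportS3Method base::print
print.noise_model <- function(x, ...) {
  cat(sprintf("noise_model '%s' at %.3g keV\n", x$label, x$photon_energy))
  cat(sprintf("  peaks: %s keV\n", paste(sprintf("%.3g", x$peaks_keV), collapse = ", ")))
  cat(sprintf("  sigma: %s keV (sigma_avg %.3g, separation %.3g sigma_avg)\n",
              paste(sprintf("%.3g", x$sigmas_keV), collapse = ", "),
              x$sigma_avg, peak_separation(x)))
  invisible(x)
}

# nominal Cu K-alpha fluorescence energy used for the stored calibrations
.CU_KA_NOMINAL_KEV <- 8.0

#' Stored AGIPD-style noise configurations
#'
#' Two parameter sets measured from single-pixel Cu fluorescence histograms:
#' the standard dynamic-range configuration (one-photon peak 8.09 keV,
#' two-photon 15.88 keV, sigma_avg 1.49 keV) and the low-noise configuration
#' (8.15/16.02 keV, sigma_avg 1.13 keV). The stored widths use
#' `sigma(k) = sigma_avg` for every k, the simplest model consistent with
#' the published averages; supply your own histogram to [fit_calibration()]
#' for per-peak widths. Peak positions are scaled from the nominal 8 keV
#' fluorescence energy to `photon_energy` (sigma stays in keV).
#'
#' @param config `"standard"` or `"low_noise"`.
#' @param photon_energy Target photon energy in keV (default 6).
#' @return A [noise_model()].
#' @export
agipd_noise_model <- function(config = c("standard", "low_noise"),
                              photon_energy = 6) {
  config <- match.arg(config)
  nm <- switch(config,
    standard  = noise_model(c(0, 8.09, 15.88), rep(1.49, 3),
                            .CU_KA_NOMINAL_KEV, "standard"),
    low_noise = noise_model(c(0, 8.15, 16.02), rep(1.13, 3),
                            .CU_KA_NOMINAL_KEV, "low_noise"))
  scale_to_photon_energy(nm, photon_energy)
}

#' Rescale peak positions to a different photon energy
#'
#' Peak positions scale linearly with the photon energy
#' (`target / photon_energy`); the Gaussian widths are an electronics
#' property and stay in keV.
#'
#' @param noise A [noise_model()].
#' @param target Target photon energy in keV.
#' @return Rescaled [noise_model()].
#' @export
scale_to_photon_energy <- function(noise, target) {
  stopifnot(inherits(noise, "noise_model"))
  if (target <= 0) stop("'target' must be > 0 keV")
  noise_model(noise$peaks_keV * target / noise$photon_energy,
              noise$sigmas_keV, target, noise$label)
}

#' Peak separation in units of sigma_avg
#'
#' `peak_position(1) / sigma_avg`: the figure of merit that governs
#' photonization error rates.
#'
#' @param noise A [noise_model()].
#' @return Unitless separation.
#' @export
peak_separation <- function(noise) {
  stopifnot(inherits(noise, "noise_model"))
  noise$peaks_keV[2] / noise$sigma_avg
}

# peak position / sigma for arbitrary photon count k (vectorized)
peak_position <- function(noise, k) {
  p <- noise$peaks_keV
  nk <- length(p) - 1L
  step <- p[nk + 1L] - p[nk]
  ifelse(k <= nk, p[pmin(k, nk) + 1L], p[nk + 1L] + (k - nk) * step)
}

peak_sigma <- function(noise, k) {
  s <- noise$sigmas_keV
  nk <- length(s) - 1L
  ifelse(k <= nk, s[pmin(k, nk) + 1L],
         noise$sigma_intercept + noise$sigma_slope * k)
}

#' Fit a noise model to a calibration histogram
#'
#' Fits a Gaussian mixture with `n_peaks` components to single-pixel keV
#' readouts (via `mclust`, unequal variances), orders components by mean,
#' and derives the linear sigma(k) fit and sigma_avg.
#'
#' @param samples Numeric vector of per-readout values in keV, or a list
#'   with element `values` (as returned by [make_calibration_samples()]).
#' @param n_peaks Number of photon peaks to resolve (including k = 0).
#' @param photon_energy Photon energy label for the resulting model
#'   (defaults to the fitted one-photon peak position).
#' @return A [noise_model()].
#' @export
fit_calibration <- function(samples, n_peaks = 3L, photon_energy = NULL) {
  if (is.list(samples)) samples <- samples$values
  samples <- as.numeric(samples)
  if (length(samples) < 1000L)
    stop("too few samples to resolve ", n_peaks, " peaks (need >= 1000)")
  if (!all(is.finite(samples))) stop("non-finite calibration samples")
  if (n_peaks == 1L) {
    mu <- mean(samples); sd1 <- stats::sd(samples)
    return(noise_model(c(mu, mu + 1), c(sd1, sd1),
                       if (is.null(photon_energy)) 1 else photon_energy,
                       "fitted"))
  }
  # initialize at the photon-peak ladder: the noise peak sits at the sample
  # median (>= ~80% of mass at calibration occupancies) and the one-photon
  # peak at the median of the clearly-separated high readouts
  mu0 <- stats::median(samples)
  s0 <- stats::mad(samples)
  high <- samples[samples > mu0 + 4 * s0]
  unit <- if (length(high) >= 10) stats::median(high) - mu0 else 6 * s0
  means0 <- mu0 + (seq_len(n_peaks) - 1) * unit
  assign0 <- pmin(pmax(round((samples - mu0) / unit), 0), n_peaks - 1)
  pro0 <- as.numeric(table(factor(assign0, levels = 0:(n_peaks - 1)))) /
    length(samples)
  if (any(pro0 == 0))
    stop("fewer modes than requested: no samples near peak(s) ",
         paste(which(pro0 == 0) - 1, collapse = ", "))
  z0 <- matrix(1e-6, length(samples), n_peaks)
  z0[cbind(seq_along(samples), assign0 + 1L)] <- 1
  z0 <- z0 / rowSums(z0)
  # mclust dispatches model-specific workers by name in the caller frame
  mstepV <- mclust::mstepV
  emV <- mclust::emV
  ms <- mclust::mstep(data = samples, modelName = "V", z = z0)
  fit <- mclust::em(data = samples, modelName = "V",
                    parameters = ms$parameters)
  if (is.null(fit) || is.null(fit$parameters) ||
      any(!is.finite(fit$parameters$mean)))
    stop("mixture fit did not converge for ", n_peaks, " peaks; ",
         "initial means ", paste(signif(means0, 4), collapse = ", "))
  ord <- order(fit$parameters$mean)
  means <- as.numeric(fit$parameters$mean[ord])
  sds <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sds) == 1L) sds <- rep(sds, n_peaks)
  sds <- sds[ord]
  if (any(diff(means) < 2 * .Machine$double.eps))
    stop("fewer distinct modes than requested: fitted means ",
         paste(signif(means, 4), collapse = ", "))
  if (is.null(photon_energy)) photon_energy <- means[2] - means[1]
  noise_model(means, sds, photon_energy, "fitted")
}

#' Corrupt a photon map with detector noise
#'
#' Each pixel holding k photons is replaced by a draw from
#' `Normal(peak_position(k), sigma(k))`; pixels are independent. `NA`
#' (masked) pixels stay `NA`.
#'
#' @param photons Integer vector/matrix of photon counts.
#' @param noise A [noise_model()] scaled to the experiment's photon energy.
#' @return Numeric keV map with the shape of `photons`.
#' @export
corrupt <- function(photons, noise) {
  stopifnot(inherits(noise, "noise_model"))
  k <- as.integer(photons)
  ok <- !is.na(k)
  out <- rep(NA_real_, length(k))
  out[ok] <- stats::rnorm(sum(ok), peak_position(noise, k[ok]),
                          peak_sigma(noise, k[ok]))
  if (!is.null(dim(photons))) dim(out) <- dim(photons)
  out
}

#' Photonize keV readouts back to integer photons
#'
#' Divides by the one-photon peak position and rounds to the nearest
#' nonnegative integer: values below 0.5 photon units give 0 photons, values
#' between 0.5 and 1.5 give 1, and so on. Negative readouts (noise below
#' pedestal) are legal and give 0.
#'
#' @param values Numeric keV map.
#' @param noise A [noise_model()] defining the photon unit.
#' @return Integer photon map with the shape of `values`.
#' @export
photonize <- function(values, noise) {
  stopifnot(inherits(noise, "noise_model"))
  unit <- noise$peaks_keV[2] - noise$peaks_keV[1]
  k <- pmax(0, round((values - noise$peaks_keV[1]) / unit))
  out <- as.integer(k)
  if (!is.null(dim(values))) dim(out) <- dim(values)
  out
}
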