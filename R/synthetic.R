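# Generators for every input the pipeline needs without downloads: atomic
# phantoms, single-pixel calibration histograms, and complete noisy
# snapshot datasets with ground-truth orientations.

#' Random atomic phantom
#'
#' Places atoms inside a sphere by blue-noise-like rejection (a minimum
#' pairwise spacing), with elements drawn from a composition roughly
#' matching protein/RNA (the algorithms only see the resulting form
#' factors). Deterministic per seed.
#'
#' @param n_atoms Number of atoms (1 gives a single atom at the origin).
#' @param extent Phantom diameter in nm.
#' @param element_mix Named weights over elements (normalized internally).
#' @param seed RNG seed.
#' @param min_spacing Minimum interatomic distance in Angstrom.
#' @return An [atomic_model()].
#' @export
make_phantom <- function(n_atoms, extent = 4,
                         element_mix = c(C = 0.60, O = 0.20, N = 0.15, P = 0.05),
                         seed = 1L, min_spacing = 1.2) {
  if (n_atoms < 1) stop("'n_atoms' must be >= 1")
  if (extent <= 0) stop("'extent' must be a positive diameter in nm")
  atomic_number(names(element_mix))  # validates symbols
  mix <- element_mix / sum(element_mix)
  radius <- extent * 10 / 2  # A
  with_seed(seed, {
    els <- sample(names(mix), n_atoms, replace = TRUE, prob = mix)
    if (n_atoms == 1L)
      return(atomic_model(els, matrix(0, 1, 3)))
    coords <- matrix(NA_real_, n_atoms, 3)
    coords[1, ] <- 0
    placed <- 1L
    tries <- 0L
    max_tries <- 2000L * n_atoms
    while (placed < n_atoms) {
      p <- stats::runif(3, -radius, radius)
      tries <- tries + 1L
      if (tries > max_tries)
        stop("minimum spacing ", min_spacing, " A infeasible for ", n_atoms,
             " atoms in a ", extent, " nm sphere")
      if (sum(p^2) > radius^2) next
      d2 <- rowSums((coords[seq_len(placed), , drop = FALSE] -
                       matrix(p, placed, 3, byrow = TRUE))^2)
      if (min(d2) < min_spacing^2) next
      placed <- placed + 1L
      coords[placed, ] <- p
    }
    atomic_model(els, coords)
  })
}

#' Synthetic single-pixel calibration histogram
#'
#' Emulates a fluorescence calibration measurement: each readout draws a
#' photon count from Poisson(occupancy) and a keV value from the
#' corresponding photon-peak Gaussian of the noise model.
#'
#' @param noise A [noise_model()].
#' @param occupancy Mean photons per readout.
#' @param n Number of samples (a real calibration uses ~18 000).
#' @param seed RNG seed.
#' @return Object of class `calibration_histogram`: list with `values`
#'   (keV), `n`, `occupancy`.
#' @export
make_calibration_samples <- function(noise, occupancy, n = 18000L, seed = 1L) {
  stopifnot(inherits(noise, "noise_model"))
  if (occupancy < 0) stop("'occupancy' must be >= 0")
  vals <- with_seed(seed, {
    k <- stats::rpois(n, occupancy)
    stats::rnorm(n, peak_position(noise, k), peak_sigma(noise, k))
  })
  h <- list(values = vals, n = as.integer(n), occupancy = occupancy,
            label = noise$label)
  class(h) <- "calibration_histogram"
  h
}

# mean expected photons per unmasked pixel, averaged over a few fixed
# orientations (used to tune the fluence scale to a target occupancy)
.mean_expected_occupancy <- function(model, qmap, beam, n_orient = 8L) {
  quats <- with_seed(12345L, sample_orientation(n_orient))
  mu <- expected_patterns(model, qmap, beam, quats)
  mask <- as.vector(beamstop_mask(qmap$geometry))
  mean(mu[!mask, , drop = FALSE])
}

#' Generate a complete snapshot dataset
#'
#' Draws a fresh Haar-uniform orientation per snapshot, computes the
#' expected photon map, adds Poisson noise, optionally applies the detector
#' noise (Gaussian corruption then threshold photonization), and applies
#' the beamstop mask. Ground-truth orientations are stored. Three noise
#' cases mirror the study design: `"poisson_only"`, `"standard"`,
#' `"low_noise"`; a custom [noise_model()] is also accepted.
#'
#' @param model An [atomic_model()].
#' @param geometry A [detector_geometry()].
#' @param beam A [beam_parameters()].
#' @param noise Noise case name or [noise_model()] (or `NULL` =
#'   poisson_only).
#' @param n_patterns Number of snapshots.
#' @param seed RNG seed (generation is bit-reproducible per seed).
#' @param target_occupancy If set, the beam fluence is rescaled so the mean
#'   expected photons per unmasked pixel matches this value (the
#'   photon-sparse regime of interest is ~0.1).
#' @param polarization Passed to [build_qmap()].
#' @param chunk Orientations simulated per block (memory control).
#' @return A [pattern_set()]; provenance records seeds, noise label and the
#'   fluence scale applied.
#' @export
make_dataset <- function(model, geometry, beam,
                         noise = c("poisson_only", "standard", "low_noise"),
                         n_patterns = 1000L, seed = 1L,
                         target_occupancy = NULL,
                         polarization = "horizontal", chunk = 256L) {
  stopifnot(inherits(model, "atomic_model"),
            inherits(geometry, "detector_geometry"),
            inherits(beam, "beam_parameters"))
  nm <- NULL
  if (inherits(noise, "noise_model")) {
    nm <- noise
    noise_label <- paste0("custom:", nm$label)
  } else {
    noise <- match.arg(noise)
    noise_label <- noise
    if (noise != "poisson_only")
      nm <- agipd_noise_model(noise, photon_energy = geometry$photon_energy)
  }
  qmap <- build_qmap(geometry, polarization)
  mask <- beamstop_mask(geometry)
  upix <- which(!mask)
  fscale <- 1
  if (!is.null(target_occupancy)) {
    base <- .mean_expected_occupancy(model, qmap, beam)
    fscale <- target_occupancy / base
  }
  sparse <- vector("list", n_patterns)
  orientations <- matrix(numeric(0), 0, 4)
  if (n_patterns > 0L) {
    # Poisson stage: its RNG stream is independent of the detector-noise
    # stage, so the same seed yields the same photon draws with and without
    # detector noise
    with_seed(seed, {
      orientations <- sample_orientation(n_patterns)
      done <- 0L
      while (done < n_patterns) {
        nb <- min(chunk, n_patterns - done)
        idx <- done + seq_len(nb)
        mu <- expected_patterns(model, qmap, beam,
                                orientations[idx, , drop = FALSE], fscale)
        for (b in seq_len(nb)) {
          counts <- stats::rpois(length(upix), mu[upix, b])
          nz <- which(counts > 0L)
          sparse[[idx[b]]] <- list(index = upix[nz],
                                   count = as.integer(counts[nz]))
        }
        done <- done + nb
      }
    })
    if (!is.null(nm)) {
      # detector stage: corrupt every unmasked pixel, then photonize
      with_seed(seed + 7919L, {
        for (i in seq_len(n_patterns)) {
          counts <- integer(length(upix))
          counts[match(sparse[[i]]$index, upix)] <- sparse[[i]]$count
          counts <- photonize(corrupt(counts, nm), nm)
          nz <- which(counts > 0L)
          sparse[[i]] <- list(index = upix[nz], count = as.integer(counts[nz]))
        }
      })
    }
  }
  pattern_set(sparse, orientations, geometry,
              provenance = list(seed = seed, noise = noise_label,
                                fluence_scale = fscale,
                                target_occupancy = target_occupancy,
                                n_atoms = model$n_atoms,
                                total_electrons = model$total_electrons,
                                polarization = polarization))
}
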