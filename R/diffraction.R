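# Forward simulator: structure factors of an atomic model, expected photon
# maps on the Ewald-sphere detector, Haar-uniform orientations, Poisson
# sampling, and the noise-free 3D reciprocal-space reference volume.

#' Atomic model
#'
#' @param elements Character vector of element symbols.
#' @param coordinates n x 3 numeric matrix of positions in Angstrom.
#' @return Object of class `atomic_model` with `total_electrons` and
#'   `extent` (largest bounding-box edge, Angstrom) attached.
#' @export
atomic_model <- function(elements, coordinates) {
  coordinates <- as.matrix(coordinates)
  if (length(elements) == 0L) stop("empty model: no atoms")
  if (nrow(coordinates) != length(elements) || ncol(coordinates) != 3L)
    stop("'coordinates' must be an n x 3 matrix matching 'elements'")
  if (!all(is.finite(coordinates))) stop("non-finite atom coordinates")
  z <- atomic_number(elements)
  ext <- if (nrow(coordinates) > 1L)
    max(apply(coordinates, 2, function(v) diff(range(v)))) else 0
  m <- list(elements = .norm_element(elements), coordinates = coordinates,
            total_electrons = sum(z), n_atoms = length(elements),
            extent = ext)
  class(m) <- "atomic_model"
  m
}

#' @exportS3Method base::print
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model: %d atoms, %d electrons, extent %.1f A\n",
              x$n_atoms, x$total_electrons, x$extent))
  invisible(x)
}

#' Load an atomic model from a PDB file
#'
#' Reads the file with [bio3d::read.pdb()]. With `strip_het = TRUE`
#' (default) all HETATM records (ligands, ions, waters) are removed, keeping
#' only the polymer; this is how "antibiotics removed" models are prepared.
#' Hydrogens are taken as deposited (none are added).
#'
#' @param path Path to a PDB file.
#' @param strip_het Drop non-polymer heteroatom records.
#' @return An [atomic_model()].
#' @export
load_model <- function(path, strip_het = TRUE) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (strip_het) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty model: no atoms after filtering")
  el <- at$elesy
  missing_el <- is.na(el) | el == ""
  if (any(missing_el))  # fall back to the first letter of the atom name
    el[missing_el] <- substr(trimws(at$elety[missing_el]), 1, 1)
  bad <- !(.norm_element(el) %in% known_elements())
  if (any(bad))
    stop("unknown element symbol in records: ",
         paste(utils::head(sprintf("%s %s/%s", at$elety[bad], at$resid[bad],
                                   at$resno[bad]), 10), collapse = "; "))
  atomic_model(el, cbind(at$x, at$y, at$z))
}

# group atoms by element; returns list(eidx 0-based, elements)
.element_groups <- function(model) {
  el <- model$elements
  u <- unique(el)
  list(eidx = match(el, u) - 1L, elements = u)
}

#' Structure factor of an atomic model
#'
#' `F(q) = sum_i f_i(|q|) exp(i q . r_i)`; `F(0)` equals the total electron
#' count.
#'
#' @param model An [atomic_model()].
#' @param q_points n x 3 matrix of scattering vectors in Angstrom^-1.
#' @return Complex vector of amplitudes.
#' @export
structure_factor <- function(model, q_points) {
  stopifnot(inherits(model, "atomic_model"))
  q_points <- matrix(as.numeric(q_points), ncol = 3L)
  g <- .element_groups(model)
  qmag <- sqrt(rowSums(q_points^2))
  fmat <- matrix(form_factor(g$elements, qmag), nrow = length(qmag))
  as.complex(sf_cpp(model$coordinates, g$eidx, fmat, q_points))
}

#' Haar-uniform random orientations
#'
#' Draws unit quaternions uniformly over SO(3) (4D Gaussian, normalized).
#' Uses the current R RNG stream.
#'
#' @param n Number of orientations.
#' @return n x 4 matrix of unit quaternions `(w, x, y, z)`.
#' @export
sample_orientation <- function(n = 1L) {
  m <- matrix(stats::rnorm(4L * n), n, 4L)
  m / sqrt(rowSums(m^2))
}

# expected photon map(s): npix x npat matrix of mu for each orientation
expected_patterns <- function(model, qmap, beam, orientations,
                              fluence_scale = 1) {
  stopifnot(inherits(qmap, "qmap"))
  orientations <- matrix(as.numeric(orientations), ncol = 4L)
  g <- .element_groups(model)
  qmag <- as.numeric(qmap$q_magnitudes)
  fmat <- matrix(form_factor(g$elements, qmag), nrow = length(qmag))
  ff2 <- ipatterns_cpp(model$coordinates, g$eidx, fmat,
                       qmap$q_vectors, orientations)
  pref <- as.numeric(qmap$solid_angles) * as.numeric(qmap$thomson_factors) *
    fluence(beam) * fluence_scale
  ff2 * pref
}

#' Simulate one diffraction snapshot
#'
#' Computes the expected photon count per pixel,
#' `mu = Omega * (dsigma_T/dOmega) * fluence * |F(R q)|^2`, with `R` the
#' orientation, and returns a Poisson draw. Beamstop pixels are masked and
#' carry `NA` in the photon matrix.
#'
#' @param model An [atomic_model()].
#' @param geometry A [detector_geometry()] (ignored if `qmap` is supplied).
#' @param beam A [beam_parameters()].
#' @param orientation Unit quaternion; defaults to identity.
#' @param qmap Optional precomputed [build_qmap()] result.
#' @param fluence_scale Multiplier applied to the beam fluence (used by the
#'   synthetic-data occupancy tuning).
#' @return Object of class `diffraction_pattern`: integer `photons` matrix
#'   (NA where masked), `expected` matrix, `orientation`, `mask`.
#' @export
simulate_pattern <- function(model, geometry, beam,
                             orientation = c(1, 0, 0, 0), qmap = NULL,
                             fluence_scale = 1) {
  if (is.null(qmap)) qmap <- build_qmap(geometry)
  geometry <- qmap$geometry
  if (abs(sqrt(sum(orientation^2)) - 1) > 1e-9)
    stop("orientation quaternion must be unit norm")
  mu <- expected_patterns(model, qmap, beam, orientation, fluence_scale)
  if (any(mu > .Machine$integer.max / 2))
    stop("expected photon counts overflow the integer range")
  counts <- stats::rpois(length(mu), mu)
  rows <- geometry$shape[1]; cols <- geometry$shape[2]
  mask <- beamstop_mask(geometry)
  photons <- matrix(as.integer(counts), rows, cols)
  photons[mask] <- NA_integer_
  p <- list(photons = photons, expected = matrix(mu, rows, cols),
            orientation = quat_normalize(orientation), mask = mask,
            geometry = geometry)
  class(p) <- "diffraction_pattern"
  p
}

#' Default reconstruction-grid voxel size for a detector
#'
#' The grid is chosen so the detector's largest scattering vector (the array
#' corner) maps to the half-grid radius: `dq = q_corner / ((edge - 1) / 2)`.
#'
#' @param qmap A [build_qmap()] result.
#' @param grid_edge Odd cubic grid edge.
#' @return Voxel size in Angstrom^-1.
#' @export
grid_voxel_size <- function(qmap, grid_edge) {
  stopifnot(inherits(qmap, "qmap"))
  max(qmap$q_magnitudes) / ((grid_edge - 1) / 2)
}

#' Render an atomic model as real-space electron density
#'
#' Places a Gaussian blob of `Z` electrons (width `sigma`, Angstrom) at
#' every atom on a cubic grid, the standard way an "ideal image" reference
#' density is prepared from a deposited model for comparison with phased
#' reconstructions. The blur bounds the model's bandwidth, so the density
#' is compact and free of truncation ringing.
#'
#' @param model An [atomic_model()].
#' @param edge Cubic grid edge (voxels).
#' @param voxel_size Real-space voxel edge in Angstrom.
#' @param sigma Gaussian blur width in Angstrom.
#' @return 3D array of electrons per voxel, particle centered at the
#'   grid's center bin.
#' @export
render_density <- function(model, edge, voxel_size, sigma = 2) {
  stopifnot(inherits(model, "atomic_model"))
  c0 <- floor(edge / 2) + 1
  ax <- ((1:edge) - c0) * voxel_size
  dens <- array(0, rep(edge, 3))
  z <- atomic_number(model$elements)
  norm <- (voxel_size / (sqrt(2 * pi) * sigma))^3
  for (a in seq_len(model$n_atoms)) {
    ex <- exp(-(ax - model$coordinates[a, 1])^2 / (2 * sigma^2))
    ey <- exp(-(ax - model$coordinates[a, 2])^2 / (2 * sigma^2))
    ez <- exp(-(ax - model$coordinates[a, 3])^2 / (2 * sigma^2))
    dens <- dens + (z[a] * norm) * outer(outer(ex, ey), ez)
  }
  dens
}

#' Noise-free 3D reciprocal-space reference volume
#'
#' Samples `prefactor * |F(q)|^2` on a cubic grid: the ideal intensity
#' I_ideal against which reconstructions are scored. The constant prefactor
#' (default 1; the per-pixel solid-angle/Thomson weighting is not applied to
#' the volume) is recorded in the metadata.
#'
#' @param model An [atomic_model()].
#' @param grid_edge Cubic grid edge (odd for EMC-compatible grids).
#' @param voxel_size Voxel size in Angstrom^-1.
#' @param prefactor Constant multiplier recorded in metadata.
#' @return An [intensity_volume()].
#' @export
build_ideal_volume <- function(model, grid_edge, voxel_size, prefactor = 1) {
  stopifnot(inherits(model, "atomic_model"))
  if (grid_edge < 3) stop("grid edge too small")
  if (as.numeric(grid_edge)^3 * 8 > 4e9)
    stop("requested grid exceeds the memory budget; use a smaller edge")
  g <- .element_groups(model)
  vals <- ideal_volume_cpp(model$coordinates, g$eidx, .cromer_mann[g$elements, , drop = FALSE],
                           as.integer(grid_edge), voxel_size)
  intensity_volume(vals * prefactor, voxel_size,
                   metadata = list(prefactor = prefactor,
                                   total_electrons = model$total_electrons))
}
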