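# Expand-maximize-compress reconstruction of the 3D reciprocal-space
# intensity from photon-sparse snapshots of unknown orientation, with
# deterministic-annealing (beta) and rotation-refinement schedules.

#' EMC configuration
#'
#' @param grid_edge Odd cubic grid edge for the reconstruction.
#' @param n_iterations Total EM iterations.
#' @param rotation_schedule Data frame with columns `iteration` (first
#'   iteration using the level, strictly increasing, starting at 1) and
#'   `level` (rotation-group refinement level).
#' @param beta_start Initial deterministic-annealing factor.
#' @param beta_factor Multiplier applied every `beta_period` iterations;
#'   beta is clipped at 1.
#' @param beta_period Iterations between beta increases.
#' @param voxel_size Grid voxel size in Angstrom^-1; `NULL` derives it from
#'   the detector (corner q over the half grid).
#' @param seed Seed for the random starting model.
#' @return Object of class `emc_config`. Configurations whose grid or
#'   rotation schedule exceed the desk scale are flagged `cluster_scale`.
#' @export
emc_config <- function(grid_edge = 63L, n_iterations = 60L,
                       rotation_schedule = data.frame(
                         iteration = c(1L, 41L, 51L), level = c(4L, 5L, 6L)),
                       beta_start = 0.05, beta_factor = sqrt(2),
                       beta_period = 5L, voxel_size = NULL, seed = 1L) {
  grid_edge <- as.integer(grid_edge)
  if (grid_edge %% 2L == 0L)
    stop("'grid_edge' must be odd so q = 0 sits on a voxel center")
  if (!all(c("iteration", "level") %in% names(rotation_schedule)))
    stop("'rotation_schedule' needs columns iteration and level")
  if (rotation_schedule$iteration[1] != 1L ||
      is.unsorted(rotation_schedule$iteration, strictly = TRUE))
    stop("schedule iterations must start at 1 and increase strictly")
  if (beta_start <= 0 || beta_factor < 1)
    stop("beta must start positive and never decrease")
  cfg <- list(grid_edge = grid_edge, n_iterations = as.integer(n_iterations),
              rotation_schedule = rotation_schedule,
              beta_start = beta_start, beta_factor = beta_factor,
              beta_period = as.integer(beta_period),
              voxel_size = voxel_size, seed = seed)
  cfg$cluster_scale <- grid_edge > 201L || max(rotation_schedule$level) > 10L
  class(cfg) <- "emc_config"
  cfg
}

#' Full-scale EMC configuration
#'
#' The cluster-scale protocol: a 951-voxel grid, 200 initial iterations on
#' the level-6 (10 860 rotation) group with beta annealed from 0.001 by a
#' factor sqrt(2) every 10 iterations, then levels 9, 12, 15, 19, 24 every
#' 20 iterations up to 300 iterations in total. Provided for configuration
#' of full runs; far beyond the desk scale.
#'
#' @param voxel_size Voxel size in Angstrom^-1 (default the 951-grid value
#'   derived from the 550 x 550, 6 keV, 0.25 m geometry).
#' @param seed Seed for the starting model.
#' @return An [emc_config()] flagged `cluster_scale`.
#' @export
full_scale_emc_config <- function(voxel_size = NULL, seed = 1L) {
  emc_config(grid_edge = 951L, n_iterations = 300L,
             rotation_schedule = data.frame(
               iteration = c(1L, 201L, 221L, 241L, 261L, 281L),
               level = c(6L, 9L, 12L, 15L, 19L, 24L)),
             beta_start = 0.001, beta_factor = sqrt(2), beta_period = 10L,
             voxel_size = voxel_size, seed = seed)
}

#' Annealing factor at a given iteration
#' @param config An [emc_config()].
#' @param iteration Iteration number (1-based).
#' @return beta, clipped at 1.
#' @export
emc_beta <- function(config, iteration) {
  pmin(1, config$beta_start *
         config$beta_factor^((iteration - 1) %/% config$beta_period))
}

# shared pixel bookkeeping: q of unmasked pixels in voxel units
.emc_qg <- function(qmap, mask, voxel_size) {
  upix <- which(!mask)
  qmap$q_vectors[upix, , drop = FALSE] / voxel_size
}

#' Expand a model volume into tomograms
#'
#' Tomogram j holds the model interpolated on the Ewald slice of rotation j:
#' `W_j(p) = model(R_j q_p)` by trilinear interpolation, over the unmasked
#' detector pixels.
#'
#' @param volume An [intensity_volume()] with odd edge.
#' @param rotations A [rotation_group()] or an n x 4 quaternion matrix.
#' @param qmap A [build_qmap()] for the detector.
#' @param mask Logical pixel mask (`TRUE` = excluded); defaults to the
#'   geometry's beamstop.
#' @return Matrix with one row per rotation, one column per unmasked pixel.
#' @export
emc_expand <- function(volume, rotations, qmap, mask = NULL) {
  stopifnot(inherits(volume, "intensity_volume"))
  quats <- if (inherits(rotations, "rotation_group"))
    rotations$quaternions else matrix(as.numeric(rotations), ncol = 4L)
  if (is.null(mask)) mask <- beamstop_mask(qmap$geometry)
  qg <- .emc_qg(qmap, mask, volume$voxel_size)
  expand_cpp(volume$values, quats, qg, volume$center)
}

#' One expectation-maximization step over a tomogram stack
#'
#' Computes orientation responsibilities
#' `P_jk = w_j exp(beta * sum_p [K_k log W_j - W_j])` (Poisson
#' log-likelihood, log-domain, normalized over j for each pattern) and the
#' standard EM tomogram update
#' `W_j(p) = sum_k P_jk K_k(p) / sum_k P_jk`. Iterating this map alone is
#' exact mixture EM: at beta = 1 the data log-likelihood it reports is
#' nondecreasing.
#'
#' @param patterns A [pattern_set()].
#' @param tomograms Rotations x unmasked-pixels matrix (from
#'   [emc_expand()]).
#' @param beta Annealing factor in (0, 1].
#' @param weights Prior rotation weights (default uniform).
#' @return List with `responsibilities` (rotations x patterns),
#'   `tomograms` (updated), `pattern_weights` (responsibility mass per
#'   rotation) and `loglik` (total beta = 1 mixture log-likelihood).
#' @export
emc_maximize <- function(patterns, tomograms, beta = 1, weights = NULL) {
  stopifnot(inherits(patterns, "pattern_set"))
  pm <- .pattern_matrices(patterns)
  if (ncol(tomograms) != nrow(pm$K))
    stop("tomogram columns must match the unmasked pixel count")
  if (is.null(weights)) weights <- rep(1 / nrow(tomograms), nrow(tomograms))
  est <- emc_estep_cpp(tomograms, pm$K, beta, log(weights))
  ms <- emc_mstep_cpp(est$P, pm$Kt)
  nj <- as.numeric(ms$nj)
  Wnew <- ms$numer
  empty <- nj <= 1e-300
  if (any(empty)) Wnew[empty, ] <- tomograms[empty, , drop = FALSE]
  list(responsibilities = est$P, tomograms = Wnew, pattern_weights = nj,
       loglik = sum(est$loglik))
}

#' Compress tomograms into a model volume
#'
#' Scatters each tomogram back onto the 3D grid with trilinear weights, each
#' tomogram weighted by its responsibility mass, and normalizes per voxel.
#' Voxels receiving no weight keep their previous value (or 0 without a
#' previous volume).
#'
#' @param tomograms Rotations x unmasked-pixels matrix.
#' @param rotations [rotation_group()] or quaternion matrix.
#' @param qmap The detector [build_qmap()].
#' @param grid_edge Odd grid edge.
#' @param voxel_size Voxel size in Angstrom^-1.
#' @param weights Per-tomogram weights (responsibility masses; default
#'   uniform).
#' @param previous Optional previous [intensity_volume()] supplying values
#'   for untouched voxels.
#' @param mask Pixel mask as in [emc_expand()].
#' @return An [intensity_volume()].
#' @export
emc_compress <- function(tomograms, rotations, qmap, grid_edge, voxel_size,
                         weights = NULL, previous = NULL, mask = NULL) {
  if (nrow(tomograms) == 0L) stop("empty tomogram stack")
  quats <- if (inherits(rotations, "rotation_group"))
    rotations$quaternions else matrix(as.numeric(rotations), ncol = 4L)
  if (is.null(weights)) weights <- rep(1, nrow(tomograms))
  if (is.null(mask)) mask <- beamstop_mask(qmap$geometry)
  qg <- .emc_qg(qmap, mask, voxel_size)
  center <- (grid_edge + 1) / 2
  cp <- compress_cpp(tomograms, weights, quats, qg, center, as.integer(grid_edge))
  vals <- cp$num
  touched <- cp$den > 1e-300
  vals[touched] <- vals[touched] / cp$den[touched]
  if (!is.null(previous)) vals[!touched] <- previous$values[!touched]
  intensity_volume(vals, voxel_size, metadata = list(touched = sum(touched)))
}

#' Run the EMC reconstruction
#'
#' Starts from a uniform-random positive model scaled to the mean photon
#' count, then iterates expand / maximize / compress under the beta and
#' rotation-refinement schedules of `config`, Friedel-symmetrizing the model
#' after each compression. Ties between equally likely rotations are shared
#' naturally by the soft EM responsibilities.
#'
#' @param patterns A [pattern_set()].
#' @param config An [emc_config()].
#' @param polarization Polarization convention for the detector q-map.
#' @param verbose Print per-iteration progress.
#' @return The reconstructed [intensity_volume()]; its metadata holds the
#'   per-iteration `trace` (iteration, level, beta, loglik) and the config.
#' @export
run_emc <- function(patterns, config = emc_config(), polarization = "horizontal",
                    verbose = FALSE) {
  stopifnot(inherits(patterns, "pattern_set"), inherits(config, "emc_config"))
  qmap <- build_qmap(patterns$geometry, polarization)
  voxel_size <- config$voxel_size
  if (is.null(voxel_size)) voxel_size <- grid_voxel_size(qmap, config$grid_edge)
  edge <- config$grid_edge
  center <- (edge + 1) / 2
  pm <- .pattern_matrices(patterns)
  qg <- qmap$q_vectors[pm$upix, , drop = FALSE] / voxel_size
  mean_count <- sum(pm$K) / (patterns$n_patterns * length(pm$upix))
  vals <- with_seed(config$seed,
    array(stats::runif(edge^3, 0.5, 1.5) * max(mean_count, 1e-12), dim = rep(edge, 3)))
  vol <- intensity_volume(vals, voxel_size)
  sched <- config$rotation_schedule
  trace <- data.frame(iteration = seq_len(config$n_iterations),
                      level = NA_integer_, beta = NA_real_, loglik = NA_real_)
  group <- NULL; cur_level <- NA_integer_
  for (t in seq_len(config$n_iterations)) {
    level <- sched$level[findInterval(t, sched$iteration)]
    if (!identical(level, cur_level)) {
      group <- rotation_group(level)
      cur_level <- level
    }
    beta <- emc_beta(config, t)
    W <- expand_cpp(vol$values, group$quaternions, qg, center)
    est <- emc_estep_cpp(W, pm$K, beta, log(group$weights))
    ms <- emc_mstep_cpp(est$P, pm$Kt)
    nj <- as.numeric(ms$nj)
    Wnew <- ms$numer
    empty <- nj <= 1e-300
    if (any(empty)) Wnew[empty, ] <- W[empty, , drop = FALSE]
    cp <- compress_cpp(Wnew, nj, group$quaternions, qg, center, edge)
    newvals <- cp$num
    touched <- cp$den > 1e-300
    newvals[touched] <- newvals[touched] / cp$den[touched]
    newvals[!touched] <- vol$values[!touched]
    if (any(!is.finite(newvals)))
      stop("EMC diverged (non-finite model) at iteration ", t)
    vol$values <- newvals
    vol <- friedel_symmetrize(vol)
    trace$level[t] <- level
    trace$beta[t] <- beta
    trace$loglik[t] <- sum(est$loglik)
    if (verbose)
      message(sprintf("EMC iter %3d: level %d (%d rot), beta %.4g, loglik %.6g",
                      t, level, group$count, beta, trace$loglik[t]))
  }
  vol$metadata <- list(trace = trace, config = config,
                       voxel_size_source = if (is.null(config$voxel_size))
                         "q_corner/half-grid" else "config",
                       n_patterns = patterns$n_patterns)
  vol
}
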