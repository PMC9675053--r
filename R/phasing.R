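# Hybrid input-output phase retrieval from a reciprocal-space intensity
# volume: ensemble of random starts, fixed spherical support, best-n
# averaging with center-of-mass plus sub-voxel (Fourier-interpolated)
# alignment, Gaussian-blur support tightening, and conversion to
# electrons/voxel.

#' Phasing configuration
#'
#' @param n_starts Independent random initializations.
#' @param n_iterations HIO iterations per start.
#' @param feedback HIO feedback parameter beta_fb in (0, 1).
#' @param support_radius Fixed spherical support radius in voxels.
#' @param n_best Number of lowest-reciprocal-error runs to average.
#' @param blur_sigma Gaussian blur width (voxels) for support tightening.
#' @param support_threshold Fraction of the blurred maximum kept inside the
#'   tight support.
#' @param positivity Impose nonnegativity inside the support (electron
#'   density) in addition to the support constraint.
#' @param er_finish Error-reduction iterations appended to every HIO run
#'   (stabilizes the oscillating HIO iterate before ranking/averaging).
#' @param upsample Sub-voxel alignment factor (10 = tenth-voxel steps).
#' @param seed Base seed; start k uses `seed + k`.
#' @return Object of class `phasing_config`.
#' @export
phasing_config <- function(n_starts = 20L, n_iterations = 500L,
                           feedback = 0.9, support_radius = NULL,
                           n_best = 3L, blur_sigma = 2, support_threshold = 0.03,
                           positivity = TRUE, er_finish = 50L, upsample = 10L,
                           seed = 1L) {
  if (n_best > n_starts) stop("'n_best' cannot exceed 'n_starts'")
  if (feedback <= 0 || feedback >= 1) stop("'feedback' must be in (0, 1)")
  cfg <- list(n_starts = as.integer(n_starts),
              n_iterations = as.integer(n_iterations), feedback = feedback,
              support_radius = support_radius, n_best = as.integer(n_best),
              blur_sigma = blur_sigma, support_threshold = support_threshold,
              positivity = positivity, er_finish = as.integer(er_finish),
              upsample = as.integer(upsample), seed = seed)
  class(cfg) <- "phasing_config"
  cfg
}

#' Full-scale phasing configuration
#'
#' The cluster-scale protocol: 300 random starts of 3000 HIO iterations each
#' on the 276-voxel preprocessed array, best 3 averaged.
#'
#' @param ... Overrides passed to [phasing_config()].
#' @return A [phasing_config()].
#' @export
full_scale_phasing_config <- function(...) {
  phasing_config(n_starts = 300L, n_iterations = 3000L, ...)
}

#' Trim/bin plan for a reconstruction grid
#'
#' Scales the full-size preprocessing (951 -> center-trim to 552 -> 2x2x2
#' bin -> 276) proportionally to other grid sizes.
#'
#' @param edge Input grid edge.
#' @param bin Binning factor.
#' @return List with `trim` (even multiple of `bin`) and `out` edges.
#' @export
preprocess_plan <- function(edge, bin = 2L) {
  trim <- bin * floor(edge * 552 / 951 / bin)
  list(trim = as.integer(trim), out = as.integer(trim / bin))
}

# mean-bin a cube by factor f along every axis
.binmean3 <- function(a, f) {
  if (f == 1L) return(a)
  for (axis in 1:3) {
    d <- dim(a)
    a <- array(a, c(f, d[1] / f, d[2], d[3]))
    a <- colMeans(a)
    a <- aperm(a, c(2, 3, 1))
  }
  a
}

#' Prepare an intensity volume for phase retrieval
#'
#' Center-trims the grid, mean-bins it, and flags a central spherical
#' beamstop region as unconstrained (its amplitudes float freely during
#' phasing). Mean (not sum) binning keeps intensities per-voxel comparable.
#'
#' @param volume An [intensity_volume()].
#' @param trim Even trim target (default from [preprocess_plan()]).
#' @param bin Binning factor (default 2).
#' @param mask_radius Beamstop mask radius in voxels of the *binned* grid
#'   (default 5, as at full scale).
#' @return An [intensity_volume()] of edge `trim / bin` whose `mask` marks
#'   the masked central sphere.
#' @export
preprocess_volume <- function(volume, trim = NULL, bin = 2L, mask_radius = 5) {
  stopifnot(inherits(volume, "intensity_volume"))
  if (is.null(trim)) trim <- preprocess_plan(volume$edge, bin)$trim
  if (trim > volume$edge)
    stop("input grid (", volume$edge, ") smaller than trim target (", trim, ")")
  if (trim %% bin != 0L) stop("'trim' must be a multiple of 'bin'")
  start <- volume$center - (floor(trim / 2) + 1L) + 1L
  idx <- start:(start + trim - 1L)
  if (idx[1] < 1L) stop("trim window leaves the grid; reduce 'trim'")
  v <- volume$values[idx, idx, idx]
  v <- .binmean3(v, bin)
  out <- intensity_volume(v, volume$voxel_size * bin,
                          metadata = c(volume$metadata,
                                       list(trim = trim, bin = bin)))
  r <- voxel_radii(out)
  mask <- r <= mask_radius
  if (!is.null(volume$mask)) {
    # carry forward any voxels already excluded, at the binned resolution
    carried <- .binmean3(volume$mask[idx, idx, idx] * 1, bin) > 0
    mask <- mask | carried
  }
  out$mask <- mask
  out
}

#' Count of voxels inside a centered sphere
#' @param radius Sphere radius in voxels.
#' @return Number of integer lattice points with `x^2+y^2+z^2 <= radius^2`.
#' @export
sphere_voxel_count <- function(radius) {
  r <- floor(radius)
  x <- (-r):r
  sum(outer(outer(x^2, x^2, `+`), x^2, `+`) <= radius^2)
}

#' Spherical support mask
#' @param edge Grid edge.
#' @param radius Support radius in voxels.
#' @return Logical cube, `TRUE` inside the sphere about the center bin.
#' @export
spherical_support <- function(edge, radius) {
  c0 <- floor(edge / 2) + 1
  x <- (1:edge) - c0
  outer(outer(x^2, x^2, `+`), x^2, `+`) <= radius^2
}

#' One hybrid input-output run
#'
#' Standard HIO: each iteration replaces Fourier amplitudes by the measured
#' magnitudes on measured voxels (masked voxels keep their current
#' amplitudes) and applies the support/positivity feedback
#' `x <- x - beta_fb * x'` outside the constraint set. The support is fixed
#' (no shrinkwrap).
#'
#' @param magnitudes 3D array of Fourier magnitudes, zero frequency at the
#'   center bin.
#' @param measured Logical array: voxels whose magnitudes constrain the
#'   iterate (beamstop and unmeasured voxels are `FALSE`).
#' @param support Logical array, the fixed real-space support.
#' @param n_iterations Iteration count.
#' @param feedback HIO beta_fb.
#' @param positivity Impose density nonnegativity inside the support.
#' @param seed Seed for the random initial phases (ignored when `init`
#'   given).
#' @param init Optional initial real-space density array.
#' @param er_finish Error-reduction iterations appended after the HIO
#'   iterations (the minimal ER-finisher option; 0 disables).
#' @return List with `density` (real array, centered) and `error` (relative
#'   magnitude residual over measured voxels).
#' @export
hio_run <- function(magnitudes, measured, support, n_iterations = 500L,
                    feedback = 0.9, positivity = TRUE, seed = 1L,
                    init = NULL, er_finish = 0L) {
  d <- dim(magnitudes)
  if (!any(measured)) stop("all Fourier magnitudes are masked")
  n3 <- prod(d)
  mw <- ifftshift3(magnitudes)
  meas <- ifftshift3(measured)
  supp <- ifftshift3(support)
  if (is.null(init)) {
    ph <- with_seed(seed, stats::runif(n3, 0, 2 * pi))
    G0 <- mw * exp(1i * array(ph, d))
    x <- Re(stats::fft(G0, inverse = TRUE)) / n3
  } else {
    x <- ifftshift3(init)
  }
  midx <- which(meas)
  mvals <- mw[midx]
  vout <- which(!supp)
  edge <- d[1]
  if (length(unique(d)) == 1L && bitwAnd(edge, edge - 1L) == 0L) {
    # power-of-two cube: compiled engine with its own radix-2 FFT
    out <- hio_cpp(mvals, midx - 1L, vout - 1L, edge,
                   as.integer(n_iterations), as.integer(er_finish),
                   feedback, positivity, as.numeric(x))
    return(list(density = fftshift3(array(out$x, d)), error = out$error))
  }
  m2 <- sum(mvals^2)
  total <- n_iterations + er_finish
  for (it in seq_len(total)) {
    G <- stats::fft(x)
    Gm <- G[midx]
    mag <- Mod(Gm)
    Gm <- ifelse(mag > 0, mvals * (Gm / mag), mvals + 0i)
    G[midx] <- Gm
    xp <- Re(stats::fft(G, inverse = TRUE)) / n3
    if (it <= n_iterations) {
      xn <- xp
      if (positivity) {
        viol <- which(xp < 0)
        xn[viol] <- x[viol] - feedback * xp[viol]
      }
      xn[vout] <- x[vout] - feedback * xp[vout]
    } else {
      xn <- if (positivity) pmax(xp, 0) else xp
      xn[vout] <- 0
      dim(xn) <- d
    }
    x <- xn
  }
  # reciprocal-space residual of the final iterate
  G <- stats::fft(x)
  err <- sqrt(sum((Mod(G[midx]) - mvals)^2) / m2)
  list(density = fftshift3(x), error = err)
}

#' Gaussian blur of a 3D array (periodic boundaries)
#' @param a 3D array.
#' @param sigma Blur width in voxels.
#' @return Blurred array.
#' @export
gaussian_blur3d <- function(a, sigma) {
  d <- dim(a)
  ax <- lapply(d, function(n) {
    u <- fft_freqs(n)
    exp(-u^2 / (2 * sigma^2))
  })
  k <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  k <- k / sum(k)
  Re(stats::fft(stats::fft(a) * stats::fft(k), inverse = TRUE)) / prod(d)
}

# center of mass of a (nonnegative part of a) density, 1-based coordinates
.center_of_mass <- function(a) {
  w <- pmax(a, 0)
  tot <- sum(w)
  if (tot <= 0) stop("zero density: center of mass undefined")
  d <- dim(a)
  g <- lapply(seq_along(d), function(ax) {
    m <- apply(w, ax, sum)
    sum(m * seq_len(d[ax])) / tot
  })
  unlist(g)
}

# shift a real array by `shift` voxels (possibly fractional) via Fourier
# phase ramp (sinc interpolation)
.fourier_shift <- function(a, shift) {
  d <- dim(a)
  ramps <- lapply(seq_along(d), function(ax)
    exp(-2i * pi * fft_freqs(d[ax]) * shift[ax] / d[ax]))
  ramp <- outer(outer(ramps[[1]], ramps[[2]]), ramps[[3]])
  Re(stats::fft(stats::fft(a) * ramp, inverse = TRUE)) / prod(d)
}

# cross-correlation of ref and img evaluated on a sub-voxel shift grid by
# separable matrix DFTs (Fourier interpolation, no global upsampled array)
.local_xcorr <- function(P, sgrids) {
  d <- dim(P)
  A <- P
  for (ax in 1:3) {
    n <- d[ax]
    E <- exp(2i * pi * outer(sgrids[[ax]], fft_freqs(n)) / n)
    da <- dim(A)
    m <- matrix(A, nrow = da[1])
    m <- E %*% m
    A <- array(m, c(length(sgrids[[ax]]), da[2], da[3]))
    A <- aperm(A, c(2, 3, 1))
  }
  Re(A) / prod(d)
}

#' Align a density to a reference
#'
#' Integer alignment by center-of-mass difference, then sub-voxel alignment
#' maximizing the Fourier-interpolated cross-correlation on a local grid of
#' `1/upsample`-voxel steps (a ten-times-finer grid by default), then the
#' Friedel-twin check: the point-reflected density is aligned the same way
#' and the branch with the higher correlation wins.
#'
#' @param density Real 3D array.
#' @param reference Real 3D array of the same shape.
#' @param upsample Sub-voxel step denominator.
#' @param try_inversion Also try the point-reflected (Friedel twin) density.
#' @return The aligned density; attributes `shift`, `correlation`,
#'   `inverted`.
#' @export
align_to_reference <- function(density, reference, upsample = 10L,
                               try_inversion = TRUE) {
  d <- dim(density)
  if (!identical(d, dim(reference))) stop("shapes differ")
  if (sum(abs(density)) == 0) stop("zero density cannot be aligned")
  Fr <- stats::fft(reference)
  com_ref <- .center_of_mass(reference)
  branch <- function(img, inverted) {
    shift0 <- round(com_ref - .center_of_mass(img))
    P <- Fr * Conj(stats::fft(img))
    off <- seq(-1.5, 1.5, by = 1 / upsample)
    sg <- lapply(1:3, function(ax) shift0[ax] + off)
    cc <- .local_xcorr(P, sg)
    best <- arrayInd(which.max(cc), dim(cc))
    shift <- vapply(1:3, function(ax) sg[[ax]][best[ax]], numeric(1))
    out <- .fourier_shift(img, shift)
    list(out = out, shift = shift,
         corr = stats::cor(as.numeric(out), as.numeric(reference)),
         inverted = inverted)
  }
  b1 <- branch(density, FALSE)
  best <- b1
  if (try_inversion) {
    n <- d
    inv <- density[n[1]:1, n[2]:1, n[3]:1]
    b2 <- branch(inv, TRUE)
    if (b2$corr > b1$corr) best <- b2
  }
  structure(best$out, shift = best$shift, correlation = best$corr,
            inverted = best$inverted)
}

#' Default support radius from the particle size
#'
#' 1.3 times the particle radius, expressed in real-space voxels of the
#' phasing grid.
#'
#' @param volume The (preprocessed) [intensity_volume()].
#' @param particle_extent_A Particle diameter in Angstrom.
#' @return Radius in voxels.
#' @export
default_support_radius <- function(volume, particle_extent_A) {
  dx <- 2 * pi / (volume$edge * volume$voxel_size)  # A per voxel
  1.3 * (particle_extent_A / 2) / dx
}

#' Ensemble phase retrieval
#'
#' Runs `n_starts` independent [hio_run()]s, ranks them by reciprocal-space
#' error, aligns the `n_best` to the best one (center of mass + sub-voxel
#' Fourier interpolation + Friedel-twin resolution), averages them, tightens
#' the support by Gaussian blurring and thresholding, zeroes the density
#' outside, and converts to electrons/voxel by normalizing the total to the
#' model's electron count.
#'
#' @param volume Preprocessed [intensity_volume()] (mask = unconstrained
#'   voxels).
#' @param config A [phasing_config()]; its `support_radius` must be set
#'   (see [default_support_radius()]).
#' @param total_electrons Electron count for the final normalization
#'   (`NULL` leaves the arbitrary scale).
#' @param reference Optional reference density; the averaged result is
#'   aligned to it before support tightening.
#' @return A [real_space_volume()]; metadata records per-start errors and
#'   the selected starts.
#' @export
ensemble_phase <- function(volume, config, total_electrons = NULL,
                           reference = NULL) {
  stopifnot(inherits(volume, "intensity_volume"),
            inherits(config, "phasing_config"))
  if (is.null(config$support_radius))
    stop("config$support_radius must be set for ensemble phasing")
  edge <- volume$edge
  mags <- sqrt(pmax(volume$values, 0))
  measured <- is.finite(mags)
  if (!is.null(volume$mask)) measured <- measured & !volume$mask
  measured <- measured & (voxel_radii(volume) <= floor((edge - 1) / 2))
  mags[!measured] <- 0
  support <- spherical_support(edge, config$support_radius)
  runs <- lapply(seq_len(config$n_starts), function(k)
    hio_run(mags, measured, support, config$n_iterations, config$feedback,
            config$positivity, seed = config$seed + k,
            er_finish = config$er_finish))
  errors <- vapply(runs, `[[`, numeric(1), "error")
  sel <- order(errors)[seq_len(config$n_best)]
  ref <- runs[[sel[1]]]$density
  acc <- ref
  if (length(sel) > 1) {
    for (k in sel[-1])
      acc <- acc + align_to_reference(runs[[k]]$density, ref,
                                      upsample = config$upsample)
    acc <- acc / length(sel)
  }
  if (!is.null(reference))
    acc <- align_to_reference(acc, reference, upsample = config$upsample)
  blurred <- gaussian_blur3d(pmax(acc, 0), config$blur_sigma)
  tight <- blurred >= config$support_threshold * max(blurred)
  dens <- acc
  dens[!tight] <- 0
  if (!is.null(total_electrons)) {
    tot <- sum(dens)
    if (tot <= 0) stop("no density inside the tight support")
    dens <- dens * total_electrons / tot
  }
  voxel_nm <- 2 * pi / (edge * volume$voxel_size) / 10
  real_space_volume(unclass(dens), voxel_nm, support = tight,
                    metadata = list(errors = errors, selected = sel,
                                    support_radius = config$support_radius))
}
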