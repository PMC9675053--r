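# Quality metrics: rotational registration of reciprocal-space volumes,
# the 3D R factor, and the resolution at the R = 0.2 threshold.

#' Register a volume to a reference by a proper rotation
#'
#' Searches a quasi-uniform rotation grid for the rotation `R` maximizing
#' the masked Pearson correlation between `volume(R x)` and
#' `reference(x)`, evaluated first on a low-q shell (where orientation
#' basins are wide), then locally refined by Nelder-Mead on the best
#' candidates over a wider shell.
#'
#' @param volume An [intensity_volume()].
#' @param reference An [intensity_volume()] on the same grid.
#' @param coarse_level Rotation-group refinement level of the global search.
#' @param r_inner Inner radius (voxels) excluded from correlations (the
#'   central speckle carries no orientation information).
#' @param r_coarse Outer radius of the coarse-search shell; default a
#'   quarter of the grid.
#' @param r_outer Outer radius for refinement/final correlation; default
#'   the inscribed sphere.
#' @param n_candidates Coarse candidates refined locally.
#' @param max_voxels Voxel subsample cap per correlation evaluation.
#' @return List with `quaternion`, `rotation` (3x3 matrix), `volume` (the
#'   resampled, registered [intensity_volume()]; voxels leaving the grid are
#'   `NA`), and `correlation`.
#' @export
register_rotation <- function(volume, reference, coarse_level = 6L,
                              r_inner = 3, r_coarse = NULL, r_outer = NULL,
                              n_candidates = 8L, max_voxels = 20000L) {
  stopifnot(inherits(volume, "intensity_volume"),
            inherits(reference, "intensity_volume"))
  if (volume$edge != reference$edge ||
      abs(volume$voxel_size - reference$voxel_size) >
        1e-9 * reference$voxel_size)
    stop("volumes must share grid shape and voxel size")
  edge <- volume$edge; c0 <- reference$center
  if (is.null(r_coarse)) r_coarse <- max(r_inner + 3, floor(edge / 4))
  if (is.null(r_outer)) r_outer <- floor((edge - 1) / 2) - 1
  r <- voxel_radii(reference)
  shell_pts <- function(rmax) {
    sel <- which(r > r_inner & r <= rmax & is.finite(reference$values))
    if (length(sel) > max_voxels)
      sel <- sel[seq(1, length(sel), length.out = max_voxels)]
    ind <- arrayInd(sel, dim(r))
    list(pts = sweep(ind, 2, c0), vals = reference$values[sel])
  }
  sh <- shell_pts(r_coarse)
  if (stats::sd(sh$vals) == 0) stop("degenerate (constant) reference volume")
  if (stats::sd(volume$values[is.finite(volume$values)]) == 0)
    stop("degenerate (constant) volume")
  grp <- rotation_group(coarse_level)
  cc <- corr_quats_cpp(volume$values, sh$pts, sh$vals, grp$quaternions, c0)
  cand <- order(cc, decreasing = TRUE)[seq_len(n_candidates)]
  shf <- shell_pts(r_outer)
  objective <- function(q) {
    -corr_quats_cpp(volume$values, shf$pts, shf$vals,
                    matrix(q, 1, 4), c0)[1]
  }
  best_q <- NULL; best_val <- Inf
  for (j in cand) {
    q0 <- grp$quaternions[j, ]
    fn <- function(v) {
      ang <- sqrt(sum(v^2))
      dq <- if (ang < 1e-12) c(1, 0, 0, 0) else quat_from_axis_angle(v, ang)
      objective(quat_normalize(quat_multiply(q0, dq)))
    }
    op <- stats::optim(c(0, 0, 0), fn, method = "Nelder-Mead",
                       control = list(reltol = 1e-7, maxit = 250))
    if (op$value < best_val) {
      best_val <- op$value
      ang <- sqrt(sum(op$par^2))
      dq <- if (ang < 1e-12) c(1, 0, 0, 0) else quat_from_axis_angle(op$par, ang)
      best_q <- quat_normalize(quat_multiply(q0, dq))
    }
  }
  M <- quat_to_matrix(best_q)
  rot <- rotate_resample_cpp(volume$values, M, c0)
  rot[!is.finite(rot)] <- NA_real_
  out <- intensity_volume(rot, volume$voxel_size, mask = volume$mask,
                          metadata = c(volume$metadata,
                                       list(registered_to = "reference")))
  list(quaternion = best_q, rotation = M, volume = out,
       correlation = -best_val)
}

#' 3D R factor as a function of resolution cutoff
#'
#' For each full-period resolution `D`, both volumes are normalized over the
#' voxels with `|q| <= 2 pi / D` and the absolute normalized differences are
#' summed:
#' `R(D) = sum_{|q| <= 2 pi/D} | I(q)/sum(I) - I_ideal(q)/sum(I_ideal) |`.
#' R lies in [0, 2], is scale-invariant, and is 0 for identical volumes.
#' Beamstop-masked and non-finite voxels are excluded from both sums.
#'
#' @param volume Registered [intensity_volume()].
#' @param ideal Reference [intensity_volume()] on the same grid.
#' @param d_grid Full-period resolutions D in nm, strictly monotone.
#' @param exclude Optional additional logical exclusion array.
#' @return Data frame of class `rfactor_curve`: `resolution_nm`, `r`,
#'   `n_voxels`.
#' @export
r_factor <- function(volume, ideal, d_grid, exclude = NULL) {
  stopifnot(inherits(volume, "intensity_volume"),
            inherits(ideal, "intensity_volume"))
  if (volume$edge != ideal$edge)
    stop("volumes must share the grid")
  if (is.unsorted(d_grid, strictly = TRUE) &&
      is.unsorted(rev(d_grid), strictly = TRUE))
    stop("'d_grid' must be strictly monotone")
  qv <- voxel_q(ideal)
  excl <- !is.finite(volume$values) | !is.finite(ideal$values)
  if (!is.null(volume$mask)) excl <- excl | volume$mask
  if (!is.null(ideal$mask)) excl <- excl | ideal$mask
  if (!is.null(exclude)) excl <- excl | exclude
  rows <- lapply(d_grid, function(D) {
    qcut <- 2 * pi / (D * 10)  # nm -> A^-1
    sel <- qv <= qcut & !excl
    n <- sum(sel)
    a <- volume$values[sel]; b <- ideal$values[sel]
    sa <- sum(a); sb <- sum(b)
    if (n == 0 || sa <= 0 || sb <= 0)
      stop("no usable intensity inside the cutoff D = ", D, " nm")
    data.frame(resolution_nm = D, r = sum(abs(a / sa - b / sb)), n_voxels = n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rfactor_curve", "data.frame")
  out
}

#' Resolution at an R-factor threshold
#'
#' Walks the curve from low q (coarse D) and linearly interpolates the first
#' upward crossing of the threshold in `1/D` (proportional to the q cutoff).
#' A curve that stays below the threshold is detector-limited (finest D in
#' the grid); one that never dips below it is unresolved (coarsest D).
#'
#' @param curve An [r_factor()] curve.
#' @param threshold R threshold (default 0.2).
#' @return List with `resolution_nm`, `flag` (`"crossed"`,
#'   `"detector-limited"` or `"unresolved"`), and `n_crossings` (more than
#'   one indicates an unstable, re-crossing curve).
#' @export
resolution_at_threshold <- function(curve, threshold = 0.2) {
  if (!nrow(curve)) stop("empty R-factor curve")
  ord <- order(curve$resolution_nm, decreasing = TRUE)  # low q first
  D <- curve$resolution_nm[ord]; r <- curve$r[ord]
  above <- r >= threshold
  n_cross <- sum(abs(diff(above)))
  first_below <- which(!above)[1]
  if (is.na(first_below))
    return(list(resolution_nm = D[1], flag = "unresolved",
                n_crossings = n_cross))
  up <- which(!above[-length(above)] & above[-1])
  up <- up[up >= first_below]
  if (!length(up))
    return(list(resolution_nm = D[length(D)], flag = "detector-limited",
                n_crossings = n_cross))
  i <- up[1]
  x1 <- 1 / D[i]; x2 <- 1 / D[i + 1]
  xs <- x1 + (threshold - r[i]) / (r[i + 1] - r[i]) * (x2 - x1)
  list(resolution_nm = 1 / xs, flag = "crossed", n_crossings = n_cross)
}
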