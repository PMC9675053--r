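# Snapshot collections: photon counts stored sparsely (photon-sparse regime,
# ~0.1 photons/pixel), with ground-truth orientations, a shared geometry and
# beamstop mask, and full provenance.

#' Snapshot collection
#'
#' @param sparse List with one entry per snapshot, each a list with integer
#'   `index` (linear pixel indices, column-major over the detector array) and
#'   `count` (photons at those pixels). Masked pixels never appear.
#' @param orientations n x 4 matrix of ground-truth unit quaternions.
#' @param geometry The shared [detector_geometry()].
#' @param provenance Free-form list (model id, beam, noise config, seeds).
#' @return Object of class `pattern_set`.
#' @export
pattern_set <- function(sparse, orientations, geometry, provenance = list()) {
  stopifnot(inherits(geometry, "detector_geometry"))
  orientations <- matrix(as.numeric(orientations), ncol = 4L)
  if (length(sparse) != nrow(orientations))
    stop("one orientation per pattern required")
  if (nrow(orientations) > 0L &&
      any(abs(sqrt(rowSums(orientations^2)) - 1) > 1e-9))
    stop("orientation quaternions must be unit norm")
  ps <- list(sparse = sparse, orientations = orientations,
             geometry = geometry, mask = beamstop_mask(geometry),
             n_patterns = length(sparse), provenance = provenance)
  class(ps) <- "pattern_set"
  ps
}

#' @exportS3Method base::print
print.pattern_set <- function(x, ...) {
  tot <- sum(vapply(x$sparse, function(s) sum(s$count), numeric(1)))
  npx <- sum(!x$mask)
  cat(sprintf("pattern_set: %d snapshots on %d x %d px (%d unmasked)\n",
              x$n_patterns, x$geometry$shape[1], x$geometry$shape[2], npx))
  if (x$n_patterns > 0)
    cat(sprintf("  mean %.4f photons/unmasked pixel\n",
                tot / (x$n_patterns * npx)))
  invisible(x)
}

#' Dense photon matrix of one snapshot
#'
#' @param patterns A [pattern_set()].
#' @param i Snapshot index.
#' @return Integer rows x cols matrix; masked pixels carry `NA`.
#' @export
pattern_counts <- function(patterns, i) {
  stopifnot(inherits(patterns, "pattern_set"))
  g <- patterns$geometry
  m <- matrix(0L, g$shape[1], g$shape[2])
  s <- patterns$sparse[[i]]
  m[s$index] <- s$count
  m[patterns$mask] <- NA_integer_
  m
}

#' Mean photons per unmasked pixel
#' @param patterns A [pattern_set()].
#' @return Mean occupancy.
#' @export
mean_occupancy <- function(patterns) {
  tot <- sum(vapply(patterns$sparse, function(s) sum(s$count), numeric(1)))
  tot / (patterns$n_patterns * sum(!patterns$mask))
}

#' Keep the first n snapshots
#' @param patterns A [pattern_set()].
#' @param n Prefix length.
#' @return Truncated [pattern_set()].
#' @export
truncate_patterns <- function(patterns, n) {
  stopifnot(n <= patterns$n_patterns)
  pattern_set(patterns$sparse[seq_len(n)],
              patterns$orientations[seq_len(n), , drop = FALSE],
              patterns$geometry, c(patterns$provenance, list(truncated_to = n)))
}

# sparse count matrix over unmasked pixels (npix_unmasked x n_patterns) and
# its transpose, plus the unmasked pixel bookkeeping
.pattern_matrices <- function(patterns) {
  g <- patterns$geometry
  upix <- which(!patterns$mask)
  pos <- integer(prod(g$shape))
  pos[upix] <- seq_along(upix)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  trip <- lapply(seq_len(patterns$n_patterns), function(k) {
    s <- patterns$sparse[[k]]
    keep <- pos[s$index] > 0L
    cbind(pos[s$index[keep]], k, s$count[keep])
  })
  trip <- do.call(rbind, trip)
  if (is.null(trip)) trip <- matrix(0, 0, 3)
  K <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                            dims = c(length(upix), patterns$n_patterns))
  list(K = K, Kt = Matrix::t(K), upix = upix)
}
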