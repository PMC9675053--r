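# Quasi-uniform sampling of SO(3): barycentric subdivision of the 600-cell,
# projected to the unit 3-sphere, with antipodal quaternions identified.
# Refinement level n yields exactly 10(5n^3 + n) rotations.

# the 120 vertices of the unit 600-cell (exact literal construction)
.cell600_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- list()
  # 8 unit-axis vertices
  for (i in 1:4) for (s in c(1, -1)) {
    x <- numeric(4); x[i] <- s; v[[length(v) + 1L]] <- x
  }
  # 16 half-integer vertices
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) for (s4 in c(1, -1))
    v[[length(v) + 1L]] <- c(s1, s2, s3, s4) / 2
  # 96 even permutations of (phi, 1, 1/phi, 0)/2
  base <- c(phi / 2, 1 / 2, 1 / (2 * phi), 0)
  perms <- .permutations4()
  even <- perms[vapply(seq_len(nrow(perms)), function(i)
    .perm_sign(perms[i, ]) == 1L, logical(1)), , drop = FALSE]
  for (i in seq_len(nrow(even))) {
    p <- base[even[i, ]]
    nz <- which(p != 0)
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      x <- p
      x[nz] <- x[nz] * c(s1, s2, s3)
      v[[length(v) + 1L]] <- x
    }
  }
  do.call(rbind, v)
}

.permutations4 <- function() {
  out <- matrix(0L, 24, 4)
  r <- 1L
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b))) {
    out[r, ] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
    r <- r + 1L
  }
  out
}

.perm_sign <- function(p) {
  inv <- 0L
  for (i in 1:3) for (j in (i + 1):4) if (p[i] > p[j]) inv <- inv + 1L
  if (inv %% 2L == 0L) 1L else -1L
}

# cached combinatorial structure of the 600-cell
.cell600_cache <- new.env(parent = emptyenv())

.cell600_structure <- function() {
  if (!is.null(.cell600_cache$s)) return(.cell600_cache$s)
  V <- .cell600_vertices()
  nV <- nrow(V)
  # antipode index map (vertex coordinates are exact sign-symmetric literals)
  key <- apply(round(V, 9), 1, paste, collapse = ",")
  akey <- apply(round(-V, 9), 1, paste, collapse = ",")
  anti <- match(akey, key)
  stopifnot(!anyNA(anti), all(anti != seq_len(nV)))
  # adjacency: nearest neighbors at dot product cos(36 deg) = phi/2
  G <- tcrossprod(V)
  phi <- (1 + sqrt(5)) / 2
  adj <- abs(G - phi / 2) < 1e-9
  stopifnot(all(rowSums(adj) == 12L))
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  stopifnot(nrow(edges) == 720L)
  # triangular faces: mutually adjacent triples
  faces <- matrix(0L, 0, 3)
  fl <- vector("list", nrow(edges))
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    k <- which(adj[i, ] & adj[j, ])
    k <- k[k > j]
    if (length(k)) fl[[r]] <- cbind(i, j, k, deparse.level = 0)
  }
  faces <- do.call(rbind, fl)
  stopifnot(nrow(faces) == 1200L)
  # tetrahedral cells: faces plus a common neighbor
  cl <- vector("list", nrow(faces))
  for (r in seq_len(nrow(faces))) {
    f <- faces[r, ]
    l <- which(adj[f[1], ] & adj[f[2], ] & adj[f[3], ])
    l <- l[l > f[3]]
    if (length(l)) cl[[r]] <- cbind(f[1], f[2], f[3], l, deparse.level = 0)
  }
  cells <- do.call(rbind, cl)
  stopifnot(nrow(cells) == 600L)
  s <- list(V = V, anti = anti, edges = edges, faces = faces, cells = cells)
  .cell600_cache$s <- s
  s
}

# keep one representative per antipodal pair of index tuples (exact,
# combinatorial: no floating-point comparisons involved)
.canonical_half <- function(tuples, anti) {
  a <- matrix(anti[tuples], nrow = nrow(tuples))
  a <- t(apply(a, 1, sort))
  keep <- logical(nrow(tuples))
  for (r in seq_len(nrow(tuples))) {
    d <- tuples[r, ] - a[r, ]
    nz <- which(d != 0)[1]
    keep[r] <- d[nz] < 0
  }
  tuples[keep, , drop = FALSE]
}

# all compositions of n into k positive parts
.compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1, 1))
  out <- list()
  for (i in seq_len(n - k + 1L)) {
    rest <- .compositions(n - i, k - 1L)
    out[[i]] <- cbind(i, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Number of rotations at a refinement level
#' @param level Refinement integer n >= 1.
#' @return `10 * (5 n^3 + n)`.
#' @export
rotation_count <- function(level) {
  10 * (5 * level^3 + level)
}

#' Quasi-uniform rotation group
#'
#' Subdivides each tetrahedral cell of the 600-cell `level` times,
#' projects the barycentric grid points onto the unit 3-sphere, and
#' identifies antipodal quaternions (q and -q encode the same rotation).
#' The result covers SO(3) quasi-uniformly with exactly
#' `10 (5 level^3 + level)` rotations and uniform quadrature weights.
#'
#' @param level Refinement integer n >= 1 (level 6 gives the 10 860-rotation
#'   coarse group; level 24 gives 691 440).
#' @return Object of class `rotation_group`: `quaternions` (count x 4),
#'   `weights` (summing to 1), `level`, `count`.
#' @export
rotation_group <- function(level) {
  level <- as.integer(level)
  if (length(level) != 1L || is.na(level) || level < 1L)
    stop("'level' must be an integer >= 1")
  s <- .cell600_structure()
  V <- s$V; anti <- s$anti; n <- level
  pts <- list()
  # vertices: one per antipodal pair
  vkeep <- which(seq_len(nrow(V)) < anti)
  pts[[1]] <- V[vkeep, , drop = FALSE]
  if (n >= 2L) {
    e <- .canonical_half(s$edges, anti)
    co <- .compositions(n, 2L) / n
    pts[[2]] <- do.call(rbind, lapply(seq_len(nrow(e)), function(r)
      co %*% V[e[r, ], , drop = FALSE]))
  }
  if (n >= 3L) {
    f <- .canonical_half(s$faces, anti)
    co <- .compositions(n, 3L) / n
    pts[[3]] <- do.call(rbind, lapply(seq_len(nrow(f)), function(r)
      co %*% V[f[r, ], , drop = FALSE]))
  }
  if (n >= 4L) {
    ce <- .canonical_half(s$cells, anti)
    co <- .compositions(n, 4L) / n
    pts[[4]] <- do.call(rbind, lapply(seq_len(nrow(ce)), function(r)
      co %*% V[ce[r, ], , drop = FALSE]))
  }
  P <- do.call(rbind, pts)
  P <- P / sqrt(rowSums(P^2))
  # canonical sign: first component of significant magnitude positive
  for (r in seq_len(nrow(P))) {
    nz <- which(abs(P[r, ]) > 1e-8)[1]
    if (P[r, nz] < 0) P[r, ] <- -P[r, ]
  }
  stopifnot(nrow(P) == rotation_count(n))
  g <- list(quaternions = P, weights = rep(1 / nrow(P), nrow(P)),
            level = n, count = nrow(P))
  class(g) <- "rotation_group"
  g
}

#' @exportS3Method base::print
print.rotation_group <- function(x, ...) {
  cat(sprintf("rotation_group: level %d, %d rotations (~%.1f deg spacing)\n",
              x$level, x$count, 72 / x$level))
  invisible(x)
}
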