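# Small shared utilities: seeded evaluation, quaternion algebra, array shifts.

# evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# quaternions are length-4 numeric (w, x, y, z), unit norm

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Rotation matrix of a unit quaternion
#' @param q Unit quaternion `c(w, x, y, z)`.
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# rotation angle (radians, in [0, pi]) represented by a unit quaternion
quat_rotation_angle <- function(q) 2 * acos(pmin(1, abs(q[1])))

# geodesic distance between two rotations (radians), antipodal-aware
rotation_distance <- function(a, b) {
  2 * acos(pmin(1, abs(sum(a * b))))
}

# fftshift moves the zero-frequency bin (index 1) to the center bin
# floor(n/2) + 1; ifftshift undoes it (they differ for odd n)
.shift_ind <- function(n, inverse = FALSE) {
  h <- if (inverse) floor(n / 2) else ceiling(n / 2)
  c((h + 1):n, 1:h)
}

fftshift3 <- function(a) {
  d <- dim(a)
  a[.shift_ind(d[1]), .shift_ind(d[2]), .shift_ind(d[3]), drop = FALSE]
}

ifftshift3 <- function(a) {
  d <- dim(a)
  a[.shift_ind(d[1], TRUE), .shift_ind(d[2], TRUE), .shift_ind(d[3], TRUE), drop = FALSE]
}

# signed DFT frequency indices 0,1,...,-1 for length n
fft_freqs <- function(n) {
  u <- 0:(n - 1)
  u[u > n / 2] <- u[u > n / 2] - n
  u
}
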