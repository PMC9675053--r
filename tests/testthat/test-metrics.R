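# Volume registration, the 3D R factor, and threshold resolution.

toy_volume <- function(values, vx = 0.03) intensity_volume(values, vx)

test_that("R factor matches a brute-force evaluation on 5^3 toys", {
  withr::with_seed(19, {
    a <- array(sample(0:9, 125, replace = TRUE) + 0.0, c(5, 5, 5))
    b <- array(sample(0:9, 125, replace = TRUE) + 0.0, c(5, 5, 5))
  })
  va <- toy_volume(a); vb <- toy_volume(b)
  d_nm <- c(2 * pi / (0.03 * 10) / 2.5, 2 * pi / (0.03 * 10) / 1.2)
  curve <- r_factor(va, vb, d_nm)
  # spreadsheet-style oracle: explicit loops over voxels
  c0 <- 3
  for (row in seq_len(nrow(curve))) {
    qcut <- 2 * pi / (curve$resolution_nm[row] * 10)
    sa <- 0; sb <- 0; n <- 0
    for (i in 1:5) for (j in 1:5) for (k in 1:5) {
      q <- 0.03 * sqrt((i - c0)^2 + (j - c0)^2 + (k - c0)^2)
      if (q <= qcut) { sa <- sa + a[i, j, k]; sb <- sb + b[i, j, k]; n <- n + 1 }
    }
    rr <- 0
    for (i in 1:5) for (j in 1:5) for (k in 1:5) {
      q <- 0.03 * sqrt((i - c0)^2 + (j - c0)^2 + (k - c0)^2)
      if (q <= qcut) rr <- rr + abs(a[i, j, k] / sa - b[i, j, k] / sb)
    }
    expect_equal(curve$r[row], rr, tolerance = 1e-12)
    expect_equal(curve$n_voxels[row], n)
  }
})

test_that("R is 0 for identical or rescaled volumes and 2 for disjoint ones", {
  v <- toy_volume(array(runif(343, 0.1, 1), c(7, 7, 7)))
  d <- 2 * pi / (0.03 * 10) / c(3, 2, 1)
  expect_equal(r_factor(v, v, d)$r, c(0, 0, 0), tolerance = 1e-12)
  v2 <- toy_volume(3.7 * v$values)
  expect_equal(r_factor(v2, v, d)$r, c(0, 0, 0), tolerance = 1e-12)
  a <- array(0, c(7, 7, 7)); b <- array(0, c(7, 7, 7))
  a[1:3, , ] <- 1; b[5:7, , ] <- 1
  disj <- r_factor(toy_volume(a), toy_volume(b), d[3])
  expect_equal(disj$r, 2, tolerance = 1e-12)
  expect_true(all(disj$r >= 0 & disj$r <= 2))
  # all-zero inside a cutoff is an error
  z <- toy_volume(array(0, c(7, 7, 7)))
  expect_error(r_factor(z, v, d), "usable intensity")
})

test_that("R is invariant under a common rotation and rises with noise", {
  hf <- hio_fixture()
  v <- hf$vol
  d <- c(1.6, 1.2, 0.9, 0.7)
  base <- r_factor(v, v, d)$r
  qrot <- withr::with_seed(23, sample_orientation(1))
  M <- quat_to_matrix(qrot[1, ])
  rot <- spisim:::rotate_resample_cpp(v$values, M, v$center)
  rot[!is.finite(rot)] <- NA_real_
  vr <- intensity_volume(rot, v$voxel_size)
  both <- r_factor(vr, vr, d)
  expect_equal(both$r, base, tolerance = 0.02)
  # one-sided rotation is far from zero, the common rotation is not
  mixed <- r_factor(vr, v, d)
  expect_gt(max(mixed$r), 0.2)
  # median R grows with the amplitude of added noise
  meds <- vapply(c(0.05, 0.2, 0.8), function(amp) {
    rs <- vapply(1:20, function(i) {
      noisy <- pmax(v$values * (1 + amp * array(withr::with_seed(100 * amp + i,
        rnorm(length(v$values))), dim(v$values))), 0)
      r_factor(intensity_volume(noisy, v$voxel_size), v, 0.9)$r
    }, numeric(1))
    median(rs)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("threshold crossing interpolates in 1/D with the stated flags", {
  curve <- structure(data.frame(resolution_nm = c(3, 2), r = c(0.1, 0.3),
                                n_voxels = c(10, 20)),
                     class = c("rfactor_curve", "data.frame"))
  res <- resolution_at_threshold(curve, 0.2)
  expect_equal(res$resolution_nm, 2.4, tolerance = 1e-12)
  expect_equal(res$flag, "crossed")
  low <- curve; low$r <- c(0.05, 0.05)
  expect_equal(resolution_at_threshold(low, 0.2)$flag, "detector-limited")
  expect_equal(resolution_at_threshold(low, 0.2)$resolution_nm, 2)
  hi <- curve; hi$r <- c(0.5, 0.6)
  expect_equal(resolution_at_threshold(hi, 0.2)$flag, "unresolved")
  expect_equal(resolution_at_threshold(hi, 0.2)$resolution_nm, 3)
  expect_error(resolution_at_threshold(curve[0, ], 0.2), "empty")
})

test_that("registration recovers a known rotation of a phantom volume", {
  hf <- hio_fixture()
  ref <- hf$vol
  qrot <- withr::with_seed(29, sample_orientation(1))[1, ]
  M <- quat_to_matrix(qrot)
  # build the rotated volume: V'(x) = V(M x), so registering V' to V must
  # find M^-1 ... and registering V' against ref recovers M itself
  rot <- spisim:::rotate_resample_cpp(ref$values, M, ref$center)
  rot[!is.finite(rot)] <- NA_real_
  vr <- intensity_volume(rot, ref$voxel_size)
  reg <- register_rotation(vr, ref, coarse_level = 6)
  expect_gt(reg$correlation, 0.98)
  ang <- spisim:::rotation_distance(reg$quaternion,
                                    spisim:::quat_conjugate(qrot))
  expect_lt(ang * 180 / pi, 5)
  # self-registration is the identity
  self <- register_rotation(ref, ref, coarse_level = 3)
  expect_gt(self$correlation, 0.999)
  expect_lt(spisim:::quat_rotation_angle(self$quaternion) * 180 / pi, 1.5)
  # Friedel-symmetric volumes score a rotation and its inversion equally
  pts <- which(voxel_radii(ref) > 3 & voxel_radii(ref) < 14)
  ind <- arrayInd(pts, dim(ref$values))
  offs <- sweep(ind, 2, ref$center)
  cc1 <- spisim:::corr_quats_cpp(ref$values, offs, ref$values[pts],
                                 rbind(qrot), ref$center)
  cc2 <- spisim:::corr_quats_cpp(ref$values, -offs, ref$values[pts],
                                 rbind(qrot), ref$center)
  expect_equal(cc1, cc2, tolerance = 1e-9)
  expect_error(register_rotation(
    intensity_volume(array(1, dim(ref$values)), ref$voxel_size), ref),
    "degenerate")
})
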