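# EMC building blocks: expand, maximize, compress, schedules, and
# small-scale reconstruction properties.

# a small pattern set with hand-controllable counts
tiny_pattern_set <- function(counts_list, geometry) {
  sparse <- lapply(counts_list, function(m) {
    nz <- which(m > 0)
    list(index = nz, count = as.integer(m[nz]))
  })
  pattern_set(sparse, sample_orientation(length(counts_list)), geometry)
}

test_that("expand reproduces an analytic field on the Ewald slice", {
  g <- desk_geometry(32, pixel = 4e-3, beamstop = 0)
  qm <- build_qmap(g)
  edge <- 41L
  vx <- grid_voxel_size(qm, edge)
  c0 <- floor(edge / 2) + 1
  ax <- ((1:edge) - c0) * vx
  grid <- as.matrix(expand.grid(ax, ax, ax))
  f <- array(rowSums(grid^2), rep(edge, 3))   # f(q) = |q|^2
  vol <- intensity_volume(f, vx)
  W <- emc_expand(vol, rbind(c(1, 0, 0, 0)), qm)
  qmag2 <- rowSums(qm$q_vectors^2)
  # trilinear interpolation of |q|^2 on spacing h overestimates by <= h^2/2
  expect_lt(max(abs(W[1, ] - qmag2)), 3 * vx^2)
  # a constant model expands to constant tomograms under any rotation
  volc <- intensity_volume(array(2.5, rep(edge, 3)), vx)
  Wc <- emc_expand(volc, sample_orientation(5), qm)
  expect_equal(as.numeric(Wc), rep(2.5, length(Wc)), tolerance = 1e-12)
})

test_that("expand of the ideal volume matches the pattern expectation", {
  m <- make_phantom(10, extent = 1.6, seed = 13)
  g <- desk_geometry(32, pixel = 4e-3, beamstop = 0)
  qm <- build_qmap(g)
  vx <- grid_voxel_size(qm, 63)
  vol <- build_ideal_volume(m, 63, vx)
  qrot <- withr::with_seed(8, sample_orientation(1))
  W <- emc_expand(vol, qrot, qm)
  b <- reference_beam()
  mu <- spisim:::expected_patterns(m, qm, b, qrot)[, 1]
  ff2 <- mu / (as.numeric(qm$solid_angles) * as.numeric(qm$thomson_factors) *
                 fluence(b))
  strong <- ff2 > 0.01 * max(ff2)
  rel <- abs(W[1, ] - ff2) / pmax(ff2, 1e-12)
  expect_lt(median(rel[strong]), 0.02)
})

test_that("maximize matches a brute-force enumeration on a toy problem", {
  g <- detector_geometry(0.25, 5e-3, c(2, 2), 6, beamstop_radius = 0)
  K <- list(matrix(c(1L, 0L, 2L, 0L), 2, 2), matrix(c(0L, 3L, 1L, 1L), 2, 2))
  ps <- withr::with_seed(1, tiny_pattern_set(K, g))
  W <- rbind(c(0.5, 1.0, 2.0, 0.3), c(1.5, 0.2, 0.7, 1.1))
  out <- emc_maximize(ps, W, beta = 1)
  # independent oracle: direct Poisson likelihood enumeration
  Pref <- matrix(NA_real_, 2, 2)
  for (k in 1:2) {
    ll <- vapply(1:2, function(j)
      sum(stats::dpois(as.numeric(K[[k]]), W[j, ], log = TRUE)), numeric(1))
    Pref[, k] <- exp(ll - max(ll)) / sum(exp(ll - max(ll)))
  }
  expect_equal(out$responsibilities, Pref, tolerance = 1e-12)
  Wref <- (outer(Pref[, 1], as.numeric(K[[1]])) +
             outer(Pref[, 2], as.numeric(K[[2]]))) / rowSums(Pref)
  expect_equal(out$tomograms, Wref, tolerance = 1e-12)
  # beta -> 0: responsibilities become uniform over the group
  out0 <- emc_maximize(ps, W, beta = 1e-12)
  expect_equal(as.numeric(out0$responsibilities), rep(0.5, 4), tolerance = 1e-6)
  # degenerate one-rotation group: unit responsibilities, mean pattern
  out1 <- emc_maximize(ps, W[1, , drop = FALSE], beta = 1)
  expect_equal(as.numeric(out1$responsibilities), c(1, 1))
  expect_equal(as.numeric(out1$tomograms),
               (as.numeric(K[[1]]) + as.numeric(K[[2]])) / 2)
})

test_that("repeated maximize steps never decrease the log-likelihood", {
  # exact EM monotonicity on a fixed tomogram stack (no compression step)
  m <- desk_phantom(15, seed = 2)
  g <- desk_geometry(24, pixel = 5.5e-3, beamstop = 1)
  ds <- make_dataset(m, g, reference_beam(), "poisson_only", 80,
                     seed = 6, target_occupancy = 0.3)
  grp <- rotation_group(2)
  W <- matrix(withr::with_seed(3, runif(grp$count * sum(!ds$mask), 0.05, 0.5)),
              grp$count)
  lls <- numeric(8)
  for (i in seq_along(lls)) {
    st <- emc_maximize(ds, W, beta = 1)
    lls[i] <- st$loglik
    W <- pmax(st$tomograms, 1e-12)
  }
  expect_true(all(diff(lls) >= -1e-9 * abs(lls[-1])))
})

test_that("compress inverts expand on smooth volumes and conserves photons", {
  g <- desk_geometry(32, pixel = 4e-3, beamstop = 0)
  qm <- build_qmap(g)
  edge <- 33L
  vx <- grid_voxel_size(qm, edge)
  c0 <- floor(edge / 2) + 1
  ax <- ((1:edge) - c0) * vx
  grid <- as.matrix(expand.grid(ax, ax, ax))
  smooth <- array(exp(-rowSums(grid^2) / (2 * (10 * vx)^2)), rep(edge, 3))
  vol <- intensity_volume(smooth, vx)
  grp <- rotation_group(6)   # rotationally rich: ~10^4 slices per voxel shell
  W <- emc_expand(vol, grp, qm)
  # constant tomograms compress to a constant on touched voxels
  cst <- emc_compress(matrix(1.7, grp$count, ncol(W)), grp, qm, edge, vx)
  touched <- cst$values > 0
  expect_equal(cst$values[touched], rep(1.7, sum(touched)), tolerance = 1e-9)
  back <- emc_compress(W, grp, qm, edge, vx)
  cp <- spisim:::compress_cpp(W, rep(1, grp$count), grp$quaternions,
                              qm$q_vectors / vx, c0, edge)
  # compare on voxels with meaningful accumulated weight (> 1), inside the
  # fully covered sphere (the outermost shell is only grazed by Ewald
  # slices and its weight-normalized average is biased)
  den_ok <- cp$den > 1 &
    voxel_radii(vol) <= max(qm$q_magnitudes) / vx - 1
  rel <- abs(back$values - vol$values)[den_ok] / vol$values[den_ok]
  expect_lt(stats::quantile(rel, 0.95), 0.05)
  # photon-weighted mass balance between stack and volume
  expect_equal(sum(cp$num), sum(W), tolerance = 0.01 * sum(W))
  expect_error(emc_compress(W[0, , drop = FALSE], grp, qm, edge, vx), "empty")
})

test_that("the annealing schedule reaches 1 exactly when designed to", {
  cfg <- full_scale_emc_config()
  expect_equal(cfg$beta_start * cfg$beta_factor^19, 0.724, tolerance = 1e-3)
  # 0.001 * sqrt(2)^20 = 1.024, clipped to 1 at iteration 201
  expect_equal(emc_beta(cfg, 201), 1)
  expect_equal(emc_beta(cfg, 195), 1.024 / sqrt(2), tolerance = 1e-3)
  expect_true(cfg$cluster_scale)
  expect_error(emc_config(grid_edge = 64), "odd")
})

test_that("single-orientation data with a one-rotation group converge at once", {
  m <- desk_phantom(15, seed = 2)
  g <- desk_geometry(24, pixel = 5.5e-3, beamstop = 1)
  qm <- build_qmap(g)
  ds <- make_dataset(m, g, reference_beam(), "poisson_only", 120,
                     seed = 10, target_occupancy = 0.5)
  # overwrite orientations: every snapshot shares the identity
  ds$sparse <- withr::with_seed(10, {
    mu <- spisim:::expected_patterns(m, qm, reference_beam(), c(1, 0, 0, 0),
                                     ds$provenance$fluence_scale)[, 1]
    upix <- which(!ds$mask)
    lapply(1:120, function(i) {
      ct <- rpois(length(upix), mu[upix])
      nz <- which(ct > 0)
      list(index = upix[nz], count = ct[nz])
    })
  })
  ds$orientations <- matrix(rep(c(1, 0, 0, 0), 120), ncol = 4, byrow = TRUE)
  W0 <- emc_expand(intensity_volume(array(1, rep(33, 3)),
                                    grid_voxel_size(qm, 33)),
                   rbind(c(1, 0, 0, 0)), qm)
  st <- emc_maximize(ds, W0, beta = 1)
  mean_pat <- Reduce(`+`, lapply(1:120, function(i) {
    v <- numeric(prod(g$shape)); s <- ds$sparse[[i]]; v[s$index] <- s$count; v
  })) / 120
  expect_equal(as.numeric(st$tomograms), mean_pat[!ds$mask], tolerance = 1e-12)
})

test_that("reconstruction is equivariant under a global rotation of the data", {
  m <- desk_phantom(25, seed = 4)
  g <- desk_geometry(40, pixel = 3.2e-3, beamstop = 1)
  beam <- reference_beam()
  cfg <- emc_config(grid_edge = 43, n_iterations = 24,
                    rotation_schedule = data.frame(iteration = c(1, 13),
                                                   level = c(3, 4)),
                    beta_start = 0.1, beta_factor = sqrt(2), beta_period = 3,
                    seed = 5)
  qm <- build_qmap(g)
  Rg <- withr::with_seed(77, sample_orientation(1))
  mk <- function(rot) {
    quats <- withr::with_seed(55, sample_orientation(1500))
    if (!is.null(rot))
      quats <- t(apply(quats, 1, function(qq) spisim:::quat_multiply(rot, qq)))
    mu <- spisim:::expected_patterns(m, qm, beam, quats, fluence_scale = 1)
    occ <- mean(mu[!as.vector(beamstop_mask(g)), ])
    mu <- mu * (6.0 / occ)
    upix <- which(!beamstop_mask(g))
    sparse <- withr::with_seed(66, lapply(seq_len(ncol(mu)), function(k) {
      ct <- rpois(length(upix), mu[upix, k])
      nz <- which(ct > 0)
      list(index = upix[nz], count = ct[nz])
    }))
    pattern_set(sparse, quats, g)
  }
  v1 <- run_emc(mk(NULL), cfg)
  v2 <- run_emc(mk(Rg[1, ]), cfg)
  # compare on the well-covered shell (high-SNR region of both volumes)
  reg <- register_rotation(v2, v1, coarse_level = 4, r_outer = 15)
  expect_gt(reg$correlation, 0.99)
})
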