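# Forward simulator: structure factors, orientation sampling, Poisson
# snapshots, and the ideal reciprocal-space volume.

test_that("models count electrons and reject bad input", {
  m <- atomic_model(c("C", "N", "O"), rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0)))
  expect_identical(m$total_electrons, 21L)
  expect_error(atomic_model(character(0), matrix(0, 0, 3)), "empty")
  expect_error(atomic_model("Xx", matrix(0, 1, 3)), "unknown element")
  # f(0) equals the atomic number for every tabulated element
  z <- atomic_number(known_elements())
  expect_equal(form_factor(known_elements(), 0)[1, ], z, tolerance = 2e-3,
               ignore_attr = TRUE)
})

test_that("a hand-written PDB loads with and without heteroatoms", {
  pdb <- file.path(tempdir(), "tri.pdb")
  writeLines(c(
    sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            1:3, c("C", "N", "O"), "GLY", 1, c(0, 1.5, 0), c(0, 0, 2.0),
            c(0, 0, 0), c("C", "N", "O")),
    sprintf("HETATM%5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            4, "MG", "MG", 2, 5.0, 5.0, 5.0, "MG"),
    "END"), pdb)
  m <- load_model(pdb, strip_het = TRUE)
  expect_identical(m$total_electrons, 21L)
  expect_identical(m$n_atoms, 3L)
  full <- load_model(pdb, strip_het = FALSE)
  expect_identical(full$total_electrons, 33L)
})

test_that("structure factors obey the two-slit and Friedel identities", {
  m1 <- atomic_model("C", matrix(0, 1, 3))
  q <- rbind(c(0.3, -0.1, 0.2), c(0, 0, 0))
  F1 <- structure_factor(m1, q)
  expect_equal(Im(F1), c(0, 0), tolerance = 1e-12)
  expect_equal(Mod(F1), form_factor("C", sqrt(rowSums(q^2))), tolerance = 1e-12)
  # two identical atoms: |F|^2 = 4 f^2 cos^2(q.d/2)
  d <- c(3, 0, 0)
  m2 <- atomic_model(c("C", "C"), rbind(-d / 2, d / 2))
  qs <- cbind(seq(0, 2, by = 0.02), 0, 0)
  I2 <- Mod(structure_factor(m2, qs))^2
  expect_equal(I2, 4 * form_factor("C", qs[, 1])^2 * cos(qs[, 1] * 1.5)^2,
               tolerance = 1e-9)
  # Friedel: |F(q)| = |F(-q)| for any real density
  m3 <- desk_phantom(12, seed = 5)
  qr <- matrix(rnorm(30, sd = 0.3), 10, 3)
  expect_equal(Mod(structure_factor(m3, qr)), Mod(structure_factor(m3, -qr)),
               tolerance = 1e-12)
})

test_that("|F|^2 is invariant under joint rotation of model and q-grid", {
  m <- desk_phantom(10, seed = 9)
  qs <- matrix(rnorm(60, sd = 0.4), 20, 3)
  base <- Mod(structure_factor(m, qs))^2
  for (qrot in list(c(0.8, 0.6, 0, 0), c(0.5, 0.5, 0.5, 0.5), c(0, 1, 0, 0))) {
    R <- quat_to_matrix(qrot)
    mr <- atomic_model(m$elements, m$coordinates %*% t(R))
    rot <- Mod(structure_factor(mr, qs %*% t(R)))^2
    expect_equal(rot, base, tolerance = 1e-8)
  }
})

test_that("snapshot photons are Poisson draws of the analytic expectation", {
  m <- desk_phantom(20, seed = 3)
  g <- desk_geometry(32, pixel = 4e-3, beamstop = 1)
  qm <- build_qmap(g)
  b <- reference_beam()
  # zero fluence gives an empty pattern
  b0 <- beam_parameters(0, 0.38, c(250e-9, 150e-9), 6)
  p0 <- withr::with_seed(1, simulate_pattern(m, g, b0, qmap = qm))
  expect_true(all(p0$photons[!p0$mask] == 0L))
  expect_true(all(is.na(p0$photons[p0$mask])))
  # scale to ~2 photons/pixel and check the Monte-Carlo mean pixel-wise
  mu1 <- spisim:::expected_patterns(m, qm, b, c(1, 0, 0, 0))
  fs <- 2 / mean(mu1[!as.vector(p0$mask), 1])
  mu <- mu1[, 1] * fs
  draws <- withr::with_seed(42, vapply(1:200, function(i)
    as.integer(simulate_pattern(m, g, b, qmap = qm,
                                fluence_scale = fs)$photons),
    integer(length(mu))))
  mean_obs <- rowMeans(draws, na.rm = TRUE)
  se <- sqrt(mu / 200)
  ok <- abs(mean_obs - mu) <= 5 * pmax(se, 1e-6)
  ok <- ok[!as.vector(p0$mask)]
  expect_gt(mean(ok), 0.99)
  # expected totals scale linearly with fluence
  expect_equal(sum(mu1 * 2), sum(spisim:::expected_patterns(
    m, qm, b, c(1, 0, 0, 0), fluence_scale = 2)), tolerance = 1e-12)
})

test_that("the ideal volume is Friedel-symmetric and slice-consistent", {
  m <- make_phantom(10, extent = 1.6, seed = 13)  # compact: high oversampling
  g <- desk_geometry(32, pixel = 4e-3, beamstop = 0)
  qm <- build_qmap(g)
  vx <- grid_voxel_size(qm, 63)
  vol <- build_ideal_volume(m, 63, vx)
  expect_equal(vol$values[32, 32, 32], m$total_electrons^2, tolerance = 1e-3)
  expect_equal(vol$values, vol$values[63:1, 63:1, 63:1], tolerance = 1e-9)
  # Ewald-matched lookup of the central slice against the pattern expectation
  b <- reference_beam()
  mu <- spisim:::expected_patterns(m, qm, b, c(1, 0, 0, 0))[, 1]
  ff2 <- mu / (as.numeric(qm$solid_angles) * as.numeric(qm$thomson_factors) *
                 fluence(b))
  pts <- sweep(qm$q_vectors / vx, 2, c(0, 0, 0)) + vol$center
  look <- spisim:::trilinear_cpp(vol$values, pts)
  # keep pixels where the Ewald curvature displacement is under half a voxel
  curv_ok <- abs(qm$q_vectors[, 3] / vx) < 0.5
  strong <- ff2 > 0.01 * max(ff2)
  rel <- abs(look - ff2) / ff2
  expect_lt(median(rel[curv_ok & strong]), 0.02)
})
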