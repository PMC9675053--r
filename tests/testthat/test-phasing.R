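# Phase retrieval: preprocessing, HIO projections, alignment, ensembles.

test_that("the preprocessing plan mirrors the full-scale 951 -> 552 -> 276 chain", {
  pl <- preprocess_plan(951)
  expect_identical(pl$trim, 552L)
  expect_identical(pl$out, 276L)
  # proportional scaling at desk sizes stays even and binnable
  pl2 <- preprocess_plan(63)
  expect_identical(pl2$trim, 36L)
  expect_identical(pl2$out, 18L)
})

test_that("preprocess trims, mean-bins, and masks the central sphere", {
  edge <- 57L
  vals <- array(4.2, rep(edge, 3))
  vol <- intensity_volume(vals, 0.01)
  out <- preprocess_volume(vol, trim = 32, bin = 2, mask_radius = 5)
  expect_identical(out$edge, 16L)
  expect_equal(out$voxel_size, 0.02)
  # constant volume: mean binning preserves the value exactly
  expect_equal(as.numeric(out$values), rep(4.2, 16^3), tolerance = 1e-12)
  # masked-voxel count equals the lattice-point enumeration
  expect_identical(sum(out$mask), sphere_voxel_count(5))
  brute <- 0L
  for (x in -5:5) for (y in -5:5) for (z in -5:5)
    if (x^2 + y^2 + z^2 <= 25) brute <- brute + 1L
  expect_identical(brute, 515L)
  expect_identical(sum(out$mask), brute)
  expect_error(preprocess_volume(vol, trim = 80), "smaller than")
  # a gradient along x bins to pairwise means
  gr <- array(rep(1:16, 16 * 16), c(16, 16, 16))
  vg <- intensity_volume(gr, 0.01)
  og <- preprocess_volume(vg, trim = 16, bin = 2, mask_radius = 0)
  expect_equal(og$values[, 1, 1], seq(1.5, 15.5, by = 2))
})

test_that("HIO holds the truth fixed and zero data give zero density", {
  hf <- hio_fixture()
  mags <- sqrt(hf$vol$values)
  measured <- array(TRUE, dim(mags))
  support <- spherical_support(hf$edge, 14)
  truth <- hf$truth
  expect_true(all(abs(truth[!support]) < 1e-6 * max(truth)))
  out <- hio_run(mags, measured, support, n_iterations = 5, feedback = 0.9,
                 positivity = FALSE, init = truth)
  expect_lt(out$error, 1e-10)
  expect_equal(out$density, truth, tolerance = 1e-8)
  z <- hio_run(array(0, dim(mags)), measured, support, n_iterations = 3,
               seed = 1)
  expect_equal(max(abs(z$density)), 0)
  expect_error(hio_run(mags, array(FALSE, dim(mags)), support), "masked")
})

test_that("magnitude projection restores measured amplitudes exactly", {
  hf <- hio_fixture()
  mags <- sqrt(hf$vol$values)
  measured <- voxel_radii(hf$vol) > 2
  support <- spherical_support(hf$edge, 14)
  out <- hio_run(mags, measured, support, n_iterations = 3, seed = 2)
  # one more explicit projection step on the final iterate
  mw <- spisim:::ifftshift3(mags); ms <- spisim:::ifftshift3(measured)
  G <- fft(spisim:::ifftshift3(out$density))
  Gp <- G
  Gp[ms] <- mw[ms] * G[ms] / Mod(G)[ms]
  expect_equal(Mod(Gp)[ms], mw[ms], tolerance = 1e-9)
  # masked voxels keep whatever amplitude the iterate carries
  expect_equal(Gp[!ms], G[!ms])
})

test_that("alignment recovers integer, fractional and inverted displacements", {
  hf <- hio_fixture()
  truth <- hf$truth
  self <- align_to_reference(truth, truth)
  expect_equal(attr(self, "shift"), c(0, 0, 0), tolerance = 1e-6)
  expect_gt(attr(self, "correlation"), 0.999999)
  shifted <- spisim:::.fourier_shift(truth, c(1.3, -0.7, 2.1))
  back <- align_to_reference(shifted, truth)
  expect_equal(attr(back, "shift"), -c(1.3, -0.7, 2.1), tolerance = 0.1)
  expect_gt(attr(back, "correlation"), 0.99)
  n <- dim(truth)[1]
  inv <- truth[n:1, n:1, n:1]
  fixed <- align_to_reference(inv, truth)
  expect_true(attr(fixed, "inverted"))
  expect_gt(attr(fixed, "correlation"), 0.99)
  expect_error(align_to_reference(array(0, dim(truth)), truth), "zero density")
})

test_that("best-run selection is permutation-invariant and averaging helps", {
  hf <- hio_fixture()
  vol <- hf$vol
  vol$mask <- voxel_radii(vol) <= 2
  cfg <- phasing_config(n_starts = 6, n_iterations = 120, support_radius = 14,
                        n_best = 3, seed = 40)
  dens <- ensemble_phase(vol, cfg, total_electrons = hf$phantom$total_electrons)
  expect_equal(sum(dens$density), hf$phantom$total_electrons, tolerance = 1e-6)
  expect_true(all(dens$density[!dens$support] == 0))
  # permuting the start order cannot change which runs are selected
  errs <- dens$metadata$errors
  perm <- rev(seq_along(errs))
  expect_setequal(perm[order(errs[perm])[1:3]], order(errs)[1:3])
  # the ensemble is at least as faithful as the median single start
  aligned <- align_to_reference(dens$density, hf$truth)
  cc_ens <- attr(aligned, "correlation")
  singles <- vapply(1:6, function(k) {
    one <- hio_run(sqrt(pmax(vol$values, 0)) * !vol$mask,
                   !vol$mask & voxel_radii(vol) <= 31,
                   spherical_support(vol$edge, 14),
                   n_iterations = 120, seed = 40 + k)
    attr(align_to_reference(one$density, hf$truth), "correlation")
  }, numeric(1))
  expect_gte(cc_ens, median(singles) - 0.02)
  expect_error(phasing_config(n_starts = 2, n_best = 5), "n_best")
})
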