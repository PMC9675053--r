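# Integrating-detector noise model: calibration fits, energy scaling,
# corruption, and threshold photonization.

test_that("stored configurations reproduce the scaled peaks and separations", {
  std <- agipd_noise_model("standard", 6)
  low <- agipd_noise_model("low_noise", 6)
  # one-photon peaks scaled from the 8 keV fluorescence measurement
  expect_equal(std$peaks_keV[2], 6.07, tolerance = 1e-3)
  expect_equal(low$peaks_keV[2], 6.11, tolerance = 1e-3)
  expect_equal(peak_separation(std), 4.07, tolerance = 1e-3)
  expect_equal(peak_separation(low), 5.41, tolerance = 1e-3)
  expect_equal(std$sigma_avg, 1.49)
  expect_equal(low$sigma_avg, 1.13)
  # scaling to the source energy is the identity
  raw <- agipd_noise_model("standard", 8)
  expect_equal(scale_to_photon_energy(raw, 8)$peaks_keV, raw$peaks_keV)
  # sigma_avg equal to the one-photon peak makes the separation exactly 1
  nm <- noise_model(c(0, 2, 4), rep(2, 3), photon_energy = 2)
  expect_equal(peak_separation(nm), 1)
  expect_error(scale_to_photon_energy(std, -1), "keV")
})

test_that("sigma(k) linear fit and extrapolation are exact on a line", {
  nm <- noise_model(c(0, 8, 16), c(1.0, 1.2, 1.4), photon_energy = 8)
  expect_equal(nm$sigma_slope, 0.2, tolerance = 1e-12)
  expect_equal(nm$sigma_intercept, 1.0, tolerance = 1e-12)
  expect_equal(nm$sigma_avg, 1.2)
  # beyond the measured peaks: linear extrapolation of position and sigma
  expect_equal(spisim:::peak_position(nm, 5), 40)
  expect_equal(spisim:::peak_sigma(nm, 5), 2.0, tolerance = 1e-12)
})

test_that("calibration fit recovers the generating mixture", {
  gen <- noise_model(c(0, 8.09, 15.88), c(1.44, 1.49, 1.54), photon_energy = 8)
  h <- make_calibration_samples(gen, occupancy = 0.105, n = 18000L, seed = 5L)
  fit <- fit_calibration(h, n_peaks = 3)
  # zero- and one-photon peaks carry >90% of the samples: tight recovery;
  # the two-photon peak has only ~100 samples (SE ~0.15 keV), so its mean
  # and width are checked at their statistical limits
  expect_lt(abs(fit$peaks_keV[1] - 0), 0.1)
  expect_lt(abs(fit$peaks_keV[2] - 8.09), 0.1)
  expect_lt(abs(fit$peaks_keV[3] - 15.88), 0.5)
  expect_lt(max(abs(fit$sigmas_keV[1:2] / gen$sigmas_keV[1:2] - 1)), 0.1)
  expect_lt(abs(log(fit$sigmas_keV[3] / gen$sigmas_keV[3])), log(2))
  # a single pure Gaussian reduces to mean/sd
  h1 <- make_calibration_samples(noise_model(c(3, 4), c(0.5, 0.5), 1),
                                 occupancy = 0, n = 5000L, seed = 2L)
  f1 <- fit_calibration(h1, n_peaks = 1)
  expect_equal(f1$peaks_keV[1], mean(h1$values), tolerance = 1e-9)
  expect_equal(f1$sigmas_keV[1], sd(h1$values), tolerance = 1e-9)
  expect_error(fit_calibration(h1$values[1:100], 3), "too few")
})

test_that("corrupt draws from the per-count Gaussians", {
  std <- agipd_noise_model("standard", 6)
  n <- 1e5
  withr::with_seed(4, {
    zeros <- corrupt(integer(n), std)
    ones <- corrupt(rep(1L, n), std)
  })
  expect_equal(sd(zeros), spisim:::peak_sigma(std, 0), tolerance = 0.02)
  se <- std$sigma_avg / sqrt(n)
  expect_lt(abs(mean(ones) - std$peaks_keV[2]), 3 * se)
  # masked pixels pass through
  expect_true(is.na(corrupt(NA_integer_, std)))
  # sigma -> 0 limit is deterministic
  tiny <- noise_model(c(0, 6), c(1e-12, 1e-12), 6)
  expect_equal(corrupt(c(0L, 1L, 3L), tiny), c(0, 6, 18), tolerance = 1e-9)
})

test_that("photonization thresholds sit halfway between peaks", {
  std <- agipd_noise_model("standard", 6)
  unit <- std$peaks_keV[2]
  expect_identical(photonize(0.4 * unit, std), 0L)
  expect_identical(photonize(1.2 * unit, std), 1L)
  expect_identical(photonize(0.51 * unit, std), 1L)
  expect_identical(photonize(1.51 * unit, std), 2L)
  expect_identical(photonize(-3, std), 0L)
})

test_that("zero-photon false-positive rate matches the Gaussian tail", {
  std <- agipd_noise_model("standard", 6)
  p_analytic <- pnorm(0.5 * std$peaks_keV[2] / std$sigma_avg,
                      lower.tail = FALSE)
  n <- 1e6
  fp <- withr::with_seed(9, mean(photonize(corrupt(integer(n), std), std) > 0))
  se <- sqrt(p_analytic * (1 - p_analytic) / n)
  expect_lt(abs(fp - p_analytic), 4 * se)
  expect_equal(p_analytic, 0.021, tolerance = 0.02)
})

test_that("noiseless round trip is exact and error rate falls with separation", {
  counts <- matrix(rpois(4096, 0.2), 64, 64)
  tiny <- noise_model(c(0, 6, 12), rep(6 * 0.01, 3), 6)
  expect_identical(photonize(corrupt(counts, tiny), tiny), counts)
  errs <- vapply(c(2, 3, 4, 6, 8), function(sep) {
    nm <- noise_model(c(0, 6, 12), rep(6 / sep, 3), 6)
    withr::with_seed(31, mean(photonize(corrupt(counts, nm), nm) != counts))
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
  expect_gt(errs[1], errs[5])
})

test_that("corruption is independent across neighboring pixels", {
  std <- agipd_noise_model("standard", 6)
  x <- withr::with_seed(13, corrupt(matrix(0L, 300, 300), std))
  n <- length(x[-1, ])
  rho <- cor(as.numeric(x[-1, ]), as.numeric(x[-nrow(x), ]))
  expect_lt(abs(rho), 3 / sqrt(n))
})
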