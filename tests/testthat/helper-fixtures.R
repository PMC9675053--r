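# Shared fixtures: the reference instrument, a desk-scale instrument, and
# cached expensive end-to-end runs (computed once per test session).

# full-size reference instrument: 550x550 AGIPD quadrant at 6 keV, 0.25 m
reference_geometry <- function() {
  detector_geometry(sdd = 0.25, pixel_size = 200e-6, shape = c(550L, 550L),
                    photon_energy = 6, beamstop_radius = 5)
}

reference_beam <- function() {
  beam_parameters(pulse_energy = 4e-3, optics_efficiency = 0.38,
                  focus_fwhm = c(250e-9, 150e-9), photon_energy = 6)
}

# desk-scale instrument: same SDD/energy, coarse 64x64 detector reaching a
# similar edge resolution regime
desk_geometry <- function(n = 64L, pixel = 2e-3, beamstop = 2) {
  detector_geometry(sdd = 0.25, pixel_size = pixel, shape = c(n, n),
                    photon_energy = 6, beamstop_radius = beamstop)
}

desk_phantom <- function(n_atoms = 40L, extent = 4, seed = 7L) {
  make_phantom(n_atoms, extent = extent, seed = seed)
}

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- expr
  .fixture_cache[[key]]
}

# desk-scale EMC recovery: 1500 Poisson-only snapshots of the 40-atom
# phantom at ~0.1 photons/pixel, 63^3 grid, rotation levels 4 -> 6
desk_emc_fixture <- function() {
  cached_fixture("desk_emc", {
    phantom <- desk_phantom()
    geom <- desk_geometry()
    beam <- reference_beam()
    ds <- make_dataset(phantom, geom, beam, "poisson_only",
                       n_patterns = 1500L, seed = 11L,
                       target_occupancy = 0.1)
    cfg <- emc_config(grid_edge = 63L, n_iterations = 60L,
                      rotation_schedule = data.frame(
                        iteration = c(1L, 36L, 46L), level = c(4L, 5L, 6L)),
                      beta_start = 0.05, beta_factor = sqrt(2),
                      beta_period = 5L, seed = 3L)
    vol <- run_emc(ds, cfg)
    vx <- grid_voxel_size(build_qmap(geom), 63L)
    ideal <- build_ideal_volume(phantom, 63L, vx)
    reg <- register_rotation(vol, ideal)
    list(phantom = phantom, geom = geom, beam = beam, ds = ds, cfg = cfg,
         vol = vol, ideal = ideal, reg = reg)
  })
}

# noise-free HIO phantom: a Gaussian-blob (B-factor-smeared) 30-atom
# phantom rendered as compact electron density on a 64^3 grid (linear
# oversampling ~2.3), with the Fourier magnitudes derived from it
hio_fixture <- function() {
  cached_fixture("hio", {
    phantom <- make_phantom(30L, extent = 3.2, seed = 21L)
    dq <- 0.055
    edge <- 64L
    dx <- 2 * pi / (edge * dq)
    support_radius <- 14
    truth <- render_density(phantom, edge, dx, sigma = 2)
    supp <- spherical_support(edge, support_radius)
    truth[!supp] <- 0   # Gaussian tails beyond the support are ~1e-9
    Fw <- fft(spisim:::ifftshift3(truth))
    vol <- intensity_volume(spisim:::fftshift3(Mod(Fw))^2, dq)
    list(phantom = phantom, vol = vol, truth = truth, dq = dq, edge = edge,
         support_radius = support_radius)
  })
}
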