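---
title: "Virtual single-particle imaging with spisim: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual single-particle imaging with spisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spisim` is a desk-scale laboratory for x-ray free-electron-laser (XFEL)
single-particle imaging (SPI). It simulates the complete measurement and
analysis chain — coherent diffraction snapshots of a biomolecule in random
orientations, integrating-detector noise, expand–maximize–compress (EMC)
orientation recovery, hybrid input–output (HIO) phase retrieval, and
R-factor resolution estimation — so that the dependence of achievable
resolution on snapshot count and detector noise configuration can be
studied quantitatively on synthetic phantoms, and configured at full scale
for a ribosome-sized particle on a cluster.

This vignette documents the science the package implements, the tunable
parameters with their defaults, the synthetic-data generators, and the
design decisions taken where the underlying protocol leaves choices open.

## The forward model

A snapshot is a Poisson draw of the expected photon count per pixel,

$$\mu(\mathbf{q}) \;=\; \Omega \,
\frac{d\sigma_T(\theta)}{d\Omega}\, n_{\mathrm{in}}\,
\bigl|F(R\,\mathbf{q})\bigr|^2 ,$$

where $\Omega$ is the exact solid angle subtended by the pixel,
$d\sigma_T/d\Omega = r_e^2 P(\theta,\varphi)$ the differential Thomson
cross section with polarization factor $P$, $n_{\mathrm{in}}$ the fluence
(photons/area), $F$ the coherent structure factor of the atomic model, and
$R$ the (Haar-uniform) orientation of the snapshot. Radiation damage and
shot-to-shot intensity fluctuation are outside the model, so the
time-resolved sum over the pulse collapses to a single term with the total
fluence.

Structure factors use the Cromer–Mann four-Gaussian parameterization
$f(s) = \sum_j a_j e^{-b_j s^2} + c$ with $s = |\mathbf{q}|/4\pi$;
anomalous dispersion is neglected, which is accurate for the light elements
that dominate biomolecules at 6 keV. `f(0)` reproduces the atomic number to
about 0.1%, the fidelity of the published coefficients. Scattering vectors
live on the Ewald sphere: $|\mathbf{q}| = 4\pi \sin\theta/\lambda$ with
$\lambda[\mathrm{\AA}] = 12.3984 / E[\mathrm{keV}]$ (the conversion
constant is fixed so derived numbers are bit-stable).

Key geometry arithmetic and the values it produces for the reference
instrument (550×550 pixels of 200 µm at 0.25 m and 6 keV, 4 mJ pulses, 38%
optics efficiency, 250×150 nm² focus):

* `fluence()` — photons per pulse divided by the FWHM focus rectangle;
  the flat-top rectangle convention is adopted deliberately because it is
  the convention under which the published fluence (4.2×10²¹ photons/cm²)
  is reproduced; a Gaussian-equivalent area would differ by a factor
  $\pi/(4\ln 2) \approx 1.13$.
* `oversampling_ratio()` — $\mathrm{SDD}\cdot\lambda/(\mathrm{pixel}\cdot L)$,
  ≈ 12.9 per dimension for a 20 nm particle.
* `edge_resolution()` — full-period resolution $2\pi/|\mathbf{q}|$ at the
  detector edge midpoint (≈ 0.96 nm, the quoted "1 nm at the edge") and at
  the array corner (≈ 0.69 nm). Both are reported because figure captions
  in the SPI literature sometimes quote the coarser slice-diagonal value
  (1.2 nm) instead; the package does not guess which convention a given
  caption uses.
* The 5-pixel beamstop equals the 2 mm central gap of the detector
  (`beamstop_diameter_mm()`).

**Polarization.** XFELs are horizontally polarized, so the default factor is
$1 - (\sin 2\theta \cos\varphi)^2$; `vertical` and `unpolarized` are
options. At the maximal $2\theta \approx 12°$ of the reference geometry the
difference between conventions is below ~5%, smaller than the other noise
sources, which is why the choice is safe to default rather than expose as a
study condition.

## The detector noise model

An integrating pixel detector at low occupancy shows a histogram of keV
readouts with Gaussian peaks at 0, 1, 2, … photons. The model is purely
per-pixel: peak positions `peak(k)` and widths `sigma(k)`, with the widths
beyond the measured k = 0, 1, 2 taken from a linear least-squares fit
through the measured ones, and positions extrapolated with the last
measured interval.

Two stored configurations reproduce a single-pixel Cu-fluorescence
calibration of the AGIPD detector: the *standard* dynamic-range setting
(one-/two-photon peaks at 8.09/15.88 keV, σ_avg = 1.49 keV) and the
*low-noise* setting (8.15/16.02 keV, σ_avg = 1.13 keV). Because the raw
calibration samples are not published, the stored models carry the printed
constants; `fit_calibration()` (a Gaussian-mixture fit via `mclust`)
rebuilds a model from any histogram, and `make_calibration_samples()`
emulates one. The stored models set `sigma(k) = sigma_avg` for every k —
the simplest assignment consistent with every published number; whether the
original analysis drew multi-photon widths from the linear fit or reused
the average is not recorded, and at 0.1 photons/pixel the two choices are
indistinguishable (multi-photon pixels are ~0.5% of all pixels).

Peak positions scale linearly with photon energy — the stored 8 keV
(nominal Cu Kα) peaks scaled to 6 keV give 6.07 and 6.11 keV — while the
widths are an electronics property and stay fixed in keV. This preserves
the published σ_avg values and yields peak separations of 4.07 σ_avg
(standard) and 5.41 σ_avg (low noise), the single figure of merit for
photonization fidelity.

The corruption pipeline follows the published ordering exactly: Poisson
noise first, then each pixel with k photons is redrawn from
$N(\mathrm{peak}(k), \sigma(k))$, then *photonization* rounds back to
integers with thresholds halfway between peaks (below 0.5 photon units → 0,
between 0.5 and 1.5 → 1, …; negative readouts → 0). The zero-photon
false-positive rate is then the Gaussian tail
$1-\Phi(0.5\,\mathrm{peak}(1)/\sigma)$ ≈ 0.021 per pixel for the standard
setting — at ~0.1 photons/pixel that is one spurious photon for every five
real ones, which is the mechanism by which the standard setting degrades
reconstructions.

## EMC orientation recovery

The 3D intensity model lives on an odd cubic grid whose voxel size defaults
to `q_corner / ((edge-1)/2)` — the detector's corner scattering vector maps
to the half-grid radius, so every rotated Ewald slice stays inside the
grid. (The full-scale protocol quotes a 951³ grid with
Δq = 3.07438×10⁻⁴ Å⁻¹; that printed voxel size does not follow from any
single obvious geometry formula we tried, so the package computes Δq from
its own documented convention and records it in the volume metadata rather
than forcing the printed value. Both conventions are configurable.)

Each iteration: *expand* interpolates the model (trilinearly) onto the
Ewald slice of every rotation in a quasi-uniform grid over SO(3); the
E-step computes Poisson log-likelihood responsibilities
$P_{jk} \propto w_j \exp\!\big(\beta \sum_p [K_{kp}\log W_{jp} - W_{jp}]\big)$
in log-domain arithmetic (masked pixels skipped); the M-step forms the
responsibility-weighted mean pattern per rotation; *compress* scatters the
updated tomograms back onto the grid with trilinear weights, each weighted
by its responsibility mass, and the model is Friedel-symmetrized (the
intensities of a real density are centrosymmetric, which also removes the
inversion ambiguity from the orientation search). Ties between equally
likely rotations need no explicit rule: soft responsibilities split them
naturally.

The SO(3) grid is the barycentric subdivision of the 600-cell projected to
the unit quaternion sphere, with antipodal quaternions identified
combinatorially (each vertex/edge/face/cell paired with its exact antipode
by index, so the count `10(5n³+n)` is exact by construction, not by
floating-point deduplication). Level 6 gives the 10 860-rotation coarse
group; levels 9–24 give 36 540 … 691 440. In-plane detector rotations are
part of the 3D group; no separate in-plane factorization is used.
Quadrature weights are uniform — at these refinement levels the cell-volume
variation of the 600-cell subdivision is a second-order effect relative to
the Poisson noise, and uniform weights keep the prior exactly
orientation-neutral.

**Annealing.** A regularization factor β multiplies the log-likelihood
(deterministic annealing): small β keeps responsibilities diffuse and
protects the early iterations from erratic updates. The full-scale schedule
starts at β = 0.001 and multiplies by √2 every 10 iterations, reaching 1
(clipped) exactly at the end of the 200 coarse iterations
(0.001·(√2)²⁰ = 1.024). The √2 factor is a deliberate reading: the protocol
text says "factor of 2", but only √2 makes the schedule meet unity at the
stated iteration count — a factor of 2 would hit β = 1 at iteration 100 and
make the remaining 100 coarse iterations indistinguishable; the radical was
evidently lost in typesetting. The factor is configurable.

**Desk scale.** The default configuration reconstructs on a 63³ grid
(rotation levels 4 → 5 → 6 over 60 iterations, β from 0.05 ×√2 every 5).
63 rather than the "64" a power-of-two habit suggests: the forward-scatter
voxel must sit exactly on a grid point for Friedel symmetrization and the
beamstop mask to be exact, so EMC grids are odd. The desk-scale study
conditions (40-atom phantom in a 4 nm sphere, 64×64-pixel detector, ~0.1
photons per pixel, 1500–2000 snapshots) reproduce the photon-sparse regime
of the full problem in minutes: the test suite requires registered
correlation ≥ 0.95 against the ideal volume, and the acceptance script
recomputes it end to end. The full-scale 951³/level-24/300-iteration
configuration is expressible (`full_scale_emc_config()`) and flagged
`cluster_scale`; nothing in the code ties the implementation to the desk
sizes.

The per-iteration mixture log-likelihood at β = 1 is recorded in the trace.
Exact EM monotonicity holds for iterated `emc_maximize()` (the pure mixture
EM on a fixed tomogram stack — this is what the test suite asserts);
the full loop's projection through compress/expand makes per-step
monotonicity only approximate near convergence, which is a known property
of EMC rather than a defect.

## Phase retrieval

The full-scale protocol trims the reconstruction to 552³ about the center,
mean-bins 2×2×2 to 276³, and masks a 5-voxel-radius central sphere (the
beamstop region, kept proportionally identical across datasets) whose
amplitudes float freely. `preprocess_volume()` implements this with all
sizes scalable; mean (not sum) binning keeps intensities per-voxel
comparable across binnings.

`hio_run()` is textbook HIO with a *fixed* spherical support (explicitly no
shrinkwrap during iteration, so every dataset sees the same constraint),
Fourier-magnitude projection on measured voxels only, and feedback
$x \leftarrow x - \beta_{fb} x'$ outside the constraint set. Choices the
protocol leaves open, and the package's defaults:

* $\beta_{fb} = 0.9$ (common practice; configurable).
* A short error-reduction (ER) finish — 50 iterations by default — is
  appended to every run: the HIO iterate oscillates by construction, and
  the ER tail settles it onto the nearest feasible point so that the
  reciprocal-error ranking and best-3 averaging act on stabilized
  solutions. Set `er_finish = 0` for strictly pure HIO.
* Nonnegativity inside the support is imposed by default — the object is an
  electron density — and can be switched off; the underlying protocol
  states only the support constraint.
* Support radius: 1.3× the particle radius (`default_support_radius()`),
  configurable.
* The ensemble runs `n_starts` random starts (300×3000 iterations at full
  scale, 20×500 at desk scale), ranks them by the reciprocal-space
  magnitude residual on measured voxels, and averages the best 3 after
  alignment.
* Alignment is center-of-mass to integer precision, then a sub-voxel
  optimization on a ten-times-finer shift grid. The "ten times bigger
  array" of the original description is realized as local Fourier (sinc)
  interpolation of the cross-correlation (a matrix-DFT evaluation around
  the CoM peak) rather than a literal 10× zero-padded volume, which would
  need ~4 GB per volume at 276³; the two are mathematically identical on
  band-limited data. The Friedel twin (point-reflected solution) is tried
  explicitly and resolved by correlation.
* Support tightening after averaging: Gaussian blur (σ = 2 voxels) and a
  threshold at 3% of the blurred maximum — chosen so ≥ 99.5% of phantom
  density stays inside the tight support; both configurable. Density
  outside is zeroed, and the total is normalized to the model's electron
  count, converting to electrons/voxel.

## The R factor and resolution

Reconstructions are compared with the noise-free ideal volume after
rotational registration (`register_rotation()`: a coarse search over a
quasi-uniform rotation grid evaluated on a low-q shell — where orientation
basins are widest — then Nelder–Mead refinement of the best candidates on a
wider shell). For each full-period resolution cutoff D,

$$R(D) = \sum_{|\mathbf{q}| \le 2\pi/D}
\left|\frac{I(\mathbf{q})}{\sum I} -
\frac{I_{\mathrm{ideal}}(\mathbf{q})}{\sum I_{\mathrm{ideal}}}\right| ,$$

with both sums over the same voxel set (beamstop and unmeasured voxels
excluded from both — the exclusion must be symmetric or identical volumes
would not give R = 0). R is scale-invariant, bounded by [0, 2], and summed
over full 3D voxel sets as written (not spherical-shell profiles). The
achievable resolution is the first upward crossing of R(D) = 0.2 coming
from low q, interpolated linearly in 1/D (proportional to the q cutoff,
which is how shells accumulate); curves that never reach the threshold are
flagged *detector-limited*, curves that never dip below it *unresolved*,
and multiple crossings are counted so that unstable high-q re-crossings
(the reason undersampled 5000-snapshot curves are dropped from full-scale
analyses) can be flagged rather than silently interpolated.

## Synthetic data: what it emulates and what it does not

`make_phantom()` places atoms with a minimum spacing of 1.2 Å (a
blue-noise-like rejection process) in a sphere, with a default element mix
of 60% C / 20% O / 15% N / 5% P approximating protein/RNA composition —
irrelevant to the algorithms, but it keeps the multi-element form-factor
paths honest. `make_dataset()` draws a fresh Haar orientation per snapshot,
adds Poisson then (optionally) detector noise, and stores ground truth; its
`target_occupancy` tunes the fluence so the mean expected photons per
unmasked pixel matches the photon-sparse regime (~0.1) regardless of
phantom size. The Poisson and detector-noise stages use independent seeded
streams, so the `poisson_only` and noisy variants of a dataset share the
same photon draws and differ only where a Gaussian excursion crossed a
photonization threshold.

`render_density()` prepares the "ideal image": the model rendered as
Gaussian blobs of `Z` electrons (default width 2 Å), the standard way a
deposited structure is converted to a reference electron density. The blur
matters: at desk-scale voxel sizes an unsmeared atomic density is
effectively a set of points, and hard q-truncation of point scatterers
rings far outside any compact support — magnitudes derived that way are
*inconsistent* with a support constraint and no phase-retrieval algorithm
can satisfy both. The B-factor-smeared density is support-compact, so
phasing fixtures built from it are exactly feasible.

The generators emulate: photon sparsity, uniform SO(3) orientations,
per-pixel Gaussian photon-peak noise with the measured separations, the
beamstop, and calibration histograms of ~18 000 samples. They do **not**
emulate: solvent/hydration scattering, Compton background, carrier-gas
parasitic scattering, sample heterogeneity, detector panel gaps, charge
sharing, or gain-switching artifacts. Desk-scale passes therefore
demonstrate the correctness of the algorithms in the noise regime they
model, not the full experimental background budget — the same scoping as
the study the package reproduces.

## Numerical choices and degenerate inputs

* Likelihoods are computed in log domain with a per-pattern max-shift;
  model values are floored at 10⁻¹⁰⁰ before the log. The E-step/M-step
  inner products run in cache-blocked single precision (photon counts are
  small integers; per-pattern log-likelihoods are ~10³, far above float
  resolution), accumulated into doubles.
* Voxels never touched by compress keep their previous value; metrics and
  registration operate inside the covered sphere.
* Empty rotations (no responsibility mass) keep their previous tomogram.
* `photonize` rounds half-integers with R's `round`; exact half-unit
  readouts have probability zero under the noise model.
* Registration of near-degenerate (constant) volumes, all-masked phasing
  inputs, empty pattern stacks, zero densities, and infeasible phantom
  specs all raise immediate errors rather than propagating NaNs.
* Desk-scale problem sizes used by the test suite and acceptance script:
  63³/43³/33³ EMC grids on 64²–24² detectors, 10³–2×10³ snapshots, 20×500
  HIO ensembles (plus the 50-iteration ER finish), and a reduced two-case
  noise comparison at 43³. These were chosen once, as the smallest sizes at
  which every qualitative property of the full-scale study (occupancy
  regime, oversampling, separation-driven ordering) is preserved.

## Known limitations

* EMC here is a faithful single-node reference implementation; it does not
  implement Dragonfly's sparse-mode file formats, GPU kernels, or
  multi-conformer classification.
* The R-factor registration assumes the two volumes share a grid; no
  magnification refinement is attempted.
* HDF5/CXI and MRC/CCP4 export are not provided in this environment;
  pattern sets and volumes serialize as RDS with full provenance, and all
  tabular outputs are CSV/JSON.
* At detector noise levels far beyond the calibrated settings (peak
  separation ≲ 2 σ_avg) the photonization model itself becomes the wrong
  abstraction (multi-photon confusion dominates), and conclusions should
  not be extrapolated there.
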