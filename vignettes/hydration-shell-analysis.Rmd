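---
title: "Hydration-shell resolved IR spectra and free-energy surfaces: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration-shell resolved IR spectra and free-energy surfaces: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrashell)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the tunable parameters with their
units and defaults, the numerical choices, and — importantly — what the
synthetic-data generator does and does not emulate, hence what a passing
test suite does and does not demonstrate about real ab initio
trajectories.

## 1. Molecular dipoles from Wannier centers

In a closed-shell system whose occupied orbitals have been localized into
Wannier centers, each center carries a formal charge of −2e and each
nucleus carries its *valence* charge (H +1, C +4, N +5, O +6: core
electrons are folded into the pseudized nucleus). The total dipole then
decomposes exactly into molecular terms,

$$\mathbf{M}(t) = \sum_i \boldsymbol{\mu}_i(t), \qquad
  \boldsymbol{\mu}_i = \sum_{n \in i} q_n \mathbf{r}_n
  - 2e \sum_{w \in i} \mathbf{r}_w,$$

and each molecular dipole is origin-independent because each molecule is
charge neutral. Three conventions make this well defined on a periodic
trajectory:

* **Center assignment.** Each Wannier center belongs to the molecule of
  its nearest atom under the minimum-image metric. Distance ties (within
  10⁻⁹ Å) break deterministically to the lower molecule index. The
  assignment is validated every frame: a molecule must receive exactly
  half its summed valence charge in centers (4 for water, 15 for the
  9-atom CH₄N₂O₂ solute); any mismatch aborts with the frame and molecule
  named, because a silent mis-assignment would corrupt dipoles in a way
  no downstream check could detect.
* **Making molecules whole.** Wrapped coordinates corrupt the dipole sum,
  so each molecule is reconstructed by minimum-image chaining from its
  first atom before summing; centers are placed at their minimum-image
  position relative to their assigned (made-whole) atom.
* **Units.** Positions in Å, dipoles in Debye (1 e·Å = 4.803204 D).

`dipole_distribution()` pools |μ| over molecules of one species and time,
and reports the maximum-likelihood normal fit (the sample mean and
standard deviation *are* the MLE for a normal law, so no iterative fitter
is involved). Constant series are flagged degenerate rather than fitted.

## 2. IR spectra from dipole time-correlation functions

The absorption coefficient is the Fourier transform of the total-dipole
TCF times a quantum-correction prefactor. The package computes spectra
from TCFs of *finite differences* of the dipole (central differences,
one-sided at the ends): the derivative route already carries the ω²
weighting, so no additional ω² factor is applied at the transform stage.

The estimator chain and its defaults:

* **TCF**: unbiased normalization, `C(τ) = (n−j)⁻¹ Σₜ a(t)·b(t+τ)`,
  averaged over all time origins via FFT; a list of series (independent
  trajectories) is ensemble averaged. The default maximum lag is half the
  series length. Cross-TCFs are symmetrized,
  `(⟨a(0)b(t)⟩ + ⟨b(0)a(t)⟩)/2`, which guarantees real spectra.
* **Window**: Hann on the lag axis by default. Records of ~20 ps at a
  nominal 1 cm⁻¹ resolution need leakage control; `window = "none"` is
  available for analytic checks (the Parseval identity is exact only
  without a window).
* **Resolution**: the symmetrized TCF is zero-padded to at least
  1/(Δν̃·c·dt) points, transformed, and linearly interpolated onto a
  uniform grid of spacing 1 cm⁻¹ (configurable; `resolution = NULL`
  keeps the native FFT grid).
* **Prefactor** F(ω): the harmonic quantum correction
  `x/(1−e^{−x})`, `x = βhcν̃`, is the default; `"classical"` and
  `"none"` (both unity) are options. Which correction a given study used
  is often unrecoverable from its text, so the choice is explicit and
  stamped into the spectrum metadata — spectra from different conventions
  are never silently comparable.
* **Smoothing**: convolution with a unit-area Gaussian, default width
  20 cm⁻¹ interpreted as the FWHM, with reflective end handling so the
  integrated intensity is preserved to 10⁻⁶ relative.
* **Intensity scale**: spectra are emitted in consistent arbitrary units
  and flagged as such; converting to a decadic molar-absorptivity scale
  requires a concentration and path volume the trajectory alone does not
  carry.

**Kramers–Kronig correction.** The raw FT spectrum is proportional to
n(ω)·α(ω). The imaginary refractive index k = α/(4πν̃) and the real index
are linked by the principal-value relation

$$n(\omega) - n_D = \frac{2}{\pi}\,\mathcal{P}\!\!\int_0^\infty
  \frac{\omega' k(\omega')}{\omega'^2 - \omega^2}\, d\omega',$$

anchored at the optical index of water, n_D = 1.3325. The PV integral is
evaluated by Maclaurin's alternate-point rule (even grid points are
integrated over odd samples and vice versa, which steps over the
singularity with second-order accuracy), and n and k are iterated to
self-consistency (3 fixed-point iterations; the map is a contraction for
physical band strengths). Zero absorption returns the spectrum unchanged.
A band that has not decayed at the grid edge sets a warning flag in the
metadata instead of silently truncating the transform. Against the
closed-form Lorentz-oscillator index the reconstruction agrees to better
than 0.1 % away from the pole (the test asserts 1 %).

**Band positions and red shifts.** The red shift of the OH stretch is
measured against the 3660 cm⁻¹ free-OH reference, and the hydrogen-bond
enthalpy follows the empirical correlation −ΔH = 1.3·√(Δν̃) (kJ/mol with
Δν̃ in cm⁻¹). The band position is the *maximum* of the smoothed band
(with three-point parabolic refinement), not its centroid: a single
scalar reference line implies a point estimate, and the maximum is the
convention that reproduces the printed shift/enthalpy pairs
(283/309/338 cm⁻¹ → ~1 and ~2 kJ/mol per bond). A centroid mode is
provided for sensitivity checks.

## 3. Spatial decompositions

Two complementary decompositions disentangle solvation-shell
contributions.

**Radially resolved spectra.** The molecular dipole density is a sum of
3-D Gaussians of width σ at the molecular centers of mass, carrying the
molecular dipoles as vector weights. Re-centering on the solute every
frame and cross-correlating the solute dipole with the density binned
into spherical shells (weighted 4πr²) gives a signed spectrum in
(ν̃, r): positive where the shell oscillates in phase with the solute,
negative where it opposes it.

Numerically the package does **not** histogram 3-D grid points into
shells: the spherical-shell average of a Gaussian centered at distance d
has the closed form

$$\bar\rho(r; d) = (2\pi\sigma^2)^{-3/2}
  e^{-(r^2+d^2)/2\sigma^2}\,\frac{\sinh(rd/\sigma^2)}{rd/\sigma^2},$$

which is the continuum limit of the grid binning, removes grid noise, and
integrates against 4πr² dr to exactly 1 — so the radial integral of the
decomposition recovers the directly computed solute–total cross spectrum
up to tail truncation (the sum-rule test runs the radial grid to
√3·L/2 + 4σ, where the minimum-image mass of a cubic cell ends). The 3-D
gridded field (`dipole_density()`) is still exported, with its own
integral invariant, for density maps. Defaults: σ = 1.0 Å (resolves
first-shell structure at the ~2.8 Å hydrogen-bond distance while keeping
the shell-average well conditioned), radial bin 0.1 Å. σ is not a
physical parameter and is stamped into the output metadata.

**Distance-dependent spectra.** A sphere of radius R_c is carved softly
around the solute: solvent dipoles enter with logistic weights
`P = 1/(1+exp((R_si − R_c)/D))` of the solute–solvent center-of-mass
distance, and the sum `μ_s + Σ P μ_i` is renormalized to a single
molecule by `N = (1+ΣP²)^{−1/2}`. Its autocorrelation spectrum
interpolates between the bare solute spectrum (R_c → 0) and the
(single-molecule normalized) total spectrum (R_c → L): both limits are
verified on synthetic boxes. Default D = 0.25 Å — sharp enough to define
shells, smooth enough that the carved dipole stays continuous from frame
to frame; the edge width is a convention, not an inference, and both it
and R_c are stamped into metadata.

`select_cutoff()` picks R_c* from a band-intensity-vs-cutoff modulation
curve as the inflection point: the maximum-magnitude slope of a natural
cubic-spline interpolant (whose derivative is second-order accurate,
unlike a monotone Hermite fit, which biases the extremum location),
required to sit between two plateaus — end slopes above 25 % of the peak
slope are diagnosed as "no plateau" and rejected rather than returning a
meaningless radius. `count_waters_within()` reports both the soft count
Σ P̄ (possibly fractional) and the hard count (distance < R_c), since
which of the two a given study reports is usually unstated.

## 4. Structural analyses

RDFs use minimum-image pair histograms normalized by shell volume and
partner density (default bin 0.02 Å, r_max = L/2, which is where the
minimum-image metric stops being a distance). The running coordination
integral n(r) counts average partners of an A atom within r; shared atoms
between selections are never paired with themselves. The coordination
number integrates g(r) to its first minimum after the first peak,
detected on a 3-bin moving-average smoothed curve to suppress bin noise
(the bound may also be given explicitly, and is always reported).

Dihedrals use the signed atan2 plane-normal convention on minimum-image
bond vectors, values in [−180°, 180°) (planar trans maps to −180°);
collinear frames yield NA and are counted, not interpolated. The
geometric hydrogen-bond criterion (donor–acceptor < 3.5 Å, angle > 140°)
is a configurable convention.

## 5. Well-tempered metadynamics

The bias is a sum of periodic Gaussians on the CV circle (images at
±360° suffice for widths ≪ 360°), deposited every τ_G with
history-attenuated heights `W = W₀ exp(−V(s′)/k_B T_bias)`. Defaults
follow the common AIMD dialect: W₀ = 0.001 Hartree = 2.6255 kJ/mol,
τ_G = 25 fs, T_bias = 1500 K, system T = 298.15 K. The hill *width* is a
CV-space quantity; a width printed in energy units in a methods section
is dimensionally unusable for an angular CV, so the width here is an
explicit configuration value, default 20°, a standard choice for
dihedral CVs — never silently derived from an energy.

Two reconstruction conventions are provided, because published ΔF values
rarely say which was used:

* `"plain"`: F(s) = −V_bias(s), the bias inversion as usually printed;
* `"well_tempered_scaled"` (default): F(s) = −(T+ΔT)/ΔT · V_bias(s),
  with ΔT the bias temperature. Under height attenuation by
  exp(−V/k_B ΔT) the bias converges to −ΔT/(T+ΔT)·F, so only the scaled
  convention is asymptotically unbiased; with T_bias = 1500 K the two
  differ by a factor 1.199, which matters at the 1.5 kJ/mol recovery
  tolerance the tests enforce.

Profiles are reported as the mean over the final third of the deposition
history (hill granularity averages out; the early transient is excluded)
and shifted to min F = 0. ΔF between basins is the difference of basin
minima with the sign convention "positive favors the second basin", the
barrier is the minimax saddle on the periodic circle minus the
origin-basin minimum, and K = exp(ΔF/RT). Engine note: the bias and its
force live on a 0.5° grid updated analytically per hill and interpolated
linearly in between, so the cost per MD step is independent of the hill
count.

## 6. The synthetic-data generator

The generator stands in for the electronic-structure engine; it is
first-class, tested code, not a fixture.

* **Boxes.** Rigid waters (OH 0.96 Å, HOH 104.5°; 3 atoms + 4 centers)
  and an optional 9-atom hydroxyurea-like solute (15 centers, 30 valence
  electrons), placed by rejection sampling — intermolecular O–O ≥ 2.4 Å
  *and* any interatomic pair ≥ 1.6 Å, with a deterministic 10⁴-retry cap.
  The second floor is load-bearing: random rigid orientations otherwise
  allow atoms of different molecules to approach closely enough that a
  bond-midpoint center lies nearer a foreign atom than its own, which
  the assignment correctly rejects. An `"ideal"` placement (uniform,
  overlaps allowed) provides the g(r) ≡ 1 baseline for RDF validation.
* **Dipoles by construction.** All four (or fifteen) centers of a
  molecule are shifted rigidly along the molecular dipole axis by
  δ(t) = (|μ₀| − target(t))/(2·n_centers) e·Å, so the dipole magnitude
  equals base + Σ Aⱼ cos(2πcν̃ⱼt + φ) *exactly*, with independent random
  phases per molecule and mode. Defaults: 1.85 D per water (the gas-phase
  water dipole; condensed-phase studies report ~2.6–3 D, but the tests
  only require a *known* target), 6.57 D for the solute. Mode wavenumbers
  are validated against the Nyquist limit 1/(2c·dt); dt defaults to 2 fs,
  the conventional dipole-saving stride.
* **Motion.** Centers of mass rattle sinusoidally (bounded, ~100 cm⁻¹,
  amplitude 0.08 Å·√(T/298.15)); orientations are static. Trajectories
  are therefore stationary by construction and need no burn-in
  diagnostics.
* **CV dynamics.** Toy potentials are sums of periodic Gaussians on
  [−180°, 180°); the sampler is Euler–Maruyama overdamped Langevin with
  stationary law ∝ exp(−U/RT). The friction defaults (0.1 kJ·mol⁻¹·fs·deg⁻²
  for free sampling, 0.5 under metadynamics bias) set the CV diffusivity
  D = RT/γ high enough that the circle is traversed many times within
  10⁵–10⁶ steps, because occupancy-ratio recovery is limited by the
  number of *independent* basin visits, not by raw step counts.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: no intermolecular forces or hydrogen
bonding (solvation structure beyond the placement exclusion is absent),
no orientational relaxation, no mode coupling or anharmonicity, no
polarization response of water to the solute, no conformational motion of
the solute. The suite validates the *estimators* — that spectra recover
known line positions, that decompositions obey their sum rules and
limits, that metadynamics recovers known landscapes — not the physics of
hydration.

## 7. Problem sizes and reproducibility

The shipped tests and the acceptance checks use: a 16-water + solute box
of 256 frames for decomposition properties; a 64-water, 20 ps
(10 240-frame, dt = 2 fs) box for spectral-peak recovery within the
20 cm⁻¹ smoothing width; 128-water single-frame ideal-gas boxes
(averaged over seeds) for the RDF baseline; 3×10⁵-step Langevin and
metadynamics runs (three seeds) for Boltzmann and ΔF recovery. These
sizes were chosen so each property is measured well inside its assertion
tolerance while the whole suite stays desk-scale.

All randomness flows from explicit integer seeds; `generate_water_box()`
is bit-for-bit reproducible from its spec, and `run_pipeline()` derives
per-stage substreams from one root seed so rerunning a config yields
byte-identical tables.

## 8. Known limitations

* Cubic, constant-volume cells only; no triclinic or NPT support.
* The radial decomposition's shell weights use the nearest image of each
  center-of-mass distance; periodic *image overlap* of the Gaussian tails
  between shells beyond L/2 is not double-counted but simply attributed
  to the nearest-image radius.
* The Kramers–Kronig correction assumes the absorption is fully contained
  in the grid; edge-truncated bands only set a warning flag.
* `read_xyz_trajectory()` requires constant atom count and ordering; it
  is a trajectory reader, not a general structure parser.
* Metadynamics is 1-D; multi-dimensional CVs, adaptive widths and
  reweighting estimators are out of scope.
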