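# hydrashell

Solvation-shell resolved infrared spectroscopy and free-energy analysis of
molecular-dynamics trajectories, in R.

## What it is for

Ab initio MD studies of hydrated solutes (e.g. a single N-hydroxyurea
molecule in ~100 waters) produce trajectories in which the electronic
structure is condensed into maximally localized Wannier function centers:
point charges of −2e stored alongside the atoms. From these, classical
per-molecule dipole moments follow by summing valence-charged nuclei and
centers, and the infrared spectrum follows from the total-dipole
time-correlation function (TCF),

    alpha(omega) = F(omega) * Int dt e^{-i omega t} <M(0) . M(t)>,
    M = sum_i mu_i,
    mu_i = sum_n q_n r_n - 2e sum_w r_w.

`hydrashell` implements the complete post-simulation pipeline around this
relation for solute–solvent systems:

* **Molecular dipoles** — nearest-atom Wannier-center assignment,
  minimum-image reconstruction of wrapped molecules, per-molecule dipole
  series and magnitude distributions with normal fits.
* **IR spectra** — finite-difference dipole derivatives, unbiased vector
  TCFs (ensemble averaged over trajectories), windowed FFT at 1 cm⁻¹
  resolution, harmonic quantum-correction prefactor, 20 cm⁻¹ Gaussian
  smoothing, and a numerical Kramers–Kronig refractive-index correction
  anchored at n_D = 1.3325.
* **Spatial decompositions** — radially resolved cross-spectra between
  the solute dipole and the Gaussian-smoothed molecular dipole density
  (signed, binned by distance from the solute), and distance-dependent
  spectra of a "carved sphere" dipole with logistic weights
  P = 1/(1+exp((R−Rc)/D)) and single-molecule normalization
  N = (1+ΣP²)^(−1/2); plus inflection-based cutoff selection and soft
  (possibly fractional) counts of spectrally affected waters.
* **Structure** — radial distribution functions with running coordination
  integrals, first-peak coordination numbers, signed dihedral time series,
  intramolecular distance distributions, a geometric H-bond criterion.
* **Well-tempered metadynamics** — periodic Gaussian bias on a dihedral
  CV, history-dependent hill heights W = W₀ exp(−V/kB·T_bias), free-energy
  reconstruction under both the plain inversion and the
  (T+ΔT)/ΔT-rescaled convention, basin ΔF, minimax barriers, equilibrium
  constants, and barriers in units of kBT.
* **Thermochemistry** — OH-stretch band positions, red shifts against the
  3660 cm⁻¹ free-OH reference, and hydrogen-bond enthalpies via the
  empirical correlation −ΔH = 1.3·√(Δν̃).
* **Synthetic data** — a generator of toy solvated boxes with
  pseudo-Wannier centers whose positions encode prescribed dipole
  magnitudes and vibrational modes, analytic harmonic dipole series, and
  an overdamped Langevin sampler on known periodic potentials, so every
  stage of the pipeline is testable end to end without an electronic-
  structure engine.

File formats: (extended) XYZ trajectories with Wannier centers inline
(pseudo-element `X`) or in a sidecar file, PLUMED-style HILLS text with
unit headers, and delimited spectrum/RDF/FES tables.

## Worked example

```r
library(hydrashell)

# a 16-water box around one solute, waters vibrating at 1650 and 3400 cm^-1
spec <- synthetic_box_spec(
  n_water = 16, n_solute = 1, n_steps = 512, seed = 1,
  vibrational_modes = data.frame(wavenumber = c(1650, 3400),
                                 amplitude  = c(0.05, 0.08)))
traj   <- generate_water_box(spec)
series <- dipole_series_from_trajectory(traj, attr(traj, "topology"))
series
#> <dipole_series> 17 molecules [solute:1 water:16], 512 samples, dt = 2 fs
#>   mean |M| = 10.8804 D

sp <- ir_spectrum_from_dipoles(series, smoothing = 20)
band_position(sp, c(3200, 3600))
#> [1] 3400.157

# distance-dependent spectrum inside the first shell
dd <- distance_dependent_spectrum(series, traj$cell_edge,
                                  R_c = 3.5, D_width = 0.25)
count_waters_within(series, traj$cell_edge, R_c = 3.5)
#> $soft
#> [1] 1.587933
#> $hard
#> [1] 1.777344

# free energy of a toy double well by well-tempered metadynamics
dw  <- toy_potential(c(-25, -15, 30), c(90, -90, 0), c(25, 25, 18))
run <- run_wtmtd(dw, wtmtd_config(), dt = 1, n_steps = 3e5, seed = 11)
fes <- reconstruct_fes(run$hills, wtmtd_config())
free_energy_difference(fes, c(10, 170), c(-170, -10))
#> [1] -9.792665  (attr s_a = 90, s_b = -91: the right basin lies lower)

# red-shift thermochemistry
enthalpy_increase(283, 338)
#> [1] 2.030824
```

The band position sits at the configured water stretch; the soft count is
the time-averaged ΣP of logistic weights (hence fractional); the toy
double well built with a 10 kJ/mol basin split is recovered to within the
hill granularity; and a 283 → 338 cm⁻¹ red-shift increase corresponds to
about 2 kJ/mol of extra hydrogen-bond enthalpy per bond.

The full pipeline — generate → dipoles → spectra → decompositions →
structure → metadynamics → thermochemistry report with provenance — runs
from a single config:

```r
res <- run_pipeline(run_config("out/", seed = 1))
```

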