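Package: hydrashell
Title: Solvation-Shell Resolved Infrared Spectra and Free-Energy Surfaces
    from Molecular-Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-simulation analysis of solvated-solute molecular-dynamics
    trajectories with Wannier-center electronic information. Computes
    per-molecule classical dipole moments from atomic positions and
    maximally localized Wannier function centers, infrared absorption
    spectra from dipole time-correlation functions (with finite-difference
    dipole derivatives, quantum-correction prefactors, Gaussian smoothing
    and a numerical Kramers-Kronig refractive-index correction), spatially
    decomposed spectra (radially resolved cross-spectra against a
    Gaussian-smoothed dipole density, and distance-dependent spectra of a
    logistic-carved sphere dipole), radial distribution functions with
    coordination numbers, dihedral time series, well-tempered metadynamics
    free-energy reconstruction on periodic collective variables, and
    red-shift based hydrogen-bond thermochemistry. A synthetic-data module
    generates toy solvated boxes with pseudo-Wannier centers, analytic
    dipole time series and Langevin samplers on known periodic potentials,
    so the whole pipeline is testable end to end without an ab initio
    engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
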