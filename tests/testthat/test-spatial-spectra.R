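# Spatial decompositions: dipole density field, radially resolved
# cross-spectra, carved-sphere dipoles and cutoff selection.

test_that("dipole density integrates to the total dipole, including at
           cell corners", {
  set.seed(1)
  mu <- matrix(rnorm(6), 2, 3)
  com <- matrix(runif(6, 0, 10), 2, 3)
  f <- dipole_density(mu, com, cell_edge = 10, spacing = 0.5, sigma = 1)
  expect_lt(max(abs(integrate_dipole_density(f) - colSums(mu))) /
              max(abs(colSums(mu))), 0.005)

  corner <- dipole_density(matrix(c(1, 0, 0), 1, 3),
                           matrix(c(0.01, 0.01, 9.99), 1, 3),
                           cell_edge = 10, spacing = 0.5, sigma = 1)
  expect_equal(integrate_dipole_density(corner), c(1, 0, 0),
               tolerance = 0.005)

  # two far-apart molecules: the field is two separate lobes
  mu2 <- rbind(c(1, 0, 0), c(0, 1, 0))
  com2 <- rbind(c(2.5, 5, 5), c(7.5, 5, 5))
  f2 <- dipole_density(mu2, com2, 10, spacing = 0.5, sigma = 0.6)
  fa <- dipole_density(mu2[1, , drop = FALSE], com2[1, , drop = FALSE],
                       10, spacing = 0.5, sigma = 0.6)
  fb <- dipole_density(mu2[2, , drop = FALSE], com2[2, , drop = FALSE],
                       10, spacing = 0.5, sigma = 0.6)
  expect_equal(f2$field, fa$field + fb$field, tolerance = 1e-12)

  expect_error(dipole_density(mu, com, 10, spacing = 1, sigma = 0.5),
               "sigma")
})

test_that("radial integral of the radially resolved spectrum equals the
           direct solute-total cross spectrum", {
  fx <- solvated_fixture()
  L <- fx$traj$cell_edge
  sigma <- 0.8
  r_max <- sqrt(3) / 2 * L + 4 * sigma   # capture all minimum-image mass
  rs <- radially_resolved_spectrum(fx$series, L, sigma = sigma,
                                   radial_bin = 0.05, r_max = r_max,
                                   resolution = 4, prefactor = "none",
                                   window = "none")
  direct <- solute_total_cross_spectrum(fx$series, resolution = 4,
                                        prefactor = "none",
                                        window = "none")
  ri <- integrate_radial_spectrum(rs)
  expect_lt(max(abs(ri$values - direct$values)) / max(abs(direct$values)),
            0.01)
})

test_that("with silent solvent the radial intensity is confined to the
           solute's own bins", {
  spec <- synthetic_box_spec(n_water = 8, n_solute = 1, n_steps = 128,
                             seed = 13, base_dipole = 0,
                             solute_modes = data.frame(wavenumber = 1600,
                                                       amplitude = 0.1),
                             com_amplitude = 0)
  tr <- generate_water_box(spec)
  ds <- dipole_series_from_trajectory(tr, attr(tr, "topology"))
  rs <- radially_resolved_spectrum(ds, tr$cell_edge, sigma = 0.5,
                                   radial_bin = 0.1, resolution = 8,
                                   prefactor = "none")
  near <- rs$radius < 2.5   # solute Gaussian lobe around r = 0
  power <- colSums(abs(rs$values))
  expect_gt(sum(power[near]), 0.999 * sum(power))
})

test_that("coherent solvent shells produce signed bands at the shell
           radius", {
  # solute at the box centre plus 6 octahedral waters at 3 A, all dipoles
  # oscillating at 1600 cm-1, in phase or antiphase with the solute
  n <- 512; dt <- 2
  t <- (0:(n - 1)) * dt
  osc <- cos(2 * pi * wavenumber_to_freq(1600) * t)
  build <- function(sign_shell) {
    nm <- 7
    mu <- array(0, dim = c(nm, 3, n))
    com <- array(0, dim = c(nm, 3, n))
    com[1, , ] <- 7.5
    shell <- rbind(c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0), c(0, -3, 0),
                   c(0, 0, 3), c(0, 0, -3))
    for (i in 1:6) com[i + 1, , ] <- 7.5 + shell[i, ]
    mu[1, 1, ] <- osc
    for (i in 1:6) mu[i + 1, 1, ] <- sign_shell * osc
    ds <- dipole_series(t, mu, c("solute", rep("water", 6)))
    attr(ds, "com") <- com
    ds
  }
  rs_pos <- radially_resolved_spectrum(build(+1), 15, sigma = 0.5,
                                       radial_bin = 0.1, resolution = 8,
                                       prefactor = "none")
  rs_neg <- radially_resolved_spectrum(build(-1), 15, sigma = 0.5,
                                       radial_bin = 0.1, resolution = 8,
                                       prefactor = "none")
  at_shell <- which(abs(rs_pos$radius - 3) < 0.3)
  at_band <- which(abs(rs_pos$wavenumber - 1600) ==
                     min(abs(rs_pos$wavenumber - 1600)))[1]
  expect_gt(sum(rs_pos$values[at_band, at_shell]), 0)
  expect_lt(sum(rs_neg$values[at_band, at_shell]), 0)
  # antiphase flips the sign without changing the magnitude (up to the
  # solute's own 1e-8-scale Gaussian tail at the shell radius)
  expect_equal(rs_neg$values[at_band, at_shell],
               -rs_pos$values[at_band, at_shell], tolerance = 1e-4)
})

test_that("carved-sphere weights follow the logistic form and its limits", {
  # hand-built series: solute + one water at controlled distance
  mk <- function(d_water, mu_w = c(1, 0, 0), n = 4) {
    mu <- array(0, dim = c(2, 3, n))
    com <- array(0, dim = c(2, 3, n))
    com[1, , ] <- 10
    com[2, 1, ] <- 10 + d_water; com[2, 2, ] <- 10; com[2, 3, ] <- 10
    mu[1, 1, ] <- 1
    for (ax in 1:3) mu[2, ax, ] <- mu_w[ax]
    ds <- dipole_series((0:(n - 1)) * 2, mu, c("solute", "water"))
    attr(ds, "com") <- com
    ds
  }
  # at exactly R_c the weight is 1/2
  cv <- carve_sphere_dipole(mk(3.5), 20, R_c = 3.5, D_width = 0.25)
  expect_equal(as.vector(attr(cv, "weights"))[1], 0.5, tolerance = 1e-12)

  # far beyond R_c + 10 D the carved dipole is the bare solute dipole
  far <- carve_sphere_dipole(mk(3.5 + 10 * 0.25 + 2), 20, R_c = 3.5,
                             D_width = 0.25)
  expect_equal(as.vector(far$mu[1, , 1]), c(1, 0, 0), tolerance = 1e-3)
  expect_equal(attr(far, "normalization")[1], 1, tolerance = 1e-3)

  # one water fully inside with mu_i = mu_s = mu gives sqrt(2) mu
  inside <- carve_sphere_dipole(mk(0.5), 20, R_c = 6, D_width = 0.05)
  expect_equal(as.vector(inside$mu[1, , 1]), sqrt(2) * c(1, 0, 0),
               tolerance = 1e-3)
})

test_that("distance-dependent spectra reduce to the bare solute at small
           R_c and to the normalized total spectrum at large R_c", {
  fx <- solvated_fixture()
  L <- fx$traj$cell_edge
  bare <- ir_spectrum_from_dipoles(subset_molecules(fx$series, "solute"),
                                   smoothing = 0, resolution = 4,
                                   prefactor = "none")
  small <- distance_dependent_spectrum(fx$series, L, R_c = 0.05,
                                       D_width = 0.02, smoothing = 0,
                                       resolution = 4, prefactor = "none")
  expect_lt(max(abs(small$values - bare$values)) / max(bare$values), 1e-6)

  total <- ir_spectrum_from_dipoles(fx$series, smoothing = 0,
                                    resolution = 4, prefactor = "none")
  big <- distance_dependent_spectrum(fx$series, L, R_c = L,
                                     D_width = 0.01, smoothing = 0,
                                     resolution = 4, prefactor = "none")
  # equal up to the single-molecule normalization N^2 = 1/(1 + n_water)
  expect_lt(max(abs(big$values / max(big$values) -
                      total$values / max(total$values))), 0.01)

  # solvent-free system: identical at every cutoff
  spec <- synthetic_box_spec(n_water = 0, n_solute = 1, n_steps = 64,
                             seed = 3, cell_edge = 12,
                             solute_modes = data.frame(wavenumber = 1600,
                                                       amplitude = 0.1))
  tr <- generate_water_box(spec)
  ds <- dipole_series_from_trajectory(tr, attr(tr, "topology"))
  s1 <- distance_dependent_spectrum(ds, 12, R_c = 2, smoothing = 0,
                                    resolution = 8, prefactor = "none")
  s2 <- distance_dependent_spectrum(ds, 12, R_c = 5, smoothing = 0,
                                    resolution = 8, prefactor = "none")
  expect_equal(s1$values, s2$values, tolerance = 1e-12)
})

test_that("the R_c family is continuous and smoother for wider logistic
           edges", {
  fx <- solvated_fixture()
  L <- fx$traj$cell_edge
  # worst adjacent-cutoff jump across a grid spanning the first shell:
  # sharp logistic edges jump when a water crosses, wide edges do not
  max_jump <- function(dw) {
    fam <- distance_dependent_spectrum(fx$series, L,
                                       R_c = seq(2.4, 4.4, by = 0.25),
                                       D_width = dw, smoothing = 0,
                                       resolution = 8, prefactor = "none")
    max(vapply(seq_len(length(fam) - 1), function(i)
      sqrt(sum((fam[[i]]$values - fam[[i + 1]]$values)^2)), 0))
  }
  expect_lt(max_jump(0.5), max_jump(0.1))
})

test_that("cutoff selection finds the inflection of sigmoidal modulation
           curves and rejects linear ones", {
  rc <- seq(1, 7, by = 0.25)
  up <- 5 / (1 + exp(-(rc - 3.7) / 0.4))
  expect_lt(abs(select_cutoff(rc, up) - 3.7), 0.05)

  down <- 5 / (1 + exp((rc - 3.7) / 0.4))   # mirrored about the centre
  expect_lt(abs(select_cutoff(rc, down) - 3.7), 0.05)

  expect_error(select_cutoff(seq(1, 8), seq(1, 8)), "non-sigmoidal")
  expect_error(select_cutoff(rc[1:5], up[1:5]), "at least 8")
})

test_that("soft water counts: zero when empty, k when k are inside,
           volume-law for an ideal gas", {
  fx <- solvated_fixture()
  L <- fx$traj$cell_edge
  none <- count_waters_within(fx$series, L, R_c = 0.3, D_width = 0.02)
  expect_lt(none$soft, 1e-6)
  expect_equal(none$hard, 0)

  # hand-built: 3 waters well inside, 2 outside
  mu <- array(1, dim = c(6, 3, 2))
  com <- array(0, dim = c(6, 3, 2))
  com[1, , ] <- 10
  d <- c(1, 1.5, 2, 8, 9)
  for (i in 1:5) { com[i + 1, 1, ] <- 10 + d[i]; com[i + 1, 2:3, ] <- 10 }
  ds <- dipole_series(c(0, 2), mu, c("solute", rep("water", 5)))
  attr(ds, "com") <- com
  k <- count_waters_within(ds, 24, R_c = 4, D_width = 0.1)
  expect_equal(k$soft, 3, tolerance = 1e-6)
  expect_equal(k$hard, 3)

  # ideal-gas solvent: soft count approaches (4/3) pi R^3 rho.
  # the ideal placement allows molecular overlap, so centers of mass are
  # taken geometrically rather than through the Wannier assignment
  counts <- vapply(1:4, function(sd) {
    spec <- synthetic_box_spec(n_water = 128, n_solute = 1, n_steps = 1,
                               seed = sd + 20, cell_edge = 14,
                               placement = "ideal", com_amplitude = 0)
    tr <- generate_water_box(spec)
    topo <- attr(tr, "topology")
    ds2 <- dipole_series(tr$times,
                         array(0, dim = c(n_molecules(topo), 3, 1)),
                         topo$species)
    attr(ds2, "com") <- molecular_com_series(tr, topo)
    count_waters_within(ds2, 14, R_c = 5, D_width = 0.02)$soft
  }, 0)
  rho <- 128 / 14^3
  expected <- 4 / 3 * pi * 5^3 * rho
  expect_lt(abs(mean(counts) - expected) / expected, 0.2)
})
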