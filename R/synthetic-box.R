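# Synthetic solvated boxes with pseudo-Wannier centers.
#
# The generator emulates what an ab initio trajectory hands the analysis
# pipeline: atoms plus Wannier centers whose positions encode per-molecule
# dipoles. Water is rigid (OH 0.96 A, HOH 104.5 deg); intramolecular
# flexibility is emulated purely by an oscillating shift of the centers
# along the molecular dipole axis, so the configured dipole magnitude
# base + sum_j A_j cos(2 pi c nu_j t + phi) holds exactly by construction.

#' Specification of a synthetic solvated box
#'
#' @param n_water number of water molecules
#' @param n_solute 0 or 1 hydroxyurea-like solute (9 atoms, 15 centers,
#'   30 valence electrons)
#' @param cell_edge cubic cell edge, Angstrom; default from
#'   [cell_edge_from_density()] at 997.05 kg/m^3 for `n_water + 3*n_solute`
#'   water-equivalents
#' @param temperature K (controls the size of the librational rattle)
#' @param dt dipole sampling stride, fs (default 2, the conventional saving
#'   stride of Wannier-center dipole analyses)
#' @param n_steps number of frames
#' @param seed integer RNG seed; trajectories are reproducible bit-for-bit
#'   from `(spec, seed)`
#' @param vibrational_modes data frame with columns `wavenumber` (cm^-1)
#'   and `amplitude` (D): harmonic dipole modes of each water
#' @param base_dipole mean water dipole magnitude, D
#' @param solute_modes like `vibrational_modes`, for the solute
#' @param solute_dipole mean solute dipole magnitude, D
#' @param placement `"rejection"` (2.4 A minimum intermolecular O-O
#'   distance and 1.6 A between any two atoms, deterministic retry cap 1e4
#'   per molecule) or `"ideal"` (ideal-gas uniform placement, for RDF
#'   baselines; overlapping molecules are possible by construction)
#' @param com_amplitude amplitude of the bounded center-of-mass rattle, A
#' @return object of class `synthetic_box_spec`
#' @export
synthetic_box_spec <- function(n_water, n_solute = 0, cell_edge = NULL,
                               temperature = 298.15, dt = 2, n_steps = 100,
                               seed = 1,
                               vibrational_modes = data.frame(
                                 wavenumber = numeric(0),
                                 amplitude = numeric(0)),
                               base_dipole = 1.85,
                               solute_modes = vibrational_modes,
                               solute_dipole = 6.57,
                               placement = c("rejection", "ideal"),
                               com_amplitude = 0.08) {
  placement <- match.arg(placement)
  if (is.null(cell_edge))
    cell_edge <- cell_edge_from_density(max(1, n_water + 3 * n_solute),
                                        997.05)
  stopifnot(n_water >= 0, n_solute %in% c(0, 1), n_water + n_solute >= 1,
            cell_edge > 0, dt > 0, n_steps >= 1, temperature > 0)
  nyq <- nyquist_wavenumber(dt)
  for (m in list(vibrational_modes, solute_modes)) {
    if (nrow(m) > 0 && any(m$wavenumber >= nyq))
      stop("vibrational mode at or above the Nyquist limit ",
           format(nyq, digits = 6), " cm^-1 for dt = ", dt, " fs")
  }
  structure(list(n_water = n_water, n_solute = n_solute,
                 cell_edge = cell_edge, temperature = temperature, dt = dt,
                 n_steps = n_steps, seed = as.integer(seed),
                 vibrational_modes = vibrational_modes,
                 base_dipole = base_dipole, solute_modes = solute_modes,
                 solute_dipole = solute_dipole, placement = placement,
                 com_amplitude = com_amplitude),
            class = "synthetic_box_spec")
}

# ---- reference geometries --------------------------------------------------

# rigid water in its molecular frame: O at origin, dipole axis +z
water_geometry <- function() {
  half <- 104.5 / 2 * pi / 180
  r_oh <- 0.96
  H1 <- r_oh * c(sin(half), 0, cos(half))
  H2 <- r_oh * c(-sin(half), 0, cos(half))
  atoms <- rbind(O = c(0, 0, 0), H = H1, H = H2)
  lp_ang <- 54.75 * pi / 180
  lp_d <- 0.35
  centers <- rbind(
    0.5 * H1,                                   # bond pair O-H1
    0.5 * H2,                                   # bond pair O-H2
    lp_d * c(0,  sin(lp_ang), -cos(lp_ang)),    # lone pair
    lp_d * c(0, -sin(lp_ang), -cos(lp_ang)))    # lone pair
  list(elements = c("O", "H", "H"), atoms = atoms, centers = centers)
}

# hydroxyurea-like solute H2N-C(=O)-NH-OH, planar heavy-atom skeleton:
# 9 atoms (C, 2 O, 2 N, 4 H), 30 valence electrons, 15 centers
solute_geometry <- function() {
  rot2 <- function(v, ang) {
    a <- ang * pi / 180
    c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2], 0)
  }
  C  <- c(0, 0, 0)
  O1 <- c(1.22, 0, 0)
  N1 <- 1.36 * c(cos(2 * pi / 3), sin(2 * pi / 3), 0)
  N2 <- 1.38 * c(cos(-2 * pi / 3), sin(-2 * pi / 3), 0)
  u1 <- N1 / sqrt(sum(N1^2))
  u2 <- N2 / sqrt(sum(N2^2))
  Ha <- N1 + 1.01 * rot2(u1,  60)
  Hb <- N1 + 1.01 * rot2(u1, -60)
  Hc <- N2 + 1.01 * rot2(u2,  60)
  O2 <- N2 + 1.40 * rot2(u2, -60)
  uo <- (O2 - N2) / sqrt(sum((O2 - N2)^2))
  Hd <- O2 + 0.97 * rot2(uo, -70)
  atoms <- rbind(C, O1, N1, N2, O2, Ha, Hb, Hc, Hd)
  elements <- c("C", "O", "N", "N", "O", "H", "H", "H", "H")
  mid <- function(a, b, f = 0.5) a + f * (b - a)
  co <- (O1 - C) / sqrt(sum((O1 - C)^2))
  centers <- rbind(
    mid(C, O1) + c(0, 0,  0.15),   # C=O banana pair
    mid(C, O1) + c(0, 0, -0.15),   # C=O banana pair
    mid(C, N1), mid(C, N2),
    mid(N1, Ha), mid(N1, Hb), mid(N2, Hc),
    mid(N2, O2), mid(O2, Hd),
    O1 + 0.30 * rot2(co,  45),     # carbonyl lone pairs
    O1 + 0.30 * rot2(co, -45),
    N1 + c(0, 0, 0.35),            # amine lone pair
    N2 + c(0, 0, 0.35),            # amide-N lone pair
    O2 + 0.30 * c(0, 0,  1) + 0.1 * uo,  # hydroxyl lone pairs
    O2 + 0.30 * c(0, 0, -1) + 0.1 * uo)
  list(elements = elements, atoms = atoms, centers = centers)
}

# canonical dipole (e*Angstrom) of a geometry in its molecular frame
geometry_dipole_eA <- function(geom, valence = default_valence_charges) {
  colSums(geom$atoms * valence[geom$elements]) - 2 * colSums(geom$centers)
}

# uniform random rotation matrix (Arvo's method via quaternion)
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a synthetic solvated box trajectory
#'
#' Places molecules (rejection sampling with a 2.4 A minimum O-O distance,
#' or ideal-gas uniform placement), gives each a random rigid orientation,
#' and evolves each frame by (i) a small bounded sinusoidal center-of-mass
#' rattle and (ii) an oscillating shift of the Wannier centers along the
#' molecular dipole axis that realizes the configured dipole magnitude
#' exactly. All coordinates are wrapped into `[0, L)`.
#'
#' @param spec a [synthetic_box_spec()]
#' @return an [md_trajectory]; its `"topology"` attribute holds the matching
#'   [md_topology]
#' @export
generate_water_box <- function(spec) {
  stopifnot(inherits(spec, "synthetic_box_spec"))
  set.seed(spec$seed)
  L <- spec$cell_edge
  wat <- water_geometry()
  sol <- solute_geometry()
  n_mol <- spec$n_water + spec$n_solute
  geoms <- c(if (spec$n_solute == 1) list(sol),
             rep(list(wat), spec$n_water))
  species <- c(if (spec$n_solute == 1) "solute", rep("water", spec$n_water))

  # rigid orientations first (the overlap test needs atom positions)
  rots <- replicate(n_mol, random_rotation(), simplify = FALSE)
  body_atoms <- lapply(seq_len(n_mol),
                       function(m) geoms[[m]]$atoms %*% t(rots[[m]]))

  # initial molecular positions: rejection sampling keeps intermolecular
  # O-O >= 2.4 A and any interatomic pair >= 1.6 A (so no Wannier center
  # can lie nearer to a foreign molecule than to its own)
  coms <- matrix(0, n_mol, 3)
  if (spec$placement == "ideal") {
    coms[] <- stats::runif(3 * n_mol, 0, L)
  } else {
    placed_at <- NULL
    placed_el <- character(0)
    for (m in seq_len(n_mol)) {
      el_m <- geoms[[m]]$elements
      ok <- FALSE
      for (try in seq_len(1e4)) {
        cand <- stats::runif(3, 0, L)
        at_m <- sweep(body_atoms[[m]], 2, cand, `+`)
        if (m == 1) { ok <- TRUE } else {
          d2 <- matrix(0, nrow(placed_at), nrow(at_m))
          for (ax in 1:3)
            d2 <- d2 + min_image(outer(placed_at[, ax], at_m[, ax], `-`),
                                 L)^2
          oo <- placed_el == "O"
          ok <- min(d2) >= 1.6^2 &&
            (!any(oo) || !any(el_m == "O") ||
               min(d2[oo, el_m == "O"]) >= 2.4^2)
        }
        if (ok) {
          coms[m, ] <- cand
          placed_at <- rbind(placed_at, at_m)
          placed_el <- c(placed_el, el_m)
          break
        }
      }
      if (!ok) stop("placement failure: could not place molecule ", m,
                    " after 10000 rejection attempts (box too dense?)")
    }
  }
  # per-molecule rattle: random direction, phase, ~100 cm^-1 libration
  rattle_dir <- t(vapply(seq_len(n_mol), function(m) {
    v <- stats::rnorm(3); v / sqrt(sum(v^2))
  }, numeric(3)))
  rattle_phase <- stats::runif(n_mol, 0, 2 * pi)
  rattle_amp <- spec$com_amplitude * sqrt(spec$temperature / 298.15)
  lib_freq <- wavenumber_to_freq(100)

  # per-molecule, per-mode phases for the dipole oscillation
  mode_tab <- function(sp) if (sp == "water") spec$vibrational_modes else
    spec$solute_modes
  base_of <- function(sp) if (sp == "water") spec$base_dipole else
    spec$solute_dipole
  phases <- lapply(species, function(sp)
    stats::runif(max(1, nrow(mode_tab(sp))), 0, 2 * pi))

  elements <- unlist(lapply(geoms, `[[`, "elements"))
  n_at <- length(elements)
  n_ct <- sum(vapply(geoms, function(g) nrow(g$centers), 0L))
  times <- (seq_len(spec$n_steps) - 1) * spec$dt
  atoms <- array(0, dim = c(n_at, 3, spec$n_steps))
  centers <- array(0, dim = c(n_ct, 3, spec$n_steps))

  # precompute rotated geometries and dipole axes
  rot_atoms <- vector("list", n_mol)
  rot_centers <- vector("list", n_mol)
  axes <- matrix(0, n_mol, 3)
  mu0_mag <- numeric(n_mol)
  for (m in seq_len(n_mol)) {
    R <- rots[[m]]
    rot_atoms[[m]] <- geoms[[m]]$atoms %*% t(R)
    rot_centers[[m]] <- geoms[[m]]$centers %*% t(R)
    mu0 <- as.vector(R %*% geometry_dipole_eA(geoms[[m]]))
    mu0_mag[m] <- sqrt(sum(mu0^2))
    axes[m, ] <- if (mu0_mag[m] > 1e-9) mu0 / mu0_mag[m] else c(0, 0, 1)
  }

  for (m in seq_len(n_mol)) {
    tab <- mode_tab(species[[m]])
    target_D <- rep(base_of(species[[m]]), spec$n_steps)
    if (nrow(tab) > 0) {
      for (j in seq_len(nrow(tab))) {
        target_D <- target_D + tab$amplitude[j] *
          cos(2 * pi * wavenumber_to_freq(tab$wavenumber[j]) * times +
                phases[[m]][j])
      }
    }
    target_eA <- target_D / hs_constants$debye_per_eA
    n_ctm <- nrow(rot_centers[[m]])
    delta <- (mu0_mag[m] - target_eA) / (2 * n_ctm)   # shift along +axis
    disp <- outer(sin(2 * pi * lib_freq * times + rattle_phase[m]),
                  rattle_amp * rattle_dir[m, ])       # [steps, 3]
    at0 <- rot_atoms[[m]]
    ct0 <- rot_centers[[m]]
    ai <- atom_offset(geoms, m) + seq_len(nrow(at0))
    ci <- center_offset(geoms, m) + seq_len(n_ctm)
    for (k in seq_len(spec$n_steps)) {
      shift <- coms[m, ] + disp[k, ]
      atoms[ai, , k] <- sweep(at0, 2, shift, `+`)
      centers[ci, , k] <- sweep(ct0, 2,
                                shift + delta[k] * axes[m, ], `+`)
    }
  }
  atoms <- atoms %% L
  centers <- centers %% L

  topo <- md_topology(
    molecule = rep(seq_len(n_mol),
                   vapply(geoms, function(g) length(g$elements), 0L)),
    species = unlist(species))
  traj <- md_trajectory(elements, atoms, centers, cell_edge = L,
                        dt = spec$dt, times = times, wrapped = TRUE)
  attr(traj, "topology") <- topo
  traj
}

atom_offset <- function(geoms, m) {
  if (m == 1) 0L else
    sum(vapply(geoms[seq_len(m - 1)], function(g) length(g$elements), 0L))
}
center_offset <- function(geoms, m) {
  if (m == 1) 0L else
    sum(vapply(geoms[seq_len(m - 1)], function(g) nrow(g$centers), 0L))
}

#' Topology of a synthetic box
#'
#' @param spec a [synthetic_box_spec()]
#' @return the [md_topology] matching [generate_water_box()] output
#' @export
box_topology <- function(spec) {
  n_mol <- spec$n_water + spec$n_solute
  n_sol_at <- length(solute_geometry()$elements)
  counts <- c(if (spec$n_solute == 1) n_sol_at, rep(3L, spec$n_water))
  md_topology(rep(seq_len(n_mol), counts),
              c(if (spec$n_solute == 1) "solute", rep("water", spec$n_water)))
}

#' Analytic single-mode dipole series
#'
#' `mu(t) = A cos(2 pi c nu t + phase)` along a fixed axis: the oracle input
#' for the spectral machinery. Rejects aliased wavenumbers.
#'
#' @param wavenumber cm^-1, below the Nyquist limit for `dt`
#' @param amplitude D
#' @param dt fs
#' @param n_steps samples
#' @param phase radians
#' @param axis unit 3-vector (default x)
#' @return a single-molecule `dipole_series`
#' @export
generate_harmonic_dipole <- function(wavenumber, amplitude, dt, n_steps,
                                     phase = 0, axis = c(1, 0, 0)) {
  if (wavenumber >= nyquist_wavenumber(dt))
    stop("wavenumber ", wavenumber, " cm^-1 is at or above the Nyquist limit ",
         format(nyquist_wavenumber(dt), digits = 6), " cm^-1 for dt = ", dt)
  stopifnot(wavenumber >= 0, n_steps >= 1)
  axis <- axis / sqrt(sum(axis^2))
  times <- (seq_len(n_steps) - 1) * dt
  s <- amplitude * cos(2 * pi * wavenumber_to_freq(wavenumber) * times +
                         phase)
  mu <- array(0, dim = c(1, 3, n_steps))
  for (ax in 1:3) mu[1, ax, ] <- s * axis[ax]
  dipole_series(times, mu, tags = "other")
}

#' Molality of a single-solute box
#'
#' `n_solute / (n_water * M_water)` with `M_water` = 18.015 g/mol.
#'
#' @param n_solute solute count
#' @param n_water water count (> 0)
#' @return molality, mol/kg
#' @export
molality_of_box <- function(n_solute, n_water) {
  stopifnot(n_water > 0)
  n_solute / (n_water * hs_constants$M_water * 1e-3)
}

#' Cubic cell edge from water count and mass density
#'
#' @param n_water number of water molecules
#' @param density kg/m^3 (997.05 for water at 298.15 K)
#' @return cell edge, Angstrom
#' @export
cell_edge_from_density <- function(n_water, density) {
  stopifnot(density > 0, n_water > 0)
  mass_kg <- n_water * hs_constants$M_water * 1e-3 / hs_constants$avogadro
  (mass_kg / density)^(1 / 3) * 1e10
}
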