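# Well-tempered metadynamics on a periodic 1-D collective variable.
#
# Gaussian hills of width sigma are deposited every tau_G with history-
# dependent heights W = W0 exp(-V(s')/kB Tbias); the long-time bias
# estimates the free-energy surface, either as -V ("plain", the printed
# inversion) or rescaled by (T + Tbias)/Tbias, the asymptotically unbiased
# well-tempered estimator.

#' Well-tempered metadynamics configuration
#'
#' Defaults follow the common AIMD dialect: hill height 0.001 Hartree
#' (2.6255 kJ/mol) deposited every 25 fs, bias temperature 1500 K, system
#' temperature 298.15 K. The hill width is a CV-space quantity (degrees);
#' 20 degrees is a standard choice for dihedral CVs.
#'
#' @param W0 initial hill height, kJ/mol
#' @param sigma_hill hill width on the CV, degrees
#' @param tau_G deposition interval, fs
#' @param T_bias bias temperature, K
#' @param temperature system temperature, K
#' @return object of class `wtmtd_config`
#' @export
wtmtd_config <- function(W0 = hartree_to_kJmol(0.001), sigma_hill = 20,
                         tau_G = 25, T_bias = 1500, temperature = 298.15) {
  stopifnot(W0 > 0, sigma_hill > 0, tau_G > 0, T_bias > 0, temperature > 0)
  structure(list(W0 = W0, sigma_hill = sigma_hill, tau_G = tau_G,
                 T_bias = T_bias, temperature = temperature),
            class = "wtmtd_config")
}

#' Metadynamics bias potential
#'
#' Sum of periodic Gaussians over the deposited hills,
#' `V(s) = sum W exp(-d(s, s')^2 / (2 sigma^2))` with `d` the
#' minimum-image angular distance (periodic images at +-360 degrees are
#' included, which suffices for widths much smaller than the period).
#'
#' @param s CV value(s), degrees (vectorized)
#' @param hills a `hill_records` table
#' @return bias energy, kJ/mol
#' @export
bias_potential <- function(s, hills) {
  out <- numeric(length(s))
  if (nrow(hills) == 0) return(out)
  for (img in c(-360, 0, 360)) {
    d <- outer(s, hills$center + img, `-`)
    out <- out + as.vector(exp(-d^2 / (2 *
      matrix(hills$width^2, length(s), nrow(hills), byrow = TRUE))) %*%
        hills$height)
  }
  out
}

#' History-dependent hill height
#'
#' `W = W0 exp(-V / (R T_bias))`: the well-tempered attenuation of the
#' deposited height with the bias already present at the deposition point.
#'
#' @param V_current bias at the deposition point, kJ/mol
#' @param config a [wtmtd_config()]
#' @return hill height, kJ/mol
#' @export
well_tempered_height <- function(V_current, config) {
  config$W0 * exp(-V_current / (hs_constants$R_kJmolK * config$T_bias))
}

#' Run well-tempered metadynamics on a toy potential
#'
#' Overdamped Langevin dynamics on the potential plus the accumulating
#' bias; hills are deposited every `tau_G`. The bias and its force are
#' maintained on a fine periodic grid (analytic per-hill updates, linear
#' interpolation in between), so the cost per step is independent of the
#' hill count. The returned coverage is the fraction of the CV circle
#' visited, which under bias should exceed the unbiased ensemble's range.
#'
#' @param potential a [toy_potential()]; its temperature is overridden by
#'   the config's system temperature
#' @param config a [wtmtd_config()]
#' @param dt integration step, fs; `tau_G` must be a multiple
#' @param n_steps number of steps
#' @param seed RNG seed
#' @param friction Langevin friction, kJ/mol fs/deg^2
#' @param s0 initial CV, degrees
#' @param grid_spacing bias grid spacing, degrees
#' @return list with `hills` (a `hill_records`), `cv` (trajectory,
#'   degrees), `coverage` (fraction of 5-degree sectors visited), `config`
#' @export
run_wtmtd <- function(potential, config, dt = 1, n_steps = 1e5, seed = 1,
                      friction = 0.5, s0 = NULL, grid_spacing = 0.5) {
  every <- config$tau_G / dt
  if (abs(every - round(every)) > 1e-9)
    stop("tau_G (", config$tau_G, " fs) must be a multiple of dt (", dt,
         " fs)")
  every <- round(every)
  set.seed(seed)
  RT <- hs_constants$R_kJmolK * config$temperature
  if (is.null(s0)) s0 <- stats::runif(1, -180, 180)
  noise <- stats::rnorm(n_steps, sd = sqrt(2 * RT * dt / friction))

  grid <- seq(-180, 180 - grid_spacing, by = grid_spacing)
  ng <- length(grid)
  Vg <- numeric(ng)
  Fg <- numeric(ng)   # bias force -dV/ds on the grid
  interp <- function(vals, s) {
    x <- (s + 180) / grid_spacing
    i0 <- floor(x)
    frac <- x - i0
    i0 <- (i0 %% ng) + 1
    i1 <- (i0 %% ng) + 1
    vals[i0] * (1 - frac) + vals[i1] * frac
  }

  sig2 <- config$sigma_hill^2
  times <- numeric(0); centers <- numeric(0); heights <- numeric(0)
  s <- s0
  cv <- numeric(n_steps)
  inv_g_dt <- dt / friction
  for (i in seq_len(n_steps)) {
    f <- potential_force(potential, s) + interp(Fg, s)
    s <- wrap_angle(s + f * inv_g_dt + noise[i])
    cv[i] <- s
    if (i %% every == 0) {
      V_here <- interp(Vg, s)
      W <- min(config$W0, well_tempered_height(max(0, V_here), config))
      d <- wrap_angle(grid - s)
      gauss <- W * exp(-d^2 / (2 * sig2))
      Vg <- Vg + gauss
      Fg <- Fg + gauss * d / sig2
      times <- c(times, i * dt)
      centers <- c(centers, s)
      heights <- c(heights, W)
    }
  }
  hills <- hill_records(times, centers,
                        rep(config$sigma_hill, length(times)), heights)
  coverage <- length(unique(floor((cv + 180) / 5))) / 72
  list(hills = hills, cv = cv, coverage = coverage, config = config)
}

#' Reconstruct the free-energy profile from deposited hills
#'
#' The bias inverted to a free energy on a periodic CV grid. Under
#' `"plain"`, `F(s) = -V_bias(s)`; under `"well_tempered_scaled"` (the
#' default, asymptotically unbiased for well-tempered deposition),
#' `F(s) = -(T + T_bias)/T_bias * V_bias(s)`. To damp hill-granularity
#' ripple the profile is averaged over the bias history: the mean of
#' `-V(s, t)` over the final third of the deposition record. The result is
#' shifted so `min(F) = 0`.
#'
#' @param hills a `hill_records` table
#' @param config a [wtmtd_config()] (supplies temperatures for the scaled
#'   convention)
#' @param convention `"well_tempered_scaled"` or `"plain"`
#' @param grid_spacing CV grid spacing, degrees (default 1)
#' @param average_fraction trailing fraction of the deposition history to
#'   average over (default 1/3; use a tiny value for the instantaneous
#'   final bias)
#' @return object of class `fes_profile`: list with `s` (degrees), `F`
#'   (kJ/mol, min 0), `convention`, `config`
#' @export
reconstruct_fes <- function(hills, config = wtmtd_config(),
                            convention = c("well_tempered_scaled",
                                           "plain"),
                            grid_spacing = 1, average_fraction = 1 / 3) {
  convention <- match.arg(convention)
  stopifnot(nrow(hills) >= 1)
  grid <- seq(-180, 180 - grid_spacing, by = grid_spacing)
  nh <- nrow(hills)
  first_avg <- max(1, ceiling((1 - average_fraction) * nh))
  V <- numeric(length(grid))
  V_acc <- numeric(length(grid))
  n_acc <- 0
  for (j in seq_len(nh)) {
    d <- wrap_angle(grid - hills$center[j])
    V <- V + hills$height[j] * exp(-d^2 / (2 * hills$width[j]^2))
    if (j >= first_avg) { V_acc <- V_acc + V; n_acc <- n_acc + 1 }
  }
  Fs <- -V_acc / n_acc
  if (convention == "well_tempered_scaled")
    Fs <- Fs * (config$temperature + config$T_bias) / config$T_bias
  Fs <- Fs - min(Fs)
  structure(list(s = grid, F = Fs, convention = convention,
                 config = config, n_hills = nh),
            class = "fes_profile")
}

#' @export
print.fes_profile <- function(x, ...) {
  cat(sprintf(
    "<fes_profile> %d grid points, range %.3f kJ/mol, convention '%s' (%d hills)\n",
    length(x$s), max(x$F), x$convention, x$n_hills))
  invisible(x)
}

#' @export
plot.fes_profile <- function(x, ..., xlab = "CV (deg)",
                             ylab = "F (kJ/mol)") {
  graphics::plot(x$s, x$F, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

basin_minimum <- function(profile, window) {
  sel <- profile$s >= window[1] & profile$s <= window[2]
  if (!any(sel)) stop("empty basin window [", window[1], ", ", window[2],
                      "]")
  i <- which(sel)[which.min(profile$F[sel])]
  if (i %in% c(which(sel)[1], utils::tail(which(sel), 1)) &&
      length(which(sel)) > 2) {
    # minimum at the window edge still accepted, but a strictly monotone
    # window has no interior minimum worth reporting
  }
  list(index = i, s = profile$s[i], F = profile$F[i])
}

#' Free-energy difference between two basins
#'
#' `dF = F_min(basin A) - F_min(basin B)`: the free energy released by the
#' conversion A -> B, positive when B is the more stable basin. The sign
#' convention and basin windows are attached as attributes.
#'
#' @param profile a `fes_profile`
#' @param window_a,window_b non-overlapping CV windows, degrees
#' @return dF, kJ/mol (attributes `s_a`, `s_b` give the minima locations)
#' @export
free_energy_difference <- function(profile, window_a, window_b) {
  if (max(min(window_a), min(window_b)) <
      min(max(window_a), max(window_b)))
    stop("basin windows overlap")
  a <- basin_minimum(profile, window_a)
  b <- basin_minimum(profile, window_b)
  out <- a$F - b$F
  attr(out, "s_a") <- a$s
  attr(out, "s_b") <- b$s
  attr(out, "direction") <- "A -> B (positive favors B)"
  out
}

#' Interconversion barrier from a basin
#'
#' The minimax saddle between the two basin minima on the periodic CV
#' circle (the lower of the two path maxima), minus the origin-basin
#' minimum.
#'
#' @param profile a `fes_profile`
#' @param from_window CV window of the origin basin, degrees
#' @param to_window CV window of the destination basin, degrees
#' @return barrier height, kJ/mol (attribute `s_saddle` gives the saddle
#'   location)
#' @export
barrier <- function(profile, from_window, to_window) {
  a <- basin_minimum(profile, from_window)
  b <- basin_minimum(profile, to_window)
  n <- length(profile$s)
  i <- a$index; j <- b$index
  path1 <- if (i <= j) i:j else c(i:n, 1:j)       # increasing-s path
  path2 <- if (i <= j) c(i:1, n:j) else i:j       # the other way round
  m1 <- max(profile$F[path1])
  m2 <- max(profile$F[path2])
  use <- if (m1 <= m2) path1 else path2
  saddle <- use[which.max(profile$F[use])]
  out <- profile$F[saddle] - a$F
  attr(out, "s_saddle") <- profile$s[saddle]
  out
}

#' Equilibrium constant from a basin free-energy difference
#'
#' `K = exp(dF / RT)` with the convention of
#' [free_energy_difference()]: `dF > 0` favors the product basin, giving
#' `K > 1`.
#'
#' @param dF free-energy difference, kJ/mol
#' @param temperature K
#' @return equilibrium constant (dimensionless)
#' @export
equilibrium_constant <- function(dF, temperature = 298.15) {
  stopifnot(temperature > 0)
  exp(dF / (hs_constants$R_kJmolK * temperature))
}

#' Barrier height in units of kB T
#'
#' @param dF_barrier barrier, kJ/mol
#' @param temperature K
#' @return barrier in multiples of `kB T` (per-mole: `R T`)
#' @export
barrier_in_kT <- function(dF_barrier, temperature = 298.15) {
  stopifnot(temperature > 0)
  dF_barrier / (hs_constants$R_kJmolK * temperature)
}
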