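# Toy periodic potentials and an overdamped Langevin sampler on the CV.
#
# These provide known free-energy landscapes against which the
# metadynamics reconstruction is validated: the sampler's stationary law is
# Boltzmann, so basin occupancies and recovered profiles have analytic
# references.

#' Define a toy periodic potential on a dihedral-like CV
#'
#' A sum of periodic Gaussian barriers/wells on `s` in `[-180, 180)`
#' degrees: `U(s) = sum_k h_k exp(-d(s, s_k)^2 / (2 w_k^2))` with `d` the
#' periodic (minimum-image) angular distance. Negative heights make wells.
#' Periodic continuity at the boundary is automatic.
#'
#' @param heights kJ/mol (negative = well)
#' @param locations degrees in `[-180, 180)`
#' @param widths degrees (> 0)
#' @param temperature K, the temperature the sampler targets
#' @return object of class `toy_potential`
#' @export
toy_potential <- function(heights, locations, widths,
                          temperature = 298.15) {
  stopifnot(length(heights) == length(locations),
            length(widths) %in% c(1, length(heights)),
            all(widths > 0), temperature > 0)
  widths <- rep_len(widths, length(heights))
  structure(list(heights = heights, locations = wrap_angle(locations),
                 widths = widths, temperature = temperature),
            class = "toy_potential")
}

#' Evaluate a toy potential
#' @param potential a [toy_potential()]
#' @param s CV values, degrees (vectorized)
#' @return energy, kJ/mol
#' @export
potential_energy <- function(potential, s) {
  out <- numeric(length(s))
  for (k in seq_along(potential$heights)) {
    d <- wrap_angle(s - potential$locations[k])
    out <- out + potential$heights[k] *
      exp(-d^2 / (2 * potential$widths[k]^2))
  }
  out
}

#' Force (-dU/ds) of a toy potential
#' @inheritParams potential_energy
#' @return force, kJ/mol/deg
#' @export
potential_force <- function(potential, s) {
  out <- numeric(length(s))
  for (k in seq_along(potential$heights)) {
    d <- wrap_angle(s - potential$locations[k])
    w2 <- potential$widths[k]^2
    out <- out + potential$heights[k] * d / w2 * exp(-d^2 / (2 * w2))
  }
  out
}

#' Overdamped Langevin sampling on a periodic toy potential
#'
#' Euler-Maruyama integration of
#' `ds = F(s)/gamma dt + sqrt(2 R T / gamma) dW`, wrapped into
#' `[-180, 180)`. The stationary distribution is Boltzmann,
#' `p(s) ~ exp(-U(s)/RT)`, which the property suite checks via basin
#' occupancy ratios.
#'
#' @param potential a [toy_potential()]
#' @param dt time step, fs
#' @param n_steps number of steps
#' @param seed RNG seed
#' @param friction gamma, kJ/mol fs/deg^2 (sets the CV diffusivity
#'   `D = RT/gamma`; the default 0.1 gives ~25 deg^2/fs at 298 K, so the
#'   sampler traverses the CV circle many times within 1e5 steps)
#' @param s0 initial CV, degrees (default: a random point)
#' @param bias_force optional function `f(s)` returning an extra force in
#'   kJ/mol/deg (used by the metadynamics driver)
#' @param callback optional function `cb(step, s)` invoked after every step
#' @return numeric vector of CV values, degrees, length `n_steps`
#' @export
langevin_on_potential <- function(potential, dt = 1, n_steps = 1000,
                                  seed = 1, friction = 0.1, s0 = NULL,
                                  bias_force = NULL, callback = NULL) {
  stopifnot(dt > 0, n_steps >= 1, friction > 0)
  set.seed(seed)
  RT <- hs_constants$R_kJmolK * potential$temperature
  if (is.null(s0)) s0 <- stats::runif(1, -180, 180)
  noise <- stats::rnorm(n_steps, sd = sqrt(2 * RT * dt / friction))
  out <- numeric(n_steps)
  s <- s0
  inv_g_dt <- dt / friction
  for (i in seq_len(n_steps)) {
    f <- potential_force(potential, s)
    if (!is.null(bias_force)) f <- f + bias_force(s)
    s <- wrap_angle(s + f * inv_g_dt + noise[i])
    out[i] <- s
    if (!is.null(callback)) callback(i, s)
  }
  out
}
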