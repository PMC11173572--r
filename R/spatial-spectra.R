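# Spatial decompositions of the IR spectrum around a solute:
#
#  * radially resolved spectra: cross-correlation of the solute dipole with
#    the Gaussian-smoothed molecular dipole density, binned by distance
#    from the solute center of mass and weighted 4 pi r^2;
#  * distance-dependent spectra: autocorrelation of a "carved sphere"
#    dipole in which solvent dipoles enter with logistic weights
#    P = 1/(1 + exp((R_si - Rc)/D)) and the sum is renormalized to a
#    single molecule by N = (1 + sum P^2)^(-1/2).

#' Gaussian-smoothed molecular dipole density on a 3D grid
#'
#' `rho_mu(r) = sum_i mu_i (2 pi sigma^2)^(-3/2) exp(-|R_i - r|^2 /
#' (2 sigma^2))` with periodic images included up to 4 sigma. The integral
#' of the field over the cell reproduces the total dipole (to within the
#' grid tolerance), which is the normalization invariant of the
#' decomposition.
#'
#' @param dipoles matrix `[n_molecules, 3]` of dipole vectors, D
#' @param coms matrix `[n_molecules, 3]` of molecular centers of mass, A
#' @param cell_edge cubic cell edge, A
#' @param spacing grid spacing, A
#' @param sigma Gaussian width, A (must be >= spacing)
#' @return object of class `dipole_density_field`: list with `axis` (grid
#'   coordinates), `field` (array `[nx, ny, nz, 3]`, D/A^3), `spacing`,
#'   `sigma`, `cell_edge`
#' @export
dipole_density <- function(dipoles, coms, cell_edge, spacing = 0.5,
                           sigma = 1.0) {
  dipoles <- rbind(dipoles)
  coms <- rbind(coms)
  stopifnot(nrow(dipoles) == nrow(coms), sigma > 0, spacing > 0)
  if (sigma < spacing)
    stop("sigma (", sigma, " A) must be at least the grid spacing (",
         spacing, " A)")
  ng <- max(2, round(cell_edge / spacing))
  h <- cell_edge / ng
  axis <- (0:(ng - 1)) * h
  norm <- (2 * pi * sigma^2)^(-3 / 2)
  field <- array(0, dim = c(ng, ng, ng, 3))
  n_img <- ceiling(4 * sigma / cell_edge)
  imgs <- (-n_img:n_img) * cell_edge
  for (i in seq_len(nrow(dipoles))) {
    w <- lapply(1:3, function(ax) {
      d <- outer(axis - coms[i, ax], imgs, `+`)
      rowSums(exp(-d^2 / (2 * sigma^2)))
    })
    g3 <- outer(outer(w[[1]], w[[2]]), w[[3]]) * norm
    for (ax in 1:3) field[, , , ax] <- field[, , , ax] + g3 * dipoles[i, ax]
  }
  structure(list(axis = axis, field = field, spacing = h, sigma = sigma,
                 cell_edge = cell_edge),
            class = "dipole_density_field")
}

#' Integrate a dipole density field over the cell
#' @param density a `dipole_density_field`
#' @return total dipole vector, D
#' @export
integrate_dipole_density <- function(density) {
  vapply(1:3, function(ax) sum(density$field[, , , ax]), 0) *
    density$spacing^3
}

# spherical-shell average of the 3D Gaussian kernel: the exact continuum
# limit of binning the Eq.-2 field into shells of radius r around the
# origin for a molecule at distance d; integrates to 1 against 4 pi r^2 dr
shell_gaussian_weight <- function(r, d, sigma) {
  pref <- (2 * pi * sigma^2)^(-3 / 2)
  x <- r * d / sigma^2
  base <- exp(-(r^2 + d^2) / (2 * sigma^2))
  small <- x < 1e-8
  out <- numeric(length(x))
  out[small] <- base[small]
  out[!small] <- base[!small] * sinh(pmin(x[!small], 700)) / x[!small]
  # guard the sinh overflow region (x > 700 implies base underflows first)
  pref * out
}

# minimum-image distances from the solute COM to every molecule, per frame
solute_com_distances <- function(series, cell_edge) {
  com <- attr(series, "com")
  if (is.null(com))
    stop("dipole series carries no centers of mass; build it with ",
         "dipole_series_from_trajectory()")
  s <- which(series$tags == "solute")
  if (length(s) != 1) stop("need exactly one solute molecule, found ",
                           length(s))
  nf <- dim(com)[3]
  nm <- dim(com)[1]
  d <- matrix(0, nm, nf)
  for (ax in 1:3) {
    dd <- min_image(com[, ax, ] -
                      matrix(com[s, ax, ], nm, nf, byrow = TRUE), cell_edge)
    d <- d + dd^2
  }
  sqrt(d)
}

#' Radially resolved IR spectrum around a solute
#'
#' Cross-correlates the solute dipole with the radially binned,
#' Gaussian-smoothed dipole density of all molecules (solute included),
#' re-centered on the solute center of mass every frame, and Fourier
#' transforms per radial bin with the `4 pi r^2` shell factor. Both inputs
#' enter through their finite-difference time derivatives and the cross-TCF
#' is symmetrized, so the output is real but signed: negative bands mean
#' anticorrelated solvent response.
#'
#' @param series a `dipole_series` from [dipole_series_from_trajectory()]
#'   (must contain one `"solute"` molecule and carry centers of mass)
#' @param cell_edge cubic cell edge, A
#' @param sigma Gaussian smoothing width of the density, A (default 1.0)
#' @param radial_bin radial bin width, A (default 0.1)
#' @param r_max outer radius (default `cell_edge / 2`)
#' @param smoothing spectral Gaussian filter FWHM, cm^-1 (0 disables)
#' @param ... passed to [spectrum_from_tcf()]
#' @return a `radial_spectrum`
#' @export
radially_resolved_spectrum <- function(series, cell_edge, sigma = 1.0,
                                       radial_bin = 0.1, r_max = NULL,
                                       smoothing = 0, ...) {
  if (is.null(r_max)) r_max <- cell_edge / 2
  dists <- solute_com_distances(series, cell_edge)
  s <- which(series$tags == "solute")
  r_grid <- seq(radial_bin / 2, r_max, by = radial_bin)
  nf <- length(series$times)
  nm <- dim(series$mu)[1]

  deriv <- dipole_derivative(series)
  mus_dot <- t(deriv$mu[s, , ])                      # [nf, 3]
  # rho_dot(t, r): radially binned density of dipole derivatives
  rho_dot <- array(0, dim = c(nf, 3, length(r_grid)))
  for (k in seq_len(nf)) {
    W <- outer(r_grid, dists[, k],
               function(r, d) shell_gaussian_weight(r, d, sigma))
    mu_k <- deriv$mu[, , k]                          # [nm, 3]
    if (nm == 1) mu_k <- rbind(mu_k)
    rho_dot[k, , ] <- t(W %*% mu_k)
  }

  tcf0 <- autocorrelation(dipole_series(series$times,
                                        array(t(mus_dot),
                                              dim = c(1, 3, nf))))
  m <- length(tcf0$values) - 1
  vals <- NULL
  for (b in seq_along(r_grid)) {
    sb <- cross_sum_fft(mus_dot, rho_dot[, , b], m)
    sb <- (sb + cross_sum_fft(rho_dot[, , b], mus_dot, m)) / 2
    ctcf <- structure(list(lags = tcf0$lags, values = sb / (nf - 0:m),
                           dt = tcf0$dt, n_series = 1, type = "cross"),
                      class = "dipole_tcf")
    sp <- spectrum_from_tcf(ctcf, ...)
    if (smoothing > 0) sp <- gaussian_smooth(sp, smoothing)
    if (is.null(vals)) vals <- matrix(0, length(sp$wavenumber),
                                      length(r_grid))
    vals[, b] <- sp$values * 4 * pi * r_grid[b]^2
    wn <- sp$wavenumber
    meta0 <- sp$meta
  }
  radial_spectrum(wn, r_grid, vals, meta = c(
    meta0, list(sigma = sigma, radial_bin = radial_bin,
                spectral_smoothing = smoothing)))
}

#' Solute-total cross spectrum
#'
#' The direct route to the quantity the radially resolved spectrum must
#' integrate to: the symmetrized cross-spectrum of the solute dipole with
#' the total dipole (derivative route).
#'
#' @param series a `dipole_series` containing a `"solute"` molecule
#' @param ... passed to [spectrum_from_tcf()]
#' @return an `ir_spectrum`
#' @export
solute_total_cross_spectrum <- function(series, ...) {
  deriv <- dipole_derivative(series)
  s <- which(series$tags == "solute")
  stopifnot(length(s) == 1)
  sol <- subset_molecules(deriv, s)
  spectrum_from_tcf(autocorrelation(sol, with = deriv), ...)
}

#' Carve a logistic sphere dipole around the solute
#'
#' `mu_s^R(t) = N_s^R(t) [mu_s(t) + sum_i P_si(t) mu_i(t)]` with
#' `P_si = 1 / (1 + exp((R_si - Rc)/D))` from solute-solvent
#' center-of-mass distances under minimum image, and
#' `N_s^R = (1 + sum_i P_si^2)^(-1/2)` normalizing to a single molecule.
#'
#' @param series a `dipole_series` with one `"solute"` molecule and centers
#'   of mass
#' @param cell_edge cubic cell edge, A
#' @param R_c cutoff radius, A (> 0)
#' @param D_width logistic width, A (> 0; default 0.25)
#' @return a single-molecule `dipole_series` of the carved dipole; the
#'   per-frame weights are in attribute `"weights"` (`[n_solvent, nf]`) and
#'   the normalization in `"normalization"`
#' @export
carve_sphere_dipole <- function(series, cell_edge, R_c, D_width = 0.25) {
  stopifnot(R_c > 0, D_width > 0)
  dists <- solute_com_distances(series, cell_edge)
  s <- which(series$tags == "solute")
  nf <- length(series$times)
  P <- 1 / (1 + exp((dists[-s, , drop = FALSE] - R_c) / D_width))
  Nn <- 1 / sqrt(1 + colSums(P^2))
  mu_s <- series$mu[s, , , drop = FALSE][1, , ]        # [3, nf]
  if (nf == 1) mu_s <- matrix(mu_s, 3, 1)
  mu_solv <- series$mu[-s, , , drop = FALSE]
  carved <- array(0, dim = c(1, 3, nf))
  for (ax in 1:3) {
    solv_sum <- colSums(mu_solv[, ax, , drop = FALSE][, 1, , drop = TRUE] *
                          P)
    if (dim(mu_solv)[1] == 1)
      solv_sum <- as.vector(mu_solv[1, ax, ] * P[1, ])
    carved[1, ax, ] <- Nn * (mu_s[ax, ] + solv_sum)
  }
  out <- dipole_series(series$times, carved, tags = "carved")
  attr(out, "weights") <- P
  attr(out, "normalization") <- Nn
  attr(out, "R_c") <- R_c
  attr(out, "D_width") <- D_width
  out
}

#' Distance-dependent IR spectrum
#'
#' Autocorrelation spectrum of the carved sphere dipole (derivative route),
#' for one cutoff or a whole family of cutoffs in one pass.
#'
#' @param series a `dipole_series` with one `"solute"` molecule
#' @param cell_edge cubic cell edge, A
#' @param R_c cutoff radius or vector of radii, A
#' @param D_width logistic width, A
#' @param smoothing Gaussian filter FWHM, cm^-1 (0 disables)
#' @param ... passed to [spectrum_from_tcf()]
#' @return an `ir_spectrum` for a single cutoff, or a named list of them
#' @export
distance_dependent_spectrum <- function(series, cell_edge, R_c,
                                        D_width = 0.25, smoothing = 20,
                                        ...) {
  one <- function(rc) {
    carved <- carve_sphere_dipole(series, cell_edge, rc, D_width)
    sp <- ir_spectrum_from_dipoles(carved, smoothing = smoothing, ...)
    sp$meta$R_c <- rc
    sp$meta$D_width <- D_width
    sp
  }
  if (length(R_c) == 1) return(one(R_c))
  out <- lapply(R_c, one)
  names(out) <- sprintf("Rc=%.3g", R_c)
  out
}

#' Select the cutoff radius from an intensity-modulation curve
#'
#' Given band intensity as a function of cutoff radius (sampled on at
#' least 8 cutoffs spanning the solute-dominated and bulk-like regimes),
#' fits a smoothing cubic-spline interpolant and returns the inflection
#' point:
#' the radius of maximum-magnitude slope between the two plateaus. A curve
#' without detectable plateaus at both ends (e.g. a straight line) is an
#' error.
#'
#' @param R_c cutoff radii, A (increasing, length >= 8)
#' @param intensity band intensity at each cutoff
#' @param plateau_frac end-slope fraction of the peak slope above which the
#'   curve is declared non-sigmoidal (default 0.25)
#' @return the inflection cutoff `R_c*`, A
#' @export
select_cutoff <- function(R_c, intensity, plateau_frac = 0.25) {
  stopifnot(length(R_c) == length(intensity))
  if (length(R_c) < 8)
    stop("need at least 8 cutoffs spanning both regimes, got ",
         length(R_c))
  o <- order(R_c)
  R_c <- R_c[o]; intensity <- intensity[o]
  f <- stats::splinefun(R_c, intensity, method = "natural")
  fine <- seq(min(R_c), max(R_c), length.out = 2001)
  slope <- abs(f(fine, deriv = 1))
  i_max <- which.max(slope)
  peak <- slope[i_max]
  n_edge <- max(3, round(length(fine) * 0.05))
  edge <- max(slope[seq_len(n_edge)],
              slope[(length(fine) - n_edge + 1):length(fine)])
  if (peak <= 0 || edge > plateau_frac * peak)
    stop("non-sigmoidal modulation curve: no plateaus detected ",
         "(end slope ", format(edge, digits = 3), " vs peak ",
         format(peak, digits = 3), ")")
  fine[i_max]
}

#' Average number of waters within the carving sphere
#'
#' The soft count is the time average of `sum_i P_si` (possibly
#' fractional); the hard count uses the sharp criterion `R_si < R_c`.
#'
#' @inheritParams carve_sphere_dipole
#' @return list with `soft` and `hard` average counts
#' @export
count_waters_within <- function(series, cell_edge, R_c, D_width = 0.25) {
  dists <- solute_com_distances(series, cell_edge)
  s <- which(series$tags == "solute")
  d <- dists[-s, , drop = FALSE]
  P <- 1 / (1 + exp((d - R_c) / D_width))
  list(soft = mean(colSums(P)), hard = mean(colSums(d < R_c)))
}
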