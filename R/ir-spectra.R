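# IR spectra from dipole time-correlation functions.
#
# The linear absorption coefficient is the Fourier transform of the total
# dipole TCF times a quantum-correction prefactor,
#   alpha(w) = F(w) Int dt e^{-iwt} <M(0).M(t)>.
# Spectra are computed from TCFs of finite differences of the dipole (the
# derivative route), so no additional w^2 factor is applied.

kJmol_per_cm <- 11.96266e-3  # h*c*N_A per cm^-1, kJ/mol

#' Finite-difference time derivative of a dipole series
#'
#' Central differences at interior points, one-sided at the ends; units
#' D/fs. The grid must be uniform.
#'
#' @param series a `dipole_series`
#' @return a `dipole_series` of derivatives on the same time grid
#' @export
dipole_derivative <- function(series) {
  n <- length(series$times)
  if (n < 3) stop("need at least 3 samples for a finite difference")
  dtg <- diff(series$times)
  if (max(abs(dtg - dtg[1])) > 1e-8 * abs(dtg[1]))
    stop("non-uniform time grid")
  dt <- dtg[1]
  mu <- series$mu
  d <- array(0, dim = dim(mu))
  d[, , 2:(n - 1)] <- (mu[, , 3:n] - mu[, , 1:(n - 2)]) / (2 * dt)
  d[, , 1] <- (mu[, , 2] - mu[, , 1]) / dt
  d[, , n] <- (mu[, , n] - mu[, , n - 1]) / dt
  dipole_series(series$times, d, series$tags)
}

# FFT-based sum over origins of x(t)*y(t+lag) for matrices [n, 3]
cross_sum_fft <- function(x, y, max_lag_steps) {
  n <- nrow(x)
  nfft <- stats::nextn(2 * n, 2)
  acc <- numeric(max_lag_steps + 1)
  for (ax in seq_len(ncol(x))) {
    fx <- stats::fft(c(x[, ax], rep(0, nfft - n)))
    fy <- stats::fft(c(y[, ax], rep(0, nfft - n)))
    cc <- Re(stats::fft(Conj(fx) * fy, inverse = TRUE)) / nfft
    acc <- acc + cc[seq_len(max_lag_steps + 1)]
  }
  acc
}

#' Time correlation function of dipole series
#'
#' Unbiased-normalized vector (auto- or cross-) correlation averaged over
#' all time origins:
#' `C(tau) = (1/(n - j)) sum_t a(t) . b(t + tau)`.
#' By default the total dipole of each series is correlated. Cross-TCFs are
#' symmetrized, `(<a(0)b(t)> + <b(0)a(t)>)/2`, so their spectra are real.
#' A list of series (independent trajectories) is ensemble averaged.
#'
#' @param series a `dipole_series` or a list of them
#' @param with optional second series (or list) for a cross-TCF
#' @param max_lag maximum lag in fs (default half the series duration)
#' @return object of class `dipole_tcf`: list with `lags` (fs), `values`,
#'   `dt`, `n_series`
#' @export
autocorrelation <- function(series, with = NULL, max_lag = NULL) {
  alist <- if (inherits(series, "dipole_series")) list(series) else series
  blist <- if (is.null(with)) alist else {
    if (inherits(with, "dipole_series")) list(with) else with
  }
  stopifnot(length(alist) == length(blist))
  dt <- alist[[1]]$times[2] - alist[[1]]$times[1]
  n <- length(alist[[1]]$times)
  m <- if (is.null(max_lag)) floor((n - 1) / 2) else round(max_lag / dt)
  if (m >= n)
    stop("max_lag (", m * dt, " fs) exceeds the series duration")
  vals <- numeric(m + 1)
  for (r in seq_along(alist)) {
    a <- total_dipole(alist[[r]])
    b <- total_dipole(blist[[r]])
    stopifnot(nrow(a) == n, nrow(b) == n)
    s <- cross_sum_fft(a, b, m)
    if (!is.null(with)) s <- (s + cross_sum_fft(b, a, m)) / 2
    vals <- vals + s / (n - 0:m)
  }
  structure(list(lags = (0:m) * dt, values = vals / length(alist), dt = dt,
                 n_series = length(alist),
                 type = if (is.null(with)) "auto" else "cross"),
            class = "dipole_tcf")
}

#' @export
print.dipole_tcf <- function(x, ...) {
  cat(sprintf(
    "<dipole_tcf> %s, %d lags (0 .. %g fs, dt = %g), %d series averaged\n",
    x$type, length(x$lags), max(x$lags), x$dt, x$n_series))
  cat(sprintf("  C(0) = %.6g\n", x$values[1]))
  invisible(x)
}

quantum_prefactor <- function(wavenumber, choice, temperature) {
  if (choice == "harmonic") {
    x <- wavenumber * kJmol_per_cm /
      (hs_constants$R_kJmolK * temperature)
    ifelse(x < 1e-12, 1, x / (1 - exp(-x)))
  } else {
    rep(1, length(wavenumber))  # classical limit / none
  }
}

#' IR spectrum from a dipole TCF
#'
#' Even-symmetrizes the TCF, applies the chosen lag window, zero-pads to at
#' least the requested spectral resolution, Fourier transforms, applies the
#' quantum-correction prefactor, and maps onto a uniform wavenumber grid.
#' With a derivative TCF (the recommended route) no additional `w^2` factor
#' is applied.
#'
#' @param tcf a `dipole_tcf`
#' @param prefactor `"harmonic"` (default: `x/(1 - exp(-x))`,
#'   `x = beta h c nu`), `"classical"` or `"none"` (both unity; the choice
#'   is stamped in the metadata)
#' @param window `"hann"` (default) or `"none"` lag window
#' @param resolution target wavenumber spacing in cm^-1 (default 1);
#'   `NULL` keeps the native FFT grid (used by the Parseval check)
#' @param temperature K, for the prefactor
#' @param max_wavenumber upper end of the output grid (default: the
#'   Nyquist limit)
#' @return an `ir_spectrum` (values in consistent arbitrary units,
#'   flagged in the metadata)
#' @export
spectrum_from_tcf <- function(tcf, prefactor = c("harmonic", "classical",
                                                 "none"),
                              window = c("hann", "none"), resolution = 1,
                              temperature = 298.15, max_wavenumber = NULL) {
  prefactor <- match.arg(prefactor)
  window <- match.arg(window)
  dt <- tcf$dt
  c_vals <- tcf$values
  m <- length(c_vals) - 1
  w <- if (window == "hann" && m > 0)
    0.5 * (1 + cos(pi * (0:m) / m)) else rep(1, m + 1)
  cw <- c_vals * w
  # even symmetrization: [c0, c1..cm, 0-pad, cm..c1]
  native_res <- if (is.null(resolution)) Inf else resolution
  n_min <- max(2 * m + 2,
               ceiling(1 / (native_res * hs_constants$c_cm_fs * dt)))
  nfft <- stats::nextn(n_min, 2)
  buf <- numeric(nfft)
  buf[1:(m + 1)] <- cw
  if (m > 0) buf[nfft - (1:m) + 1] <- cw[2:(m + 1)]
  sp <- Re(stats::fft(buf)) * dt
  wn_native <- (0:(nfft - 1)) / (nfft * dt * hs_constants$c_cm_fs)
  nyq <- nyquist_wavenumber(dt)
  if (is.null(max_wavenumber)) max_wavenumber <- nyq
  keep <- wn_native <= min(max_wavenumber, nyq) + 1e-9
  wn <- wn_native[keep]
  vals <- sp[keep]
  if (!is.null(resolution)) {
    grid <- seq(0, min(max_wavenumber, nyq), by = resolution)
    vals <- stats::approx(wn, vals, xout = grid, rule = 2)$y
    wn <- grid
  }
  vals <- vals * quantum_prefactor(wn, prefactor, temperature)
  ir_spectrum(wn, vals, meta = list(
    prefactor = prefactor, window = window,
    resolution = if (is.null(resolution)) "native" else resolution,
    temperature = temperature, n_series = tcf$n_series,
    units = "arbitrary", tcf_type = tcf$type))
}

#' One-call IR spectrum from dipole series
#'
#' The standard route: finite-difference dipole derivative, unbiased TCF
#' (ensemble averaged over a list of trajectories), windowed FFT, prefactor,
#' then Gaussian smoothing.
#'
#' @param series a `dipole_series` or list of them
#' @param smoothing Gaussian filter width (FWHM), cm^-1; 0 disables
#' @param ... passed to [spectrum_from_tcf()]
#' @return an `ir_spectrum`
#' @export
ir_spectrum_from_dipoles <- function(series, smoothing = 20, ...) {
  alist <- if (inherits(series, "dipole_series")) list(series) else series
  dlist <- lapply(alist, dipole_derivative)
  sp <- spectrum_from_tcf(autocorrelation(dlist), ...)
  if (smoothing > 0) sp <- gaussian_smooth(sp, width = smoothing)
  sp
}

#' Gaussian smoothing of a spectrum
#'
#' Convolution with a unit-area Gaussian of the given width (interpreted as
#' the FWHM), with reflective end handling so the integrated intensity is
#' preserved.
#'
#' @param spectrum an `ir_spectrum`
#' @param width filter width (FWHM), cm^-1; must be at least the grid
#'   spacing
#' @return the smoothed `ir_spectrum`
#' @export
gaussian_smooth <- function(spectrum, width = 20) {
  wn <- spectrum$wavenumber
  if (length(wn) < 2) return(spectrum)
  h <- wn[2] - wn[1]
  if (width < h)
    stop("smoothing width ", width, " cm^-1 is below the grid spacing ", h)
  sigma <- width / (2 * sqrt(2 * log(2)))
  half <- ceiling(4 * sigma / h)
  kern <- stats::dnorm(seq(-half, half) * h, sd = sigma)
  kern <- kern / sum(kern)
  n <- length(wn)
  pad_lo <- spectrum$values[pmin(n, pmax(1, (half + 1):2))]
  pad_hi <- spectrum$values[pmax(1, pmin(n, (n - 1):(n - half)))]
  padded <- c(pad_lo, spectrum$values, pad_hi)
  sm <- stats::filter(padded, kern, sides = 2)[(half + 1):(half + n)]
  ir_spectrum(wn, as.numeric(sm),
              meta = c(spectrum$meta, list(smoothing_fwhm = width)))
}

# principal-value Hilbert-type integral by Maclaurin's alternate-point rule:
# n(w_i) - n_inf = (2/pi) PV Int w' k(w') / (w'^2 - w_i^2) dw'
kk_index_from_k <- function(wavenumber, k, n_inf) {
  h <- wavenumber[2] - wavenumber[1]
  n_pts <- length(wavenumber)
  out <- numeric(n_pts)
  g <- wavenumber * k
  parity <- seq_len(n_pts) %% 2
  for (start in seq(1, n_pts, by = 512)) {
    idx <- start:min(start + 511, n_pts)
    denom <- outer(wavenumber^2, wavenumber[idx]^2, `-`)
    mask <- outer(parity, parity[idx], `!=`)
    contrib <- (g * mask) / ifelse(denom == 0, Inf, denom)
    out[idx] <- colSums(contrib) * 2 * h * 2 / pi
  }
  n_inf + out
}

#' Kramers-Kronig refractive-index correction
#'
#' The raw FT spectrum is proportional to `n(w) alpha(w)`. The imaginary
#' refractive index is `k = alpha / (4 pi nu)`; the real index follows from
#' the principal-value Kramers-Kronig relation anchored at the optical
#' index `n_D`. The two are solved self-consistently by fixed-point
#' iteration and the absorption is rescaled by the reconstructed `n(w)`.
#' Zero absorption returns the spectrum unchanged with `n(w) = n_D`.
#'
#' @param spectrum an `ir_spectrum`; values are treated as
#'   `n(w) * alpha(w)` in consistent units
#' @param n_D optical (anchor) refractive index, default 1.3325 (water)
#' @param iterations fixed-point iterations (default 3)
#' @return an `ir_spectrum` of `alpha(w)`, with the reconstructed index in
#'   `$meta$refractive_index` and a `kk_edge_warning` flag when the
#'   absorption has not decayed at the grid ends
#' @export
kramers_kronig_refractive_correction <- function(spectrum, n_D = 1.3325,
                                                 iterations = 3) {
  wn <- spectrum$wavenumber
  A <- spectrum$values
  if (length(wn) < 4 || all(abs(A) < 1e-300)) {
    spectrum$meta$refractive_index <- rep(n_D, length(wn))
    spectrum$meta$n_D <- n_D
    return(spectrum)
  }
  edge_warn <- FALSE
  peak <- max(abs(A))
  if (abs(A[length(A)]) > 0.05 * peak || abs(A[1]) > 0.25 * peak)
    edge_warn <- TRUE
  wsafe <- pmax(wn, wn[2] / 2)  # avoid the w = 0 division
  n_cur <- rep(n_D, length(wn))
  for (it in seq_len(iterations)) {
    k <- A / (4 * pi * wsafe * n_cur)
    n_cur <- kk_index_from_k(wn, k, n_D)
    n_cur <- pmax(n_cur, 0.1)
  }
  out <- ir_spectrum(wn, A / n_cur, meta = c(
    spectrum$meta,
    list(n_D = n_D, kk_applied = TRUE, kk_edge_warning = edge_warn)))
  out$meta$refractive_index <- n_cur
  out
}

#' Reconstruct n(w) from an imaginary-index spectrum
#'
#' Direct access to the principal-value Kramers-Kronig step: given `k(w)`
#' on a uniform grid, returns `n(w)` anchored at `n_inf`. Used to validate
#' the transform against the closed-form Lorentz-oscillator index.
#'
#' @param wavenumber uniform grid, cm^-1
#' @param k imaginary refractive index on the grid
#' @param n_inf high-frequency (anchor) index
#' @return numeric vector `n(w)`
#' @export
kk_refractive_index <- function(wavenumber, k, n_inf = 1.3325) {
  stopifnot(length(wavenumber) == length(k), length(wavenumber) >= 4)
  kk_index_from_k(wavenumber, k, n_inf)
}

#' Band position within a window
#'
#' Position of the band maximum of the (already smoothed) spectrum inside
#' the window, with three-point parabolic refinement; or the intensity
#' centroid when `mode = "centroid"`.
#'
#' @param spectrum an `ir_spectrum`
#' @param window length-2 wavenumber range, cm^-1
#' @param mode `"maximum"` (default) or `"centroid"`
#' @return band position, cm^-1
#' @export
band_position <- function(spectrum, window, mode = c("maximum", "centroid")) {
  mode <- match.arg(mode)
  sel <- which(spectrum$wavenumber >= window[1] &
                 spectrum$wavenumber <= window[2])
  if (length(sel) == 0) stop("empty band window [", window[1], ", ",
                             window[2], "] cm^-1")
  wn <- spectrum$wavenumber[sel]
  v <- spectrum$values[sel]
  if (mode == "centroid") return(sum(wn * v) / sum(v))
  i <- which.max(v)
  if (i > 1 && i < length(v)) {
    denom <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (abs(denom) > 1e-300) {
      shift <- 0.5 * (v[i - 1] - v[i + 1]) / denom
      return(wn[i] + shift * (wn[2] - wn[1]))
    }
  }
  wn[i]
}

#' Red shift of an OH-stretch band
#'
#' Displacement of the band below the free-OH reference (3660 cm^-1 for
#' water diluted in CCl4).
#'
#' @param position band position, cm^-1
#' @param reference free-OH reference, cm^-1
#' @return red shift, cm^-1
#' @export
red_shift <- function(position, reference = 3660) reference - position

#' Hydrogen-bond enthalpy from an OH-stretch red shift
#'
#' The empirical correlation `-dH = 1.3 sqrt(red_shift)` between the
#' red shift of the OH stretching band (cm^-1) and the hydrogen-bond
#' enthalpy (kJ/mol).
#'
#' @param red_shift red shift, cm^-1 (>= 0)
#' @return `-dH`, kJ/mol
#' @export
hbond_enthalpy <- function(red_shift) {
  if (any(red_shift < 0)) stop("red shift must be non-negative")
  1.3 * sqrt(red_shift)
}

#' Hydrogen-bond enthalpy increase between two red shifts
#'
#' Per-bond enthalpy gain of environment `b` relative to environment `a`
#' (e.g. a hydration shell relative to bulk water).
#'
#' @param shift_a reference red shift, cm^-1
#' @param shift_b probe red shift, cm^-1
#' @return `ddH = (-dH_b) - (-dH_a)`, kJ/mol
#' @export
enthalpy_increase <- function(shift_a, shift_b) {
  hbond_enthalpy(shift_b) - hbond_enthalpy(shift_a)
}
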