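# TCF -> spectrum machinery: derivatives, autocorrelations, FFT spectra,
# smoothing, Kramers-Kronig, band positions and red-shift thermochemistry.

make_series <- function(values, dt = 2) {
  n <- length(values)
  mu <- array(0, dim = c(1, 3, n))
  mu[1, 1, ] <- values
  dipole_series((0:(n - 1)) * dt, mu)
}

test_that("finite-difference dipole derivative is exact on ramps and
           second-order on cosines", {
  t <- (0:99) * 2
  ramp <- make_series(0.3 * t)
  d <- dipole_derivative(ramp)
  expect_equal(as.vector(d$mu[1, 1, ]), rep(0.3, 100), tolerance = 1e-12)

  const <- make_series(rep(2.5, 50))
  expect_equal(max(abs(dipole_derivative(const)$mu)), 0)

  nu <- 1000
  om <- 2 * pi * wavenumber_to_freq(nu)
  cosine <- make_series(cos(om * t))
  dcos <- dipole_derivative(cosine)
  expected <- -om * sin(om * t)
  interior <- 2:99
  expect_lt(max(abs(dcos$mu[1, 1, interior] - expected[interior])),
            om^3 * 2^2 / 6 * 1.01)   # central-difference error bound

  bad <- make_series(rep(1, 3))
  bad$times <- c(0, 1, 3)
  expect_error(dipole_derivative(bad), "non-uniform")
})

test_that("autocorrelation: white noise is delta-like, cosines transform to
           cosines, scaling is quadratic", {
  set.seed(1)
  n <- 1e5
  wn <- make_series(rnorm(n))
  tcf <- autocorrelation(wn, max_lag = 100 * 2)
  sigma_est <- 3 / sqrt(n)    # estimator noise for i.i.d. samples
  expect_equal(tcf$values[1], 1, tolerance = 0.02)
  expect_lt(max(abs(tcf$values[-1])), 3.5 * sigma_est)

  t <- (0:4095) * 2
  om <- 2 * pi * wavenumber_to_freq(800)
  cs <- make_series(1.4 * cos(om * t))
  tc <- autocorrelation(cs, max_lag = 400)
  expect_equal(tc$values, 1.4^2 / 2 * cos(om * tc$lags), tolerance = 0.02)

  tc2 <- autocorrelation(make_series(3 * 1.4 * cos(om * t)),
                         max_lag = 400)
  expect_equal(tc2$values, 9 * tc$values, tolerance = 1e-9)

  expect_error(autocorrelation(cs, max_lag = 1e6), "max_lag")
})

test_that("spectrum of a cosine dipole peaks at its wavenumber and is
           linear over independent components", {
  s <- generate_harmonic_dipole(1000, 1, dt = 2, n_steps = 8192)
  sp <- ir_spectrum_from_dipoles(s, smoothing = 0)
  expect_lt(abs(band_position(sp, c(600, 1400)) - 1000), 2)

  # zero TCF -> zero spectrum
  z <- structure(list(lags = (0:32) * 2, values = numeric(33), dt = 2,
                      n_series = 1, type = "auto"), class = "dipole_tcf")
  expect_equal(max(abs(spectrum_from_tcf(z)$values)), 0)

  # independent series: the sum's spectrum is the sum of spectra up to a
  # small cross term
  set.seed(4)
  t <- (0:8191) * 2
  a <- make_series(cos(2 * pi * wavenumber_to_freq(900) * t))
  b <- make_series(cos(2 * pi * wavenumber_to_freq(2600) * t + 1.1))
  spa <- ir_spectrum_from_dipoles(a, smoothing = 0)
  spb <- ir_spectrum_from_dipoles(b, smoothing = 0)
  spab <- ir_spectrum_from_dipoles(dipole_series(a$times, a$mu + b$mu),
                                   smoothing = 0)
  resid <- spab$values - spa$values - spb$values
  expect_lt(max(abs(resid)), 0.02 * max(spa$values))

  # time-replication of a periodic signal preserves the peak position:
  # pick a wavenumber holding an integer number of periods in the segment
  nu_per <- 55 / (1024 * 2 * hs_constants$c_cm_fs)   # ~895.6 cm^-1
  seg <- cos(2 * pi * wavenumber_to_freq(nu_per) * (0:1023) * 2)
  sp1 <- ir_spectrum_from_dipoles(make_series(seg), smoothing = 0)
  spr <- ir_spectrum_from_dipoles(make_series(rep(seg, 3)), smoothing = 0)
  expect_lt(abs(band_position(spr, c(600, 1200)) -
                  band_position(sp1, c(600, 1200))), 2)
})

test_that("power spectrum integrates to the lag-zero TCF value
           (Parseval)", {
  s <- generate_harmonic_dipole(800, 1, dt = 2, n_steps = 4096)
  tcf <- autocorrelation(dipole_derivative(s))
  sp <- spectrum_from_tcf(tcf, prefactor = "none", window = "none",
                          resolution = NULL)
  dnu <- sp$wavenumber[2] - sp$wavenumber[1]
  total <- (2 * sum(sp$values) - sp$values[1] -
              sp$values[length(sp$values)]) * dnu * hs_constants$c_cm_fs
  expect_lt(abs(total / tcf$values[1] - 1), 1e-6)
})

test_that("Gaussian smoothing preserves integrals and resolves a
           100 cm-1 doublet at width 20", {
  wn <- seq(0, 600, by = 1)
  delta <- ir_spectrum(wn, as.numeric(wn == 300))
  sm <- gaussian_smooth(delta, 20)
  expect_lt(abs(sum(sm$values) / sum(delta$values) - 1), 1e-6)
  sigma <- 20 / (2 * sqrt(2 * log(2)))
  expect_equal(sm$values[wn == 300], dnorm(0, sd = sigma),
               tolerance = 1e-3)

  const <- ir_spectrum(wn, rep(2, length(wn)))
  expect_equal(gaussian_smooth(const, 20)$values, const$values,
               tolerance = 1e-9)

  doublet <- ir_spectrum(wn, as.numeric(wn %in% c(250, 350)))
  smd <- gaussian_smooth(doublet, 20)
  expect_lt(abs(band_position(smd, c(200, 300)) - 250), 1)
  expect_lt(abs(band_position(smd, c(300, 400)) - 350), 1)

  expect_error(gaussian_smooth(delta, 0.5), "grid spacing")
})

test_that("Kramers-Kronig: identity at zero absorption, matches the
           Lorentz oscillator closed form, linear when weak", {
  wn <- seq(1, 3000, by = 1.5)
  zero <- ir_spectrum(wn, numeric(length(wn)))
  out <- kramers_kronig_refractive_correction(zero)
  expect_equal(out$values, zero$values)
  expect_equal(out$meta$refractive_index, rep(1.3325, length(wn)))

  w0 <- 1500; gam <- 100; S <- 0.05; ninf <- 1.3325
  nk <- sqrt(ninf^2 + S * w0^2 / (w0^2 - wn^2 - 1i * gam * wn))
  n_rec <- kk_refractive_index(wn, Im(nk), n_inf = ninf)
  away <- abs(wn - w0) > 300
  expect_lt(max(abs(n_rec[away] - Re(nk)[away]) / Re(nk)[away]), 0.01)

  # weak-absorption linearity of n - n_D
  k1 <- 1e-4 * exp(-(wn - 1200)^2 / 2e4)
  d1 <- kk_refractive_index(wn, k1, ninf) - ninf
  d2 <- kk_refractive_index(wn, 2 * k1, ninf) - ninf
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
})

test_that("band positions and red shifts follow the smoothed maximum", {
  wn <- seq(3000, 3800, by = 1)
  band <- gaussian_smooth(ir_spectrum(wn, as.numeric(wn == 3377)), 20)
  pos <- band_position(band, c(3100, 3600))
  expect_lt(abs(pos - 3377), 0.5)
  expect_equal(red_shift(3377), 283)

  # symmetric Gaussian band: position equals its centre, both modes
  g <- ir_spectrum(wn, exp(-(wn - 3400)^2 / 800))
  expect_lt(abs(band_position(g, c(3200, 3600)) - 3400), 0.5)
  expect_lt(abs(band_position(g, c(3200, 3600), mode = "centroid") - 3400),
            0.5)

  # invariant under intensity scaling
  g2 <- ir_spectrum(wn, 7 * g$values)
  expect_equal(band_position(g2, c(3200, 3600)),
               band_position(g, c(3200, 3600)))

  expect_error(band_position(g, c(100, 200)), "empty")
})

test_that("red-shift -> hydrogen-bond enthalpy correlation", {
  expect_equal(hbond_enthalpy(283), 1.3 * sqrt(283))
  expect_equal(round(enthalpy_increase(283, 309)), 1)   # hydrated Z
  expect_equal(round(enthalpy_increase(283, 338)), 2)   # hydrated E
  expect_equal(enthalpy_increase(283, 309), 0.98, tolerance = 0.005)
  expect_equal(enthalpy_increase(283, 338), 2.03, tolerance = 0.005)
  expect_equal(enthalpy_increase(300, 300), 0)
  expect_error(hbond_enthalpy(-5), "non-negative")
})
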