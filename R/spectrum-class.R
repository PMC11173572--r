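# Spectrum containers: 1-D IR spectra and radius-resolved 2-D spectra.

#' Construct an IR spectrum
#'
#' Absorption (or cross-absorption) values on a strictly increasing uniform
#' wavenumber grid. Values may be signed: cross-spectra between a solute and
#' its environment carry meaningful negative lobes.
#'
#' @param wavenumber uniform wavenumber grid, cm^-1
#' @param values absorption values (arbitrary consistent units unless the
#'   metadata says otherwise)
#' @param meta named list of metadata (prefactor choice, smoothing width,
#'   trajectory count averaged, flags)
#' @return object of class `ir_spectrum`
#' @export
ir_spectrum <- function(wavenumber, values, meta = list()) {
  stopifnot(length(wavenumber) == length(values), all(is.finite(values)))
  if (length(wavenumber) > 2) {
    dg <- diff(wavenumber)
    stopifnot(all(dg > 0),
              max(abs(dg - dg[1])) < 1e-8 * max(abs(dg[1]), 1e-12))
  }
  structure(list(wavenumber = as.numeric(wavenumber),
                 values = as.numeric(values), meta = meta),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  n <- length(x$wavenumber)
  cat("<ir_spectrum>\n")
  if (n == 0) { cat("  (empty)\n"); return(invisible(x)) }
  cat(sprintf("  grid : %d points, %.6g .. %.6g cm^-1 (step %.6g)\n",
              n, x$wavenumber[1], x$wavenumber[n],
              if (n > 1) x$wavenumber[2] - x$wavenumber[1] else NA))
  pk <- which.max(x$values)
  cat(sprintf("  max  : %.6g at %.6g cm^-1\n", x$values[pk],
              x$wavenumber[pk]))
  if (length(x$meta))
    cat("  meta :", paste(names(x$meta), unlist(lapply(x$meta, format)),
                          sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.ir_spectrum <- function(x, ..., xlab = expression(tilde(nu) ~ (cm^-1)),
                             ylab = "absorption", type = "l") {
  graphics::plot(x$wavenumber, x$values, type = type, xlab = xlab,
                 ylab = ylab, ...)
  invisible(x)
}

#' Construct a radius-resolved spectrum
#'
#' Cross-absorption values indexed by wavenumber and by distance from the
#' solute center of mass.
#'
#' @param wavenumber uniform wavenumber grid, cm^-1
#' @param radius radial grid, Angstrom
#' @param values matrix `[wavenumber, radius]` of signed cross-absorption
#' @param meta named metadata list
#' @return object of class `radial_spectrum`
#' @export
radial_spectrum <- function(wavenumber, radius, values, meta = list()) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(wavenumber),
            ncol(values) == length(radius),
            all(is.finite(values)))
  structure(list(wavenumber = as.numeric(wavenumber),
                 radius = as.numeric(radius), values = values, meta = meta),
            class = "radial_spectrum")
}

#' @export
print.radial_spectrum <- function(x, ...) {
  cat("<radial_spectrum>\n")
  cat(sprintf("  wavenumber : %d points, %.6g .. %.6g cm^-1\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  cat(sprintf("  radius     : %d bins, %.4g .. %.4g Angstrom\n",
              length(x$radius), min(x$radius), max(x$radius)))
  cat(sprintf("  values     : signed, range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.radial_spectrum <- function(x, ...,
                                 xlab = expression(tilde(nu) ~ (cm^-1)),
                                 ylab = "r (Angstrom)") {
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(x$wavenumber, x$radius, x$values, col = pal, xlab = xlab,
                  ylab = ylab, ...)
  invisible(x)
}

#' Integrate a radial spectrum over radius
#'
#' Collapses the radial dimension by trapezoidal integration, recovering the
#' solute-total cross spectrum (the sum rule used to validate the
#' decomposition).
#'
#' @param rspec a `radial_spectrum`
#' @return an `ir_spectrum`
#' @export
integrate_radial_spectrum <- function(rspec) {
  r <- rspec$radius
  v <- rspec$values
  w <- trapezoid_weights(r)
  ir_spectrum(rspec$wavenumber, as.vector(v %*% w),
              meta = c(rspec$meta, list(radially_integrated = TRUE)))
}

trapezoid_weights <- function(x) {
  n <- length(x)
  if (n == 1) return(1)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}
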