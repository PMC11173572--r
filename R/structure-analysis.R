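# Structural analyses: radial distribution functions, coordination
# numbers, dihedral time series, intramolecular distance distributions.

#' Select atoms by element and molecule species
#'
#' @param traj an [md_trajectory]
#' @param topology optional [md_topology] (required for species filters)
#' @param element optional element symbol(s)
#' @param species optional molecule species tag(s)
#' @return integer atom indices
#' @export
select_atoms <- function(traj, topology = NULL, element = NULL,
                         species = NULL) {
  keep <- rep(TRUE, length(traj$elements))
  if (!is.null(element)) keep <- keep & traj$elements %in% element
  if (!is.null(species)) {
    stopifnot(!is.null(topology))
    keep <- keep & topology$species[topology$molecule] %in% species
  }
  which(keep)
}

#' Radial distribution function
#'
#' Minimum-image pair histogram between two atom selections, normalized by
#' the spherical shell volume and the partner number density, with the
#' running coordination integral `n(r)` (average partners of an A atom
#' within `r`). Shared atoms between the selections are never paired with
#' themselves.
#'
#' @param traj an [md_trajectory]
#' @param select_a,select_b integer atom-index vectors
#' @param bin_width histogram bin, A (default 0.02)
#' @param r_max outer radius, A; at most `cell_edge / 2` (the default)
#' @return object of class `rdf_result`: list with `r` (bin centers), `g`,
#'   `n` (coordination integral), `density` (partner density, 1/A^3),
#'   `bin_width`
#' @export
rdf <- function(traj, select_a, select_b, bin_width = 0.02, r_max = NULL) {
  L <- traj$cell_edge
  if (is.null(r_max)) r_max <- L / 2
  if (r_max > L / 2 + 1e-9)
    stop("r_max (", r_max, " A) exceeds half the cell edge (", L / 2, " A)")
  stopifnot(length(select_a) >= 1, length(select_b) >= 1, bin_width > 0)
  nb <- ceiling(r_max / bin_width)
  edges <- (0:nb) * bin_width
  counts <- numeric(nb)
  nf <- n_frames(traj)
  overlap <- intersect(select_a, select_b)
  for (k in seq_len(nf)) {
    A <- matrix(traj$atoms[select_a, , k], ncol = 3)
    B <- matrix(traj$atoms[select_b, , k], ncol = 3)
    d2 <- matrix(0, nrow(A), nrow(B))
    for (ax in 1:3)
      d2 <- d2 + min_image(outer(A[, ax], B[, ax], `-`), L)^2
    if (length(overlap))
      d2[cbind(match(overlap, select_a), match(overlap, select_b))] <- Inf
    d <- sqrt(d2[d2 < r_max^2])
    counts <- counts + tabulate(pmin(nb, floor(d / bin_width) + 1L), nb)
  }
  vol <- L^3
  # each A atom sees N_B partners, minus itself when it is in both sets
  n_b_eff <- length(select_b) - as.numeric(length(overlap) > 0)
  rho <- n_b_eff / vol
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
  g <- counts / (nf * length(select_a) * rho * shell)
  n_run <- cumsum(counts) / (nf * length(select_a))
  structure(list(r = edges[-(nb + 1)] + bin_width / 2, g = g, n = n_run,
                 density = rho, bin_width = bin_width,
                 n_frames = nf),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  pk <- which.max(x$g)
  cat(sprintf(
    "<rdf_result> %d bins (%.3g A each), partner density %.5g A^-3\n",
    length(x$r), x$bin_width, x$density))
  cat(sprintf("  g max %.3f at r = %.3f A; n(r_max) = %.3f\n",
              x$g[pk], x$r[pk], x$n[length(x$n)]))
  invisible(x)
}

#' @export
plot.rdf_result <- function(x, ..., xlab = "r (Angstrom)", ylab = "g(r)") {
  graphics::plot(x$r, x$g, type = "l", xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Coordination number from an RDF
#'
#' `n(r_bound)` with the bound either given explicitly or placed at the
#' first local minimum of the (3-bin moving-average smoothed) `g(r)` after
#' its first peak. The chosen bound is attached as attribute `"r_bound"`.
#'
#' @param rdf_result an `rdf_result`
#' @param bound `"first-minimum"` (default) or an explicit radius, A
#' @return coordination number (numeric, with attribute `r_bound`)
#' @export
coordination_number <- function(rdf_result, bound = "first-minimum") {
  r <- rdf_result$r
  if (is.numeric(bound)) {
    r_bound <- bound
  } else {
    g <- stats::filter(rdf_result$g, rep(1 / 3, 3), sides = 2)
    g[is.na(g)] <- rdf_result$g[is.na(g)]
    dg <- diff(g)
    peak <- NA
    for (i in seq_along(dg)[-1]) {
      if (dg[i - 1] > 0 && dg[i] <= 0 && g[i] > 0.1) { peak <- i; break }
    }
    if (is.na(peak)) stop("no first peak detected in g(r)")
    minimum <- NA
    for (i in seq(peak + 1, length(dg))) {
      if (dg[i - 1] < 0 && dg[i] >= 0) { minimum <- i; break }
    }
    if (is.na(minimum))
      stop("no first minimum after the first peak of g(r)")
    r_bound <- r[minimum]
  }
  val <- stats::approx(r, rdf_result$n, xout = r_bound, rule = 2)$y
  attr(val, "r_bound") <- r_bound
  val
}

# minimum-image vector between two atom positions
mi_vec <- function(a, b, L) min_image(b - a, L)

#' Dihedral-angle time series
#'
#' Signed dihedral of an atom quadruple per frame, using the standard
#' plane-normal `atan2` convention and minimum-image bond vectors; values
#' in `[-180, 180)` degrees (a planar trans quadruple maps to -180).
#' Collinear degenerate geometries yield `NA` for that frame and are
#' counted in the `n_degenerate` field.
#'
#' @param traj an [md_trajectory]
#' @param atoms four distinct atom indices
#' @return object of class `dihedral_series`: list with `times`, `angle`
#'   (degrees), `atoms`, `n_degenerate`
#' @export
dihedral_series <- function(traj, atoms) {
  stopifnot(length(atoms) == 4, length(unique(atoms)) == 4)
  L <- traj$cell_edge
  nf <- n_frames(traj)
  ang <- rep(NA_real_, nf)
  for (k in seq_len(nf)) {
    p <- traj$atoms[atoms, , k]
    b1 <- mi_vec(p[1, ], p[2, ], L)
    b2 <- mi_vec(p[2, ], p[3, ], L)
    b3 <- mi_vec(p[3, ], p[4, ], L)
    n1 <- cross3(b1, b2)
    n2 <- cross3(b2, b3)
    if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16) next  # collinear
    b2n <- b2 / sqrt(sum(b2^2))
    x <- sum(n1 * n2)
    y <- sum(cross3(n1, n2) * b2n)
    ang[k] <- wrap_angle(atan2(y, x) * 180 / pi)
  }
  structure(list(times = traj$times, angle = ang, atoms = atoms,
                 n_degenerate = sum(is.na(ang))),
            class = "dihedral_series")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat(sprintf(
    "<dihedral_series> atoms (%s), %d frames, mean %.2f deg%s\n",
    paste(x$atoms, collapse = ","), length(x$angle),
    mean(x$angle, na.rm = TRUE),
    if (x$n_degenerate > 0)
      sprintf(", %d degenerate frames flagged", x$n_degenerate) else ""))
  invisible(x)
}

#' @export
plot.dihedral_series <- function(x, ..., xlab = "t (fs)",
                                 ylab = "dihedral (deg)") {
  graphics::plot(x$times, x$angle, type = "l", ylim = c(-180, 180),
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Intramolecular distance distribution
#'
#' Normalized histogram of the (minimum-image, i.e. made-whole) distance
#' between two atoms of the same molecule across the trajectory.
#'
#' @param traj an [md_trajectory]
#' @param pair two atom indices
#' @param topology an [md_topology]; both atoms must belong to the same
#'   molecule
#' @param bin_width histogram bin, A
#' @return object of class `distance_distribution`: `mids`, `density`,
#'   `breaks` (density integrates to 1)
#' @export
intramolecular_distance_distribution <- function(traj, pair, topology,
                                                 bin_width = 0.02) {
  stopifnot(length(pair) == 2)
  if (topology$molecule[pair[1]] != topology$molecule[pair[2]])
    stop("atoms ", pair[1], " and ", pair[2],
         " belong to different molecules")
  L <- traj$cell_edge
  d <- sqrt(colSums(min_image(traj$atoms[pair[2], , ] -
                                traj$atoms[pair[1], , ], L)^2))
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width + 1e-9) * bin_width
  breaks <- seq(lo, max(hi, lo + bin_width), by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  structure(list(mids = h$mids, density = h$density, breaks = h$breaks,
                 n = length(d)),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf(
    "<distance_distribution> %d samples, mode at %.3f A\n",
    x$n, x$mids[which.max(x$density)]))
  invisible(x)
}

#' Geometric hydrogen-bond check for a snapshot
#'
#' Standard geometric criterion: donor-acceptor heavy-atom distance below
#' `d_max` and donor-H...acceptor angle above `angle_min`.
#'
#' @param donor,hydrogen,acceptor positions (length-3 vectors), A
#' @param cell_edge cubic cell edge, A
#' @param d_max heavy-atom distance cutoff, A (default 3.5)
#' @param angle_min angle cutoff, degrees (default 140)
#' @return logical
#' @export
is_hydrogen_bonded <- function(donor, hydrogen, acceptor, cell_edge,
                               d_max = 3.5, angle_min = 140) {
  da <- mi_vec(donor, acceptor, cell_edge)
  if (sqrt(sum(da^2)) >= d_max) return(FALSE)
  hd <- mi_vec(hydrogen, donor, cell_edge)
  ha <- mi_vec(hydrogen, acceptor, cell_edge)
  cosang <- sum(hd * ha) / sqrt(sum(hd^2) * sum(ha^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi > angle_min
}
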