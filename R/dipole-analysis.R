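# Molecular dipoles from atomic positions and Wannier centers.
#
# The total dipole of a closed-shell system decomposes exactly into
# molecular terms: each nucleus carries its valence charge (cores are
# pseudized) and each Wannier center carries -2e, so
#   mu = sum_n q_n r_n - 2e sum_w r_w
# is origin-independent whenever the molecule is charge neutral.

#' Construct a dipole time series
#'
#' Per-molecule dipole vectors on a uniform time grid, in Debye. The total
#' dipole is always the sum of the molecular terms; it is not stored
#' separately.
#'
#' @param times fs, uniform grid
#' @param mu numeric array `[n_molecules, 3, n_times]` of dipole vectors (D)
#' @param tags character vector of per-molecule species tags
#' @return object of class `dipole_series`
#' @export
dipole_series <- function(times, mu, tags = NULL) {
  if (is.matrix(mu)) mu <- array(mu, dim = c(1, dim(mu)))
  stopifnot(length(dim(mu)) == 3, dim(mu)[2] == 3,
            dim(mu)[3] == length(times))
  if (length(times) > 2) {
    dtg <- diff(times)
    stopifnot(max(abs(dtg - dtg[1])) < 1e-8 * abs(dtg[1]))
  }
  if (is.null(tags)) tags <- rep("other", dim(mu)[1])
  stopifnot(length(tags) == dim(mu)[1])
  structure(list(times = as.numeric(times), mu = mu,
                 tags = as.character(tags)),
            class = "dipole_series")
}

#' @export
print.dipole_series <- function(x, ...) {
  tab <- table(x$tags)
  cat(sprintf(
    "<dipole_series> %d molecules [%s], %d samples, dt = %g fs\n",
    dim(x$mu)[1], paste(sprintf("%s:%d", names(tab), tab), collapse = " "),
    length(x$times),
    if (length(x$times) > 1) x$times[2] - x$times[1] else NA))
  m <- total_dipole(x)
  cat(sprintf("  mean |M| = %.4f D\n", mean(sqrt(rowSums(m^2)))))
  invisible(x)
}

#' Total dipole of a series
#' @param series a `dipole_series`
#' @return matrix `[n_times, 3]`, Debye
#' @export
total_dipole <- function(series) {
  t(apply(series$mu, c(2, 3), sum))
}

#' Subset a dipole series by molecule
#' @param series a `dipole_series`
#' @param which integer indices or a species tag
#' @return a `dipole_series`
#' @export
subset_molecules <- function(series, which) {
  idx <- if (is.character(which)) which(series$tags %in% which) else which
  stopifnot(length(idx) >= 1)
  dipole_series(series$times,
                series$mu[idx, , , drop = FALSE], series$tags[idx])
}

#' Assign Wannier centers to molecules
#'
#' Each center goes to the molecule of its nearest atom under the
#' minimum-image metric. Distance ties (within 1e-9 Angstrom) break to the
#' lower molecule index. The expected center count per molecule is half its
#' summed valence charge (closed shell, -2e per center); any mismatch is an
#' error naming the molecule (and frame, when known).
#'
#' @param frame a frame as returned by [get_frame()]
#' @param topology an [md_topology]
#' @param frame_index optional frame number used in error messages
#' @return list of integer vectors: center indices per molecule
#' @export
assign_centers <- function(frame, topology, frame_index = NA) {
  impl <- assign_centers_impl(frame, topology)
  n_mol <- n_molecules(topology)
  if (is.null(impl)) return(rep(list(integer(0)), n_mol))
  out <- split(seq_along(impl$molecule),
               factor(impl$molecule, levels = seq_len(n_mol)))
  # closed-shell consistency: centers must pair up the valence electrons
  for (m in seq_len(n_mol)) {
    el <- frame$elements[topology$molecule == m]
    expected <- sum(topology$valence[el]) / 2
    got <- length(out[[m]])
    if (got != expected) {
      stop(sprintf(
        "center assignment error: molecule %d (%s) received %d centers, expected %g%s",
        m, topology$species[m], got, expected,
        if (is.na(frame_index)) "" else sprintf(" (frame %s)", frame_index)))
    }
  }
  names(out) <- NULL
  out
}

# centers -> (molecule, nearest atom) under minimum image; ties (within
# 1e-9 A) break to the lower molecule index
assign_centers_impl <- function(frame, topology) {
  n_ct <- nrow(frame$centers)
  if (n_ct == 0) return(NULL)
  L <- frame$cell_edge
  d2 <- matrix(0, n_ct, nrow(frame$atoms))
  for (ax in 1:3) {
    dd <- min_image(outer(frame$centers[, ax], frame$atoms[, ax], `-`), L)
    d2 <- d2 + dd * dd
  }
  molecule <- integer(n_ct)
  nearest <- integer(n_ct)
  dmin <- apply(d2, 1, min)
  for (w in seq_len(n_ct)) {
    cand <- which(d2[w, ] <= dmin[w] + 1e-9)
    molecule[w] <- min(topology$molecule[cand])
    nearest[w] <- cand[topology$molecule[cand] == molecule[w]][1]
  }
  list(molecule = molecule, nearest = nearest)
}

#' Classical molecular dipole from nuclei and Wannier centers
#'
#' The molecule is first made whole by minimum-image chaining from its first
#' atom (wrapped coordinates would corrupt the sum); each center is then
#' placed at its minimum-image position relative to the nearest made-whole
#' atom. The dipole is `sum q_n r_n - 2 sum r_w` in e-Angstrom, converted to
#' Debye. A non-neutral molecule is an error: its dipole would depend on the
#' origin.
#'
#' @param atoms matrix `[n, 3]` of atomic positions, Angstrom
#' @param elements character vector of element symbols
#' @param centers matrix `[m, 3]` of Wannier-center positions, Angstrom
#' @param valence named valence-charge vector
#' @param cell_edge cubic cell edge for minimum-image reconstruction; `NULL`
#'   means coordinates are already whole
#' @return dipole vector, Debye
#' @export
molecular_dipole <- function(atoms, elements, centers,
                             valence = default_valence_charges,
                             cell_edge = NULL) {
  atoms <- rbind(atoms)
  centers <- if (length(centers)) rbind(centers) else matrix(numeric(0), 0, 3)
  q <- valence[elements]
  stopifnot(!anyNA(q))
  net <- sum(q) - 2 * nrow(centers)
  if (abs(net) > 1e-9)
    stop("molecule is not charge neutral (net ", net,
         " e); dipole would be origin-dependent")
  if (!is.null(cell_edge)) {
    atoms <- make_whole(atoms, cell_edge)
    if (nrow(centers) > 0) {
      for (w in seq_len(nrow(centers))) {
        dd <- sweep(atoms, 2, centers[w, ], `-`)
        near <- which.min(rowSums(min_image(dd, cell_edge)^2))
        centers[w, ] <- atoms[near, ] -
          min_image(atoms[near, ] - centers[w, ], cell_edge)
      }
    }
  }
  mu_eA <- colSums(atoms * q) -
    if (nrow(centers) > 0) 2 * colSums(centers) else 0
  unname(mu_eA * hs_constants$debye_per_eA)
}

#' Per-molecule dipole time series from a trajectory
#'
#' Runs the center assignment and the classical dipole sum for every frame.
#' Also records each molecule's center of mass per frame (needed by the
#' spatial decompositions).
#'
#' @param traj an [md_trajectory]
#' @param topology an [md_topology]
#' @return a `dipole_series` with attribute `com`, an array
#'   `[n_molecules, 3, n_frames]` of molecular centers of mass (Angstrom)
#' @export
dipole_series_from_trajectory <- function(traj, topology) {
  nf <- n_frames(traj)
  nm <- n_molecules(topology)
  mu <- array(0, dim = c(nm, 3, nf))
  com <- array(0, dim = c(nm, 3, nf))
  L <- traj$cell_edge
  mol <- topology$molecule
  molf <- factor(mol, levels = seq_len(nm))
  # index of each molecule's reference (first) atom, expanded per atom
  ref_idx <- match(seq_len(nm), mol)[mol]
  q <- topology$valence[traj$elements]
  if (anyNA(q)) stop("unknown element in valence table")
  mass <- atomic_masses[traj$elements]
  mass_mol <- as.vector(rowsum(mass, molf))
  expected <- as.vector(rowsum(q, molf)) / 2
  for (k in seq_len(nf)) {
    at <- matrix(traj$atoms[, , k], ncol = 3)
    # make every molecule whole: minimum image relative to its first atom
    ref <- at[ref_idx, , drop = FALSE]
    at_whole <- ref + min_image(at - ref, L)
    ct <- matrix(traj$centers[, , k], ncol = 3)
    asg <- assign_centers_impl(list(atoms = at, centers = ct,
                                    cell_edge = L), topology)
    mu_k <- rowsum(at_whole * q, molf)
    if (!is.null(asg)) {
      got <- tabulate(asg$molecule, nm)
      bad <- which(got != expected)
      if (length(bad)) {
        stop(sprintf(
          "center assignment error: molecule %d (%s) received %d centers, expected %g (frame %d)",
          bad[1], topology$species[bad[1]], got[bad[1]], expected[bad[1]],
          k))
      }
      near <- asg$nearest
      ct_whole <- at_whole[near, , drop = FALSE] -
        min_image(at[near, , drop = FALSE] - ct, L)
      mu_k <- mu_k - 2 * rowsum(ct_whole,
                                factor(asg$molecule,
                                       levels = seq_len(nm)))
    }
    mu[, , k] <- mu_k * hs_constants$debye_per_eA
    com[, , k] <- rowsum(at_whole * mass, molf) / mass_mol
  }
  out <- dipole_series(traj$times, mu, topology$species)
  attr(out, "com") <- com
  out
}

#' Molecular centers of mass along a trajectory
#'
#' Computes per-molecule centers of mass (molecules made whole by
#' minimum-image chaining) without touching the Wannier centers; useful
#' for purely geometric analyses on boxes whose centers are absent or
#' ambiguous (e.g. ideal-gas placements).
#'
#' @param traj an [md_trajectory]
#' @param topology an [md_topology]
#' @return array `[n_molecules, 3, n_frames]`, Angstrom
#' @export
molecular_com_series <- function(traj, topology) {
  nf <- n_frames(traj)
  nm <- n_molecules(topology)
  com <- array(0, dim = c(nm, 3, nf))
  mol <- topology$molecule
  molf <- factor(mol, levels = seq_len(nm))
  ref_idx <- match(seq_len(nm), mol)[mol]
  mass <- atomic_masses[traj$elements]
  mass_mol <- as.vector(rowsum(mass, molf))
  for (k in seq_len(nf)) {
    at <- matrix(traj$atoms[, , k], ncol = 3)
    ref <- at[ref_idx, , drop = FALSE]
    at_whole <- ref + min_image(at - ref, traj$cell_edge)
    com[, , k] <- rowsum(at_whole * mass, molf) / mass_mol
  }
  com
}

#' Distribution of molecular dipole magnitudes
#'
#' Pools `|mu|` over all molecules carrying the requested tag and over time,
#' returns a normalized histogram together with the maximum-likelihood
#' normal fit (sample mean and standard deviation). A degenerate, constant
#' series skips the fit and sets `degenerate = TRUE`.
#'
#' @param series a `dipole_series`
#' @param tag species tag to pool (default `"water"`)
#' @param breaks histogram breaks specification (passed to [graphics::hist()])
#' @return object of class `dipole_distribution`: list with `mids`,
#'   `density`, `mean`, `sd`, `n`, `degenerate`
#' @export
dipole_distribution <- function(series, tag = "water", breaks = "FD") {
  sel <- subset_molecules(series, tag)
  mags <- sqrt(apply(sel$mu^2, c(1, 3), sum))
  x <- as.vector(mags)
  if (length(x) < 100)
    stop("need at least 100 samples for a dipole distribution, got ",
         length(x))
  degenerate <- stats::sd(x) < 1e-12 * max(abs(mean(x)), 1)
  h <- if (degenerate) {
    list(mids = mean(x), density = 1 / max(1e-12, diff(range(x), 1)))
  } else {
    graphics::hist(x, breaks = breaks, plot = FALSE)
  }
  structure(list(mids = h$mids, density = h$density,
                 mean = if (degenerate) NA_real_ else mean(x),
                 sd = if (degenerate) NA_real_ else stats::sd(x),
                 n = length(x), degenerate = degenerate, tag = tag),
            class = "dipole_distribution")
}

#' @export
print.dipole_distribution <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf(
      "<dipole_distribution> tag=%s n=%d: degenerate (constant |mu|)\n",
      x$tag, x$n))
  } else {
    cat(sprintf(
      "<dipole_distribution> tag=%s n=%d: normal fit mean %.4f D, sd %.4f D\n",
      x$tag, x$n, x$mean, x$sd))
  }
  invisible(x)
}
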