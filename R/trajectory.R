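# Trajectory and topology containers.
#
# A trajectory is stored column-major as 3D arrays [particle, xyz, frame]:
# atoms and Wannier centers are kept separately because centers are
# re-assigned to molecules per frame, not bonded.

#' Construct an MD trajectory object
#'
#' Time-ordered frames of atomic and Wannier-center positions in a periodic
#' cubic cell. Coordinates are in Angstrom and may be wrapped into `[0, L)`
#' or unwrapped; the flag is recorded so that downstream analyses can make
#' molecules whole via minimum-image chaining.
#'
#' @param elements character vector of element symbols, one per atom
#' @param atoms numeric array `[n_atoms, 3, n_frames]` of positions (Angstrom)
#' @param centers numeric array `[n_centers, 3, n_frames]` of Wannier-center
#'   positions (Angstrom); may have zero rows
#' @param cell_edge cubic cell edge in Angstrom
#' @param dt frame spacing in fs
#' @param times optional per-frame times in fs (default `(0:(n-1)) * dt`)
#' @param wrapped logical; are coordinates wrapped into `[0, cell_edge)`?
#' @return object of class `md_trajectory`
#' @export
md_trajectory <- function(elements, atoms, centers = NULL, cell_edge, dt,
                          times = NULL, wrapped = TRUE) {
  atoms <- as_coord_array(atoms)
  if (is.null(centers)) {
    centers <- array(numeric(0), dim = c(0, 3, dim(atoms)[3]))
  }
  centers <- as_coord_array(centers, n_frames = dim(atoms)[3])
  stopifnot(
    length(elements) == dim(atoms)[1],
    cell_edge > 0, dt > 0,
    dim(centers)[3] == dim(atoms)[3],
    all(is.finite(atoms)), all(is.finite(centers))
  )
  n_frames <- dim(atoms)[3]
  if (is.null(times)) times <- (seq_len(n_frames) - 1) * dt
  stopifnot(length(times) == n_frames)
  structure(
    list(elements = as.character(elements), atoms = atoms, centers = centers,
         cell_edge = cell_edge, dt = dt, times = times, wrapped = wrapped),
    class = "md_trajectory"
  )
}

as_coord_array <- function(x, n_frames = NULL) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  stopifnot(length(dim(x)) == 3, dim(x)[2] == 3)
  if (!is.null(n_frames) && dim(x)[1] == 0 && dim(x)[3] != n_frames) {
    x <- array(numeric(0), dim = c(0, 3, n_frames))
  }
  x
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory>\n")
  cat(sprintf("  frames   : %d (dt = %g fs, t = %g .. %g fs)\n",
              n_frames(x), x$dt, x$times[1], x$times[n_frames(x)]))
  cat(sprintf("  atoms    : %d  [%s]\n", length(x$elements),
              paste(sprintf("%s:%d", names(table(x$elements)),
                            table(x$elements)), collapse = " ")))
  cat(sprintf("  centers  : %d per frame\n", dim(x$centers)[1]))
  cat(sprintf("  cell     : cubic, L = %.4f Angstrom (%s)\n", x$cell_edge,
              if (x$wrapped) "wrapped" else "unwrapped"))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$atoms)[3]

#' Extract one frame from a trajectory
#'
#' @param traj an `md_trajectory`
#' @param i frame index (1-based)
#' @return list with `time`, `cell_edge`, `elements`, `atoms` (matrix n x 3),
#'   `centers` (matrix m x 3)
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  list(time = traj$times[i], cell_edge = traj$cell_edge,
       elements = traj$elements,
       atoms = traj$atoms[, , i, drop = FALSE][, , 1],
       centers = if (dim(traj$centers)[1] > 0)
         traj$centers[, , i, drop = FALSE][, , 1]
       else matrix(numeric(0), 0, 3))
}

#' Construct a molecular topology
#'
#' Assigns every atom to exactly one molecule and tags each molecule with a
#' species label. Valence charges follow the pseudopotential convention
#' (H +1, C +4, N +5, O +6): core electrons are folded into the nucleus, so
#' each nucleus carries its valence charge in classical dipole sums and each
#' Wannier center carries -2e.
#'
#' @param molecule integer vector, molecule index per atom (1-based,
#'   contiguous)
#' @param species character vector, one tag per molecule
#'   (`"water"`, `"solute"`, or `"other"`)
#' @param valence named numeric vector of valence charges per element
#' @return object of class `md_topology`
#' @export
md_topology <- function(molecule, species,
                        valence = default_valence_charges) {
  molecule <- as.integer(molecule)
  stopifnot(all(molecule >= 1), max(molecule) == length(species),
            all(seq_len(max(molecule)) %in% molecule))
  structure(list(molecule = molecule, species = as.character(species),
                 valence = valence),
            class = "md_topology")
}

#' @export
print.md_topology <- function(x, ...) {
  tab <- table(x$species)
  cat(sprintf("<md_topology> %d atoms in %d molecules [%s]\n",
              length(x$molecule), length(x$species),
              paste(sprintf("%s:%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Number of molecules in a topology
#' @param topology an `md_topology`
#' @return integer count
#' @export
n_molecules <- function(topology) length(topology$species)

# Make a molecule whole across periodic boundaries by minimum-image chaining
# from its first atom; returns the adjusted coordinate matrix.
make_whole <- function(coords, cell_edge) {
  if (nrow(coords) <= 1) return(coords)
  ref <- coords[1, ]
  delta <- sweep(coords, 2, ref)
  sweep(min_image(delta, cell_edge), 2, ref, `+`)
}

# Center of mass of a molecule (standard atomic masses, minimal table).
atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, X = 0)

center_of_mass <- function(coords, elements) {
  m <- atomic_masses[elements]
  stopifnot(!anyNA(m))
  colSums(coords * m) / sum(m)
}
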