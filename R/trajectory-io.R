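# File I/O: (extended) XYZ trajectories with Wannier pseudo-element records,
# PLUMED-style HILLS files, and delimited spectrum tables.
#
# All readers are strict: silently truncated or ragged files raise errors
# naming the offending frame rather than returning partial data.

#' Read an (extended) XYZ trajectory
#'
#' Frames follow the XYZ convention: an atom-count line, a comment line, then
#' one `element x y z` record per atom. The comment line may carry
#' `key=value` pairs (`cell`, `time`, `frame`); `cell` overrides the
#' `cell_edge` argument, per-frame `time` overrides the `t0 + k*dt` default.
#' Records with the pseudo-element `"X"` are split out as Wannier centers.
#' A sidecar XYZ of centers (pseudo-element or any element label) may be
#' supplied; its frame count must equal the main trajectory's.
#'
#' @param path path to the XYZ file
#' @param cell_edge cubic cell edge in Angstrom (required unless the comment
#'   lines carry `cell=`)
#' @param dt frame spacing in fs (default 2, the conventional dipole-saving
#'   stride)
#' @param centers_path optional sidecar XYZ holding Wannier centers
#' @return an [md_trajectory]
#' @export
read_xyz_trajectory <- function(path, cell_edge = NULL, dt = 2,
                                centers_path = NULL) {
  frames <- parse_xyz_frames(path)
  n <- length(frames)
  if (n == 0) stop("no frames found in ", path)

  elements0 <- frames[[1]]$elements
  for (k in seq_len(n)) {
    if (!identical(frames[[k]]$elements, elements0))
      stop("inconsistent atom ordering or count at frame ", k, " of ", path)
  }
  is_center <- elements0 == "X"
  n_at <- sum(!is_center)
  n_ct <- sum(is_center)

  atoms <- array(0, dim = c(n_at, 3, n))
  centers <- array(0, dim = c(n_ct, 3, n))
  times <- rep(NA_real_, n)
  cells <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    atoms[, , k] <- frames[[k]]$coords[!is_center, , drop = FALSE]
    centers[, , k] <- frames[[k]]$coords[is_center, , drop = FALSE]
    times[k] <- frames[[k]]$time
    cells[k] <- frames[[k]]$cell
  }
  if (any(!is.na(cells))) {
    cell_edge <- cells[which(!is.na(cells))[1]]
  }
  if (is.null(cell_edge)) stop("cell_edge not given and no cell= in ", path)
  if (anyNA(times)) times <- (seq_len(n) - 1) * dt

  if (!is.null(centers_path)) {
    side <- parse_xyz_frames(centers_path)
    if (length(side) != n)
      stop("sidecar has ", length(side), " frames but trajectory has ", n)
    n_side <- nrow(side[[1]]$coords)
    centers <- array(0, dim = c(n_side, 3, n))
    for (k in seq_len(n)) {
      if (nrow(side[[k]]$coords) != n_side)
        stop("ragged sidecar frame ", k, " in ", centers_path)
      centers[, , k] <- side[[k]]$coords
    }
  }
  md_trajectory(elements0[!is_center], atoms, centers,
                cell_edge = cell_edge, dt = dt, times = times)
}

parse_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    k <- k + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 0)
      stop("bad atom-count line at frame ", k, " of ", path)
    if (i + 1L + nat > length(lines))
      stop("truncated frame ", k, " in ", path, ": expected ", nat, " atoms")
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + nat)]
    recs <- strsplit(trimws(body), "\\s+")
    lens <- lengths(recs)
    if (any(lens < 4))
      stop("ragged record in frame ", k, " of ", path)
    el <- vapply(recs, `[`, "", 1L)
    xyz <- matrix(suppressWarnings(as.numeric(
      unlist(lapply(recs, function(r) r[2:4])))), ncol = 3, byrow = TRUE)
    if (anyNA(xyz))
      stop("non-numeric coordinate in frame ", k, " of ", path)
    kv <- parse_key_values(comment)
    frames[[k]] <- list(elements = el, coords = xyz,
                        time = kv[["time"]] %||% NA_real_,
                        cell = kv[["cell"]] %||% NA_real_)
    i <- i + 2L + nat
  }
  frames
}

parse_key_values <- function(line) {
  out <- list()
  m <- regmatches(line, gregexpr("([A-Za-z_]+)=([-0-9.eE+]+)", line))[[1]]
  for (tok in m) {
    parts <- strsplit(tok, "=", fixed = TRUE)[[1]]
    out[[parts[1]]] <- as.numeric(parts[2])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory as (extended) XYZ
#'
#' Wannier centers are written inline as pseudo-element `"X"` records, or to
#' a sidecar file, or dropped. The comment line carries
#' `cell=<L> time=<t> frame=<k>`.
#'
#' @param traj an [md_trajectory]
#' @param path output path
#' @param centers one of `"inline"`, `"sidecar"`, `"none"`
#' @param sidecar_path path for the sidecar file when `centers = "sidecar"`
#' @param digits coordinate precision (decimal digits)
#' @return `path`, invisibly
#' @export
write_xyz_trajectory <- function(traj, path, centers = c("inline", "sidecar",
                                                         "none"),
                                 sidecar_path = NULL, digits = 10) {
  centers <- match.arg(centers)
  n <- n_frames(traj)
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df", digits, digits, digits)
  main <- character(0)
  side <- character(0)
  n_ct <- dim(traj$centers)[1]
  for (k in seq_len(n)) {
    fr <- get_frame(traj, k)
    cmt <- sprintf("cell=%.10g time=%.10g frame=%d", traj$cell_edge,
                   fr$time, k - 1L)
    at_lines <- sprintf(fmt, fr$elements, fr$atoms[, 1], fr$atoms[, 2],
                        fr$atoms[, 3])
    ct_lines <- if (n_ct > 0)
      sprintf(fmt, "X", fr$centers[, 1], fr$centers[, 2], fr$centers[, 3])
    else character(0)
    if (centers == "inline") {
      main <- c(main, length(at_lines) + length(ct_lines), cmt, at_lines,
                ct_lines)
    } else {
      main <- c(main, length(at_lines), cmt, at_lines)
      if (centers == "sidecar")
        side <- c(side, length(ct_lines), cmt, ct_lines)
    }
  }
  writeLines(main, path)
  if (centers == "sidecar") {
    if (is.null(sidecar_path))
      sidecar_path <- sub("(\\.[^.]*)?$", "-centers.xyz", path)
    writeLines(side, sidecar_path)
  }
  invisible(path)
}

# ---- HILLS files -----------------------------------------------------------

hill_unit_factors <- list(
  time = c(fs = 1, ps = 1000),
  cv = c(deg = 1, degree = 1),
  height = c(`kj/mol` = 1, kjmol = 1,
             hartree = 2625.4996, `kcal/mol` = 4.184)
)

#' Read a metadynamics HILLS file
#'
#' Whitespace-delimited records `time  center  width  height`
#' (PLUMED-HILLS-like dialect). A header comment of the form
#' `#! units time=fs cv=deg height=hartree` (or `# units: ...`) declares the
#' on-disk units; everything is converted to the internal convention
#' (fs, degrees, degrees, kJ/mol). `cv=rad` applies to center and width.
#' Unknown unit tags and non-monotone times are errors.
#'
#' @param path path to the HILLS file
#' @param units optional named character vector overriding the header, e.g.
#'   `c(time = "fs", cv = "deg", height = "hartree")`
#' @return a `hill_records` data frame with columns `time` (fs),
#'   `center` (deg), `width` (deg), `height` (kJ/mol)
#' @export
read_hills <- function(path, units = NULL) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  body <- grep("^\\s*#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]

  u <- c(time = "fs", cv = "deg", height = "kJ/mol")
  for (h in hdr) {
    m <- regmatches(h, gregexpr("(time|cv|height)=([A-Za-z/]+)", h))[[1]]
    for (tok in m) {
      parts <- strsplit(tok, "=", fixed = TRUE)[[1]]
      u[parts[1]] <- parts[2]
    }
  }
  if (!is.null(units)) u[names(units)] <- units

  f_time <- hill_unit_factors$time[u[["time"]]]
  f_height <- hill_unit_factors$height[tolower(u[["height"]])]
  cv_unit <- u[["cv"]]
  if (is.na(f_time)) stop("unknown time unit tag: ", u[["time"]])
  if (is.na(f_height)) stop("unknown height unit tag: ", u[["height"]])
  if (!cv_unit %in% c("deg", "degree", "rad"))
    stop("unknown cv unit tag: ", cv_unit)
  f_cv <- if (cv_unit == "rad") 180 / pi else 1

  if (length(body) == 0) {
    return(hill_records(numeric(0), numeric(0), numeric(0), numeric(0)))
  }
  recs <- strsplit(trimws(body), "\\s+")
  if (any(lengths(recs) < 4)) stop("short HILLS record in ", path)
  num <- matrix(as.numeric(unlist(lapply(recs, `[`, 1:4))), ncol = 4,
                byrow = TRUE)
  if (anyNA(num)) stop("non-numeric HILLS record in ", path)
  tm <- num[, 1] * f_time
  if (any(diff(tm) <= 0)) stop("non-monotone deposition times in ", path)
  hill_records(time = tm, center = wrap_angle(num[, 2] * f_cv),
               width = num[, 3] * f_cv, height = num[, 4] * f_height)
}

#' Construct a hill-record table
#'
#' @param time deposition times, fs (strictly increasing)
#' @param center Gaussian centers on the CV, degrees
#' @param width Gaussian widths, degrees (> 0)
#' @param height deposited heights, kJ/mol (> 0)
#' @return data frame of class `hill_records`
#' @export
hill_records <- function(time, center, width, height) {
  stopifnot(all(width > 0) || length(width) == 0,
            all(height > 0) || length(height) == 0,
            !is.unsorted(time, strictly = TRUE) || length(time) <= 1)
  structure(data.frame(time = time, center = center, width = width,
                       height = height),
            class = c("hill_records", "data.frame"))
}

#' Write a HILLS file in the internal unit convention
#'
#' @param hills a `hill_records` table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_hills <- function(hills, path) {
  hdr <- "#! FIELDS time center width height units time=fs cv=deg height=kJ/mol"
  rows <- sprintf("%.8f %.10g %.10g %.12g", hills$time, hills$center,
                  hills$width, hills$height)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ---- spectrum tables -------------------------------------------------------

#' Write a spectrum to a delimited text table
#'
#' One-dimensional spectra become two columns (`wavenumber value`);
#' radius-resolved spectra become long-format three columns
#' (`wavenumber radius value`). A `#`-comment header records units and
#' metadata so that a round trip preserves provenance.
#'
#' @param spectrum an `ir_spectrum` or `radial_spectrum`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_spectrum <- function(spectrum, path) {
  meta <- Filter(function(x) is.atomic(x) && length(x) == 1,
                 spectrum$meta)
  meta_lines <- sprintf("# meta %s=%s", names(meta),
                        vapply(meta, format, "", digits = 15))
  if (inherits(spectrum, "radial_spectrum")) {
    hdr <- "# wavenumber_cm-1 radius_A value"
    grid <- expand.grid(wavenumber = spectrum$wavenumber,
                        radius = spectrum$radius)
    rows <- sprintf("%.17g %.17g %.17g", grid$wavenumber, grid$radius,
                    as.vector(spectrum$values))
  } else {
    hdr <- "# wavenumber_cm-1 absorption"
    rows <- sprintf("%.17g %.17g", spectrum$wavenumber, spectrum$values)
  }
  writeLines(c(meta_lines, hdr, rows), path)
  invisible(path)
}

#' Read a spectrum table written by [write_spectrum()]
#'
#' @param path path to the table
#' @return an `ir_spectrum` or `radial_spectrum`, according to the column
#'   count
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# meta ", lines, value = TRUE)
  body <- grep("^\\s*#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^# meta ", "", ml)
    pos <- regexpr("=", kv, fixed = TRUE)
    key <- substr(kv, 1, pos - 1)
    val <- substr(kv, pos + 1, nchar(kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (is.na(num)) val else num
  }
  if (length(body) == 0) {
    return(ir_spectrum(numeric(0), numeric(0), meta = meta))
  }
  recs <- strsplit(trimws(body), "\\s+")
  ncol <- unique(lengths(recs))
  if (length(ncol) != 1) stop("ragged spectrum table in ", path)
  num <- matrix(as.numeric(unlist(recs)), ncol = ncol, byrow = TRUE)
  if (anyNA(num)) stop("non-numeric value in spectrum table ", path)
  if (ncol == 2) {
    ir_spectrum(num[, 1], num[, 2], meta = meta)
  } else if (ncol == 3) {
    wn <- sort(unique(num[, 1]))
    rr <- sort(unique(num[, 2]))
    vals <- matrix(NA_real_, length(wn), length(rr))
    vals[cbind(match(num[, 1], wn), match(num[, 2], rr))] <- num[, 3]
    radial_spectrum(wn, rr, vals, meta = meta)
  } else stop("unexpected column count in spectrum table ", path)
}
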