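# RDFs, coordination numbers, dihedrals and intramolecular distances.

test_that("ideal-gas box gives g(r) = 1 beyond the molecular size", {
  gs <- NULL
  for (sd in 1:4) {
    spec <- synthetic_box_spec(n_water = 128, n_solute = 0, n_steps = 1,
                               seed = sd, cell_edge = 15.66,
                               placement = "ideal", com_amplitude = 0)
    tr <- generate_water_box(spec)
    o <- select_atoms(tr, element = "O")
    r <- rdf(tr, o, o, bin_width = 0.2)
    gs <- rbind(gs, r$g)
  }
  g_mean <- colMeans(gs)
  window <- r$r > 3 & r$r < 7
  expect_lt(mean(abs(g_mean[window] - 1)), 0.05)
  expect_lt(max(abs(g_mean[window] - 1)), 0.2)
  expect_lt(abs(mean(g_mean[window]) - 1), 0.05)
})

test_that("RDF density sum rule: the full integral counts all partners", {
  spec <- synthetic_box_spec(n_water = 64, n_solute = 0, n_steps = 2,
                             seed = 8, placement = "ideal",
                             com_amplitude = 0)
  tr <- generate_water_box(spec)
  o <- select_atoms(tr, element = "O")
  r <- rdf(tr, o, o, bin_width = 0.1)
  # n(L/2) counts partners within the inscribed sphere of the cell
  frac <- 4 / 3 * pi * (tr$cell_edge / 2)^3 / tr$cell_edge^3
  expect_equal(r$n[length(r$n)], (length(o) - 1) * frac,
               tolerance = 0.15)
  expect_true(all(diff(r$n) >= 0))
  expect_true(all(r$g >= 0))
})

test_that("a fixed pair produces a single peak whose integral is one
           partner", {
  atoms <- rbind(c(5, 5, 5), c(6.7, 5, 5))
  tr <- md_trajectory(c("N", "H"), as_frames(atoms, 3), cell_edge = 12,
                      dt = 1)
  r <- rdf(tr, 1, 2, bin_width = 0.02)
  expect_equal(r$r[which.max(r$g)], 1.71, tolerance = 0.02)
  expect_equal(r$n[length(r$n)], 1, tolerance = 1e-9)

  # doubling the bin width preserves the coordination integral
  r2 <- rdf(tr, 1, 2, bin_width = 0.04)
  expect_equal(r2$n[length(r2$n)], r$n[length(r$n)], tolerance = 1e-9)

  expect_error(rdf(tr, 1, 2, r_max = 7), "half the cell")
})

test_that("coordination number integrates the first RDF peak to the first
           minimum", {
  # central atom with 2 then 3 partners at ~2.8 A (avg 2.5) and a far
  # second shell at 6 A
  a1 <- rbind(c(10, 10, 10), c(12.8, 10, 10), c(10, 12.8, 10),
              c(7.2, 10, 10), c(10, 10, 16), c(16, 10, 10), c(10, 16, 10))
  a2 <- a1
  a2[4, ] <- c(10, 7.2, 10)   # third partner in frame 2 as well
  arr <- array(0, dim = c(7, 3, 2))
  arr[, , 1] <- a1; arr[, , 2] <- a2
  # frame 1: partners at rows 2,3,4 (2.8 A) -> 3; drop one by moving it far
  arr[4, , 1] <- c(10, 10, 3)   # 7 A away in frame 1 -> 2 close partners
  tr <- md_trajectory(c("O", rep("H", 6)), arr, cell_edge = 20, dt = 1)
  r <- rdf(tr, 1, 2:7, bin_width = 0.1)
  cn <- coordination_number(r)
  expect_equal(as.numeric(cn), 2.5, tolerance = 1e-9)
  expect_gt(attr(cn, "r_bound"), 2.8)
  expect_lt(attr(cn, "r_bound"), 6)

  # explicit bound before the peak gives less than the peak content
  cn_early <- coordination_number(r, bound = 2.0)
  expect_lt(as.numeric(cn_early), as.numeric(cn))

  # monotone g(r) with no interior peak is an error
  fake <- structure(list(r = seq(0.05, 5, 0.1),
                         g = seq(0.05, 5, 0.1)^2 / 25,
                         n = cumsum(seq(0.05, 5, 0.1)) / 50,
                         density = 0.03, bin_width = 0.1),
                    class = "rdf_result")
  expect_error(coordination_number(fake), "peak|minimum")
})

test_that("dihedral angles follow the signed atan2 convention", {
  quad <- function(phi_deg) {
    phi <- phi_deg * pi / 180
    rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0),
          c(2, cos(phi), sin(phi)) + c(1, 0, 0) * 0)
  }
  mk <- function(coords) md_trajectory(c("O", "C", "N", "O"),
                                       as_frames(coords), cell_edge = 20,
                                       dt = 1)
  # planar cis -> 0; planar trans -> -180 (wrap convention); +90 -> +90
  expect_equal(dihedral_series(mk(quad(0)), 1:4)$angle, 0,
               tolerance = 1e-9)
  expect_equal(abs(dihedral_series(mk(quad(180)), 1:4)$angle), 180,
               tolerance = 1e-9)
  d90 <- dihedral_series(mk(quad(90)), 1:4)$angle
  expect_equal(d90, 90, tolerance = 1e-9)

  # mirror reflection flips the sign
  mirror <- quad(90); mirror[, 3] <- -mirror[, 3]
  expect_equal(dihedral_series(mk(mirror), 1:4)$angle, -90,
               tolerance = 1e-9)

  # rigid rotation + translation leave the dihedral unchanged
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- quad(90) %*% R + 3
  expect_equal(dihedral_series(mk(moved), 1:4)$angle, 90,
               tolerance = 1e-9)

  # collinear geometry is flagged, not fabricated
  lin <- rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0), c(4, 0, 0))
  ds <- dihedral_series(mk(lin), 1:4)
  expect_true(is.na(ds$angle))
  expect_equal(ds$n_degenerate, 1)
})

test_that("intramolecular distance distributions are normalized and
           located correctly", {
  # rigid pair at 2.52 A
  atoms <- rbind(c(5, 5, 5), c(7.52, 5, 5), c(5, 6, 5))
  tr <- md_trajectory(c("O", "O", "C"), as_frames(atoms, 4),
                      cell_edge = 15, dt = 1)
  topo <- md_topology(c(1, 1, 1), "solute")
  dd <- intramolecular_distance_distribution(tr, c(1, 2), topo)
  expect_equal(dd$mids[which.max(dd$density)], 2.52, tolerance = 0.02)
  expect_equal(sum(dd$density * diff(dd$breaks)), 1, tolerance = 1e-9)

  # harmonic bond about 3.1 A: mode within one bin of 3.1
  set.seed(5)
  n <- 4000
  d <- 3.1 + rnorm(n, 0, 0.08)
  arr <- array(0, dim = c(2, 3, n))
  arr[1, , ] <- 7
  arr[2, 1, ] <- 7 + d; arr[2, 2, ] <- 7; arr[2, 3, ] <- 7
  trh <- md_trajectory(c("H", "O"), arr, cell_edge = 15, dt = 1)
  topoh <- md_topology(c(1, 1), "solute")
  ddh <- intramolecular_distance_distribution(trh, c(1, 2), topoh,
                                              bin_width = 0.05)
  expect_lt(abs(ddh$mids[which.max(ddh$density)] - 3.1), 0.075)
  expect_equal(sum(ddh$density * diff(ddh$breaks)), 1, tolerance = 1e-9)

  topo2 <- md_topology(c(1, 2, 2), c("solute", "water"))
  expect_error(intramolecular_distance_distribution(tr, c(1, 2), topo2),
               "different molecules")
})

test_that("the geometric hydrogen-bond criterion separates bonded from
           non-bonded snapshots", {
  donor <- c(5, 5, 5); hyd <- c(5.96, 5, 5); acc <- c(7.8, 5, 5)
  expect_true(is_hydrogen_bonded(donor, hyd, acc, 20))
  expect_false(is_hydrogen_bonded(donor, hyd, c(9, 5, 5), 20))   # too far
  bent <- c(5, 8, 5)
  expect_false(is_hydrogen_bonded(donor, hyd, bent, 20))         # angle
})
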