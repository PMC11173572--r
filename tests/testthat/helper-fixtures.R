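# Shared fixtures, built once per test run.

RT298 <- hydrashell::hs_constants$R_kJmolK * 298.15

as_frames <- function(mat, n_frames = 1) {
  out <- array(0, dim = c(nrow(mat), 3, n_frames))
  for (k in seq_len(n_frames)) out[, , k] <- mat
  out
}

# small solvated box with water and solute vibrational modes; reused by the
# spatial and pipeline tests
solvated_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_box_spec(
        n_water = 16, n_solute = 1, n_steps = 256, seed = 42,
        vibrational_modes = data.frame(wavenumber = c(1650, 3400),
                                       amplitude = c(0.05, 0.08)),
        solute_modes = data.frame(wavenumber = 1600, amplitude = 0.1))
      traj <- generate_water_box(spec)
      series <- dipole_series_from_trajectory(traj, attr(traj, "topology"))
      cache <<- list(spec = spec, traj = traj, series = series)
    }
    cache
  }
})

# hand-built two-water frame (no boundary crossings) in a 20 A cell, for
# conservation and assignment tests
two_water_frame <- function() {
  atoms <- rbind(
    c(5, 5, 5), c(5.96, 5, 5), c(5, 5.96, 5),           # O H H, molecule 1
    c(12, 12, 12), c(12.96, 12, 12), c(12, 12.96, 12))  # O H H, molecule 2
  centers <- rbind(
    c(5.48, 5, 5), c(5, 5.48, 5), c(4.8, 4.8, 5.2), c(4.8, 4.8, 4.8),
    c(12.48, 12, 12), c(12, 12.48, 12), c(11.8, 11.8, 12.2),
    c(11.8, 11.8, 11.8))
  traj <- md_trajectory(rep(c("O", "H", "H"), 2), as_frames(atoms),
                        as_frames(centers), cell_edge = 20, dt = 1)
  topo <- md_topology(rep(1:2, each = 3), c("water", "water"))
  list(traj = traj, topo = topo)
}
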