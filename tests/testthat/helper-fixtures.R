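# Shared fixtures, simulated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

rigid_sim <- function() cached("rigid_sim", simulate_trial(sim_params(n_strides = 6)))

rigid_analysis <- function() cached("rigid_analysis",
  suppressWarnings(analyze_trial(rigid_sim()$trial)))

wobble_sim <- function() cached("wobble_sim", {
  p <- sim_params(n_strides = 6)
  p$wobble <- list(mass_fraction = 0.15, freq_hz = 10, zeta = 0.4)
  simulate_trial(p)
})

wobble_analysis <- function() cached("wobble_analysis",
  suppressWarnings(analyze_trial(wobble_sim()$trial)))

# offset of the prepared (marker-clipped) force grid into the raw grid
grid_offset <- function(sim, analysis) {
  which(abs(sim$trial$forces$time - analysis$prepared$forces$time[1]) < 1e-9) - 1L
}

# static single-support fixture for the inverse-dynamics oracle:
# constant pose, constant force, COP a given distance ahead of the ankle
static_fixture <- function(n = 50, mass = 70, cop_ahead = 0.10,
                           foot_fraction = 0.0145) {
  g <- 9.81
  tt <- (seq_len(n) - 1) / 1000
  pose <- list(
    GT_R = c(0, 0.88), GT_L = c(0, 0.88),
    knee_R = c(0.03, 0.46), knee_L = c(0.03, 0.46),
    ankle_R = c(0, 0.08), ankle_L = c(0, 0.08),
    heel_R = c(-0.07, 0.02), heel_L = c(-0.07, 0.02),
    VM_R = c(0.15, 0.02), VM_L = c(0.15, 0.02),
    waist = c(0.06, 0.95), backwaist = c(-0.06, 0.95), neck = c(0, 1.5))
  coords <- lapply(pose, function(p) cbind(rep(p[1], n), rep(p[2], n)))
  markers <- marker_trajectories(tt, coords = coords)
  tab <- anthropometric_table()
  tab$mass_fraction[tab$segment == "foot"] <- foot_fraction
  segs <- build_segments(markers, mass, tab)
  forces <- force_series(tt, rep(0, n), rep(mass * g, n),
                         rep(cop_ahead, n))
  list(markers = markers, segs = segs, forces = forces, mass = mass,
       time = tt, n = n)
}
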