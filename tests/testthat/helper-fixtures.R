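# Shared, lazily computed simulation fixtures. The heavier runs (falling
# mass, air-puff sweep) are memoised so several test files can share them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fix_mesh <- function() memo("mesh", build_eye_mesh(eye_geometry_config()))

fix_materials <- function() memo("materials", eye_materials())

# pressurised baseline eye at 15 mmHg (from the reference geometry)
fix_state15 <- function() memo("state15",
  pressurize(fix_mesh(), fix_materials(), 15))

# zero-pressure recovery at 15 mmHg, with its re-inflated state
fix_zp15 <- function() memo("zp15",
  recover_zero_pressure(fix_mesh(), fix_materials(), 15))

# default falling-mass impact run
fix_mass_run <- function() memo("mass_run", {
  traj <- run_falling_mass(fix_state15(), falling_mass_config())
  list(traj = traj,
       ledger = work_ledger(traj, falling_mass_config()),
       energies = mass_energies(traj, falling_mass_config()))
})

# default air-puff run from the recovered zero-pressure configuration
fix_puff_run <- function() memo("puff_run", {
  st <- attr(fix_zp15(), "pressurized_state")
  traj <- run_air_puff(st, air_puff_profile())
  list(traj = traj, ledger = work_ledger(traj))
})

# the full sixteen-case sweep at the coarse desk-scale resolution
fix_sweep <- function() memo("sweep",
  run_sweep(sweep_cases(), air_puff_profile(), verbose = FALSE))

# a random small-strain deformation state (used by consistency checks)
random_small_F <- function() {
  diag(3) + matrix(stats::rnorm(9, 0, 0.02), 3, 3)
}
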