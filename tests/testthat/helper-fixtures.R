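# Shared fixtures, built once per test run and memoised. All fixtures are
# generated in code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

small_head <- function() memo("small_head", build_spherical_head(n_sources = 600))

small_electrodes <- function() memo("small_el", place_sensors(small_head(), "eeg32"))

small_optodes <- function() memo("small_opt", place_sensors(small_head(), "dot_regular"))

small_leadfield <- function() {
  memo("small_lf", compute_eeg_leadfield(small_head(), small_electrodes()))
}

small_jacobian <- function() {
  memo("small_jac", compute_dot_jacobian(small_head(), small_optodes()))
}

# a source space constructed at an arbitrary radius (for depth-decay checks)
shell_sources <- function(radius, n = 200) {
  dirs <- eegdot:::fibonacci_sphere(n)
  structure(
    list(positions = dirs * radius, normals = dirs, voxel_ids = seq_len(n),
         radius_mm = radius, spacing_mm = eegdot:::lattice_spacing(radius, n)),
    class = "eegdot_source_space"
  )
}

# the default two-source scenario, reconstructed at every timestep, with the
# projection-prior baseline: shared by the acceptance tests
acceptance_report <- function() {
  memo("acc_report", run_two_source_scenario(
    scenario_config(include_projection = TRUE), timesteps = "all"
  ))
}

bsm_cell <- function(tab, method, spot, time_ms) {
  tab[tab$method == method & tab$spot == spot & tab$time_ms == time_ms, ]
}
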