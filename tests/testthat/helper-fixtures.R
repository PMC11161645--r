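# Shared desk-scale fixtures. Everything is generated in code; heavier
# design runs are cached per session so several tests can share them.

test_config <- function(grid_n = 64, ...) optical_config(grid_n = grid_n, ...)

.fixture_env <- new.env(parent = emptyenv())

# memoised heavy fixtures (computed once per test run)
fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

tetrapod_fixture <- function() {
  fixture("tetrapod64", function() {
    optimize_tetrapod(
      test_config(),
      optimize_settings(iterations = 300, z_range = c(-20, 20), n_z = 20,
                        seed = 1),
      noise_model())
  })
}

edof_fixture <- function() {
  fixture("edof64", function() {
    optimize_edof(
      test_config(),
      optimize_settings(iterations = 300, z_range = c(-30, 30), n_z = 20,
                        seed = 1))
  })
}

# a fixed, mildly structured non-symmetric mask for gradient/Fisher tests
rough_mask <- function(config, seed = 42, sd = 0.5) {
  set.seed(seed)
  g <- make_pupil_grid(config)
  phase_mask(matrix(stats::rnorm(config$grid_n^2, sd = sd),
                    config$grid_n) * g$aperture, label = "rough")
}
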