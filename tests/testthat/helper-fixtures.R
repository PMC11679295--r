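# Shared small fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# 16x16x12 10 cm phantom with one off-centre source, solved tightly.
fixture_small_solve <- function() {
  if (is.null(.fixtures$small)) {
    spec <- phantom_spec(nx = 16, ny = 16, nz = 12)
    grid <- discretize_phantom(spec)
    sources <- source_spec(x = 0.062, y = 0.05, z = spec$height / 2,
                           radius = 0.008, height = 0.03, power = 5e4)
    S <- rasterize_sources(sources, grid)
    tf <- solve_steady_state(S, grid, tol = 1e-5, method = "sor")
    .fixtures$small <- list(spec = spec, grid = grid, sources = sources,
                            S = S, tf = tf)
  }
  .fixtures$small
}

# The micro-scale three-regime comparison (shared across acceptance blocks).
fixture_regime_trio <- function() {
  if (is.null(.fixtures$trio)) {
    .fixtures$trio <- run_regime_comparison(scale = "micro", seed = 1)
  }
  .fixtures$trio
}
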