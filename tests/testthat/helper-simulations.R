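# The three 24 h preset simulations are deterministic and reused by
# several test files; run each at most once per session.
.sim_cache <- new.env(parent = emptyenv())

cached_preset_run <- function(name) {
  if (is.null(.sim_cache[[name]])) {
    cfg <- configPreset(name)
    .sim_cache[[name]] <- runSimulation(cfg$chamber, cfg$layout)
  }
  .sim_cache[[name]]
}

# Small quick configuration with a genuine spotless margin (boundary bias
# present) for cheap solver property tests.
mini_bias_run <- function(duration = 2 * 3600, symmetry = "quadrant",
                          dt = 30, ...) {
  runSimulation(chamberGeometry(2.4e-3, 150e-6),
                spotArrayLayout(8, 8), duration = duration, dt = dt,
                symmetry = symmetry, ...)
}
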