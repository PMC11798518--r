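# shared fixtures: small detector, tiny scenes, convenience composition

tiny_det <- function(...) detector_model(n_channels = 1024, ...)

# composition of a matrix with traces folded in, reference element untouched
# at its registry value so that fit o simulate is an exact identity
comp_with_traces <- function(matrix_name, traces) {
  m <- mc_matrices()[[matrix_name]]
  comp <- m$composition * (1 - sum(traces))
  for (el in names(traces)) {
    comp[el] <- (if (is.na(comp[el])) 0 else comp[el]) + traces[[el]]
  }
  comp
}

tiny_scene <- function(preset = "benign", seed = 42, n = 16)
  build_scene(preset, seed = seed, nx = n, ny = n)
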