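# One shared noise-free synthetic bundle and pipeline run, generated once
# per test session and reused across test files.
.sim_cache <- new.env(parent = emptyenv())

noise_free_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    dir <- file.path(tempdir(), "enhscan-sim-nf")
    .sim_cache$sim <- generate_synthetic_data(dir,
                                              sim_config(noise = FALSE),
                                              seed = 7)
  }
  .sim_cache$sim
}

noise_free_scan <- function() {
  if (is.null(.sim_cache$scan)) {
    .sim_cache$scan <- run_enhancer_pipeline(
      noise_free_sim()$paths,
      pipeline_config(n_permutations = 100),
      profile = TRUE)
  }
  .sim_cache$scan
}
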