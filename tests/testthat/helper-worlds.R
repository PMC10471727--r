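# Shared small worlds, built once per test run.
.world_cache <- new.env(parent = emptyenv())

cached_world <- function(name, config) {
  if (is.null(.world_cache[[name]])) {
    .world_cache[[name]] <- simulate_world(config)
  }
  .world_cache[[name]]
}

small_world <- function() {
  cached_world("small", world_config(
    n_glaciers = 8, stations_per_glacier = 4, n_months = 12, seed = 42
  ))
}

noise_free_world <- function() {
  cached_world("noise_free", world_config(
    n_glaciers = 3, stations_per_glacier = 3, n_months = 6,
    residual_sd = 0, glacier_intercept_sd = 0, cloud_missing_prob = 0,
    seed = 7
  ))
}
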