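# One larger synthetic world shared across test files (built on first use).
.big_world_env <- new.env(parent = emptyenv())

big_world <- function() {
  if (is.null(.big_world_env$w)) {
    cfg <- world_config(n_providers = 10000, n_plans = 200, n_hospitals = 150,
                        seed = 2024)
    .big_world_env$w <- suppressWarnings(generate_world(cfg))
  }
  .big_world_env$w
}
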