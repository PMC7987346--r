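# Session cache shared across test files: full default sessions are costly to
# generate, so each (params-label, seed) pair is built once per test run.

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(seed, label = "default", params = generator_params()) {
  key <- paste0(label, "-", seed)
  if (is.null(.session_cache[[key]]))
    .session_cache[[key]] <- generate_session(params, seed = seed)
  .session_cache[[key]]
}
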