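# Shared, lazily computed fixtures. Simulations are deterministic, so caching
# them across test files only saves time, never changes results.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

dapa_pk_10mg <- function() cached("dapa_pk_10mg", {
  simulate_pk(build_pbpk_model(sglt_drug("dapagliflozin")), dose_regimen(10))
})
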