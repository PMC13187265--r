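## Shared fixtures: all synthetic, generated in code, memoized per test run.

small_config <- function(...) {
  synthetic_config(n_trees = 10, cores_per_tree = 1, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_proxies <- function() {
  cached("small_proxies", {
    cfg <- small_config()
    generate_proxies(cfg, generate_climate(cfg))
  })
}

zero_noise_proxies <- function() {
  cached("zero_noise_proxies", {
    cfg <- zero_noise_config(small_config())
    generate_proxies(cfg, generate_climate(cfg))
  })
}

default_climate <- function() {
  cached("default_climate", generate_climate(synthetic_config()))
}

## Exact modified negative exponential, for constructing pure-trend series.
negexp_curve <- function(age, amplitude = 0.8, decay = 0.02, asymptote = 0.25) {
  amplitude * exp(-decay * age) + asymptote
}

make_rwl <- function(..., first_year = 1821L) {
  series <- list(...)
  ns <- lengths(series)
  years <- seq.int(first_year, first_year + max(ns) - 1L)
  out <- as.data.frame(matrix(NA_real_, length(years), length(series)))
  names(out) <- names(series) %||% sprintf("S%02d", seq_along(series))
  rownames(out) <- years
  for (j in seq_along(series)) out[seq_len(ns[j]), j] <- series[[j]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
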