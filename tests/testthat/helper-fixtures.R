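# Shared fixtures and small oracles.  Heavier populations are memoized so
# several test files (and acceptance blocks) can share one generation pass.

jaccard <- function(a, b) sum(a & b) / sum(a | b)

clean_spec <- function(profile_type = "T2", condition = "CONTROL", ...) {
  nucleus_spec(profile_type, condition, noise_sd = 0, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# 100-nucleus condition populations at noise_sd = 5, analyzed end-to-end;
# shared by the treatment-ordering and correlation checks.
analyzed_condition_population <- function(condition, n = 100, seed_base = 500) {
  memo(paste0("cond_", condition, "_", n), function() {
    popn <- generate_population(
      condition_population(condition, n),
      labeled_fraction = default_labeling_fraction(condition),
      seed = seed_base + match(condition, conditions()),
      noise_sd = 5)
    res <- analyze_population(popn)
    list(popn = popn, per_nucleus = res$per_nucleus)
  })
}
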