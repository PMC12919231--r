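# Seeded draws through the global RNG stream; callers pass explicit seeds so
# every stochastic step is reproducible.
local_rng <- function(seed) {
  set.seed(as.integer(seed))
  list(sample = function(x, size) sample(x, size),
       resample_idx = function(n) sample.int(n, n, replace = TRUE),
       norm = function(n, sd = 1) rnorm(n, sd = sd))
}
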