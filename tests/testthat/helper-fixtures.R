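# Shared fixtures: small slabs and session bundles generated in code.

small_slab <- function(shape = c(10, 10, 22)) make_slab(shape)

# Idealized session: no noise anywhere, step gas traces, no ground-truth
# jitter. The estimation chain should be exact on this.
noiseless_session <- function(shape = c(10, 10, 22), sequence = "GE",
                              levels = c("+5", "+10"), seed = 5) {
  simulate_session(small_slab(shape), sequence = sequence, levels = levels,
                   tsnr = Inf, transition_tau = 0, gas_noise_sd = 0,
                   jitter_sd = 0, seed = seed)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual / expected - 1) < tol),
              label = sprintf("max rel dev %.3g < %.3g",
                              max(abs(actual / expected - 1)), tol))
}
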