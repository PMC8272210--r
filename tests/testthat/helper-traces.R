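# programmatic fixtures: exact forward-model traces used across the suite

make_cpmg_trace <- function(t2 = c(0.03, 0.3), p = c(0.2, 0.8), m0 = 100,
                            times = seq(0.002, 1.2, length.out = 200),
                            noise_sd = 0) {
  clean <- m0 * colSums(p * exp(-outer(1 / t2, times)))
  y <- clean + if (noise_sd > 0) rnorm(length(times), 0, noise_sd) else 0
  signal_trace(times, y, kind = "cpmg")
}

make_ir_trace <- function(t1 = c(0.06, 0.6), p = c(0.2, 0.8), m0 = 100,
                          times = exp(seq(log(0.005), log(4),
                                          length.out = 30)),
                          noise_sd = 0, alpha = 1) {
  clean <- m0 * (1 - 2 * alpha * colSums(p * exp(-outer(1 / t1, times))))
  y <- clean + if (noise_sd > 0) rnorm(length(times), 0, noise_sd) else 0
  signal_trace(times, y, kind = "inversion_recovery")
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * abs(expected)),
              label = sprintf("max rel diff %.3g vs tol %.3g",
                              max(abs(actual - expected) / abs(expected)),
                              tol))
}
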