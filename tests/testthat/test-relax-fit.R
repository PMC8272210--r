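# Multiexponential trace fitting, phase assignment, weighted rates

test_that("signal_trace validates its contract", {
  t <- seq(0.01, 1, length.out = 10)
  expect_s3_class(signal_trace(t, exp(-t), "cpmg"), "signal_trace")
  expect_error(signal_trace(t[1:5], exp(-t[1:5]), "cpmg"), "at least 8")
  expect_error(signal_trace(rev(t), exp(-t), "cpmg"), "increasing")
  expect_error(signal_trace(t, exp(-t)[1:5], "cpmg"), "equal length")
  expect_error(signal_trace(t, exp(-t), "cpmg", n_accumulations = 0), ">= 1")
})

test_that("noiseless monoexponential inversion recovery is recovered exactly", {
  tr <- make_ir_trace(t1 = 0.5, p = 1,
                      times = exp(seq(log(0.01), log(3), length.out = 20)))
  fit <- fit_inversion_recovery(tr, 1)
  expect_rel_equal(fit$components$time_constant_s, 0.5, 1e-6)
  expect_equal(fit$components$fraction, 1)
  expect_true(fit$converged)
})

test_that("noiseless biexponential IR and CPMG round-trip their parameters", {
  fit1 <- fit_inversion_recovery(make_ir_trace(t1 = c(0.06, 0.6),
                                               p = c(0.2, 0.8)), 2)
  expect_rel_equal(fit1$components$time_constant_s, c(0.06, 0.6), 1e-4)
  expect_rel_equal(fit1$components$fraction, c(0.2, 0.8), 1e-4)
  expect_rel_equal(fit1$m0, 100, 1e-6)

  fit2 <- fit_cpmg(make_cpmg_trace(t2 = c(0.03, 0.3), p = c(0.2, 0.8)), 2)
  expect_rel_equal(fit2$components$time_constant_s, c(0.03, 0.3), 1e-4)
  expect_rel_equal(fit2$components$fraction, c(0.2, 0.8), 1e-4)
})

test_that("noiseless recovery holds across the admissible parameter box", {
  # property: T in [10 ms, 2 s], p in [0.1, 0.9], T ratio >= 3
  set.seed(21)
  for (i in 1:8) {
    t_short <- runif(1, 0.01, 0.4)
    t_long <- t_short * runif(1, 3, 20)
    p <- runif(1, 0.1, 0.9)
    times_ir <- exp(seq(log(t_short / 10), log(4 * t_long),
                        length.out = 32))
    fit1 <- fit_inversion_recovery(
      make_ir_trace(t1 = c(t_short, t_long), p = c(p, 1 - p),
                    times = times_ir), 2)
    expect_rel_equal(fit1$components$time_constant_s,
                     c(t_short, t_long), 1e-3)
    expect_rel_equal(fit1$components$fraction, c(p, 1 - p), 1e-3)
    times_cp <- seq(t_short / 10, 4 * t_long, length.out = 400)
    fit2 <- fit_cpmg(
      make_cpmg_trace(t2 = c(t_short, t_long), p = c(p, 1 - p),
                      times = times_cp), 2)
    expect_rel_equal(fit2$components$time_constant_s,
                     c(t_short, t_long), 1e-3)
    # fractions always sum to 1 and components come back sorted
    expect_equal(sum(fit1$components$fraction), 1, tolerance = 1e-9)
    expect_equal(sum(fit2$components$fraction), 1, tolerance = 1e-9)
    expect_false(is.unsorted(fit2$components$time_constant_s))
  }
})

test_that("fits under seeded noise stay close to truth", {
  # repeated-fit check at SNR 200: typical (median) errors stay within
  # 5% on time constants and 0.05 on fractions
  set.seed(17)
  reps <- replicate(15, {
    tr <- make_cpmg_trace(noise_sd = 100 / 200)
    fit <- suppressWarnings(fit_cpmg(tr, 2))
    c(max(abs(fit$components$time_constant_s - c(0.03, 0.3)) /
            c(0.03, 0.3)),
      max(abs(fit$components$fraction - c(0.2, 0.8))))
  })
  expect_lt(median(reps[1, ]), 0.05)
  expect_lt(median(reps[2, ]), 0.05)
})

test_that("fit preconditions are enforced", {
  t8 <- seq(0.01, 1, length.out = 8)
  tr8 <- signal_trace(t8, 100 * (1 - 2 * exp(-t8 / 0.3)),
                      "inversion_recovery")
  expect_error(fit_inversion_recovery(tr8, 3), "at least 12")
  expect_error(fit_inversion_recovery(make_cpmg_trace(), 2), "kind")
  expect_error(fit_cpmg(make_ir_trace(), 2), "kind")
  flat <- signal_trace(t8, rep(5, 8), "cpmg")
  expect_error(fit_cpmg(flat, 1), "non-decaying")
})

test_that("component-count selection prefers the simplest adequate model", {
  t <- seq(0.002, 1.2, length.out = 200)
  mono <- make_cpmg_trace(t2 = 0.1, p = 1, times = t)
  expect_equal(select_n_components(mono, 3), 1L)
  # well-separated pair (T ratio 10) is detected
  bi <- make_cpmg_trace(t2 = c(0.03, 0.3), p = c(0.3, 0.7), times = t)
  expect_equal(select_n_components(bi, 3), 2L)
  # a 5% split in time constants is unresolvable against measurement
  # noise: the criterion collapses it to one pool
  set.seed(6)
  near <- make_cpmg_trace(t2 = c(0.1, 0.105), p = c(0.5, 0.5), times = t,
                          noise_sd = 100 / 200)
  expect_equal(suppressWarnings(select_n_components(near, 2)), 1L)
})

test_that("observed_rate is the fraction-weighted mean rate", {
  expect_equal(observed_rate(relaxation_components(2, 1, "T1")), 0.5)
  expect_equal(observed_rate(
    relaxation_components(c(1, 1 + 1e-12), c(0.5, 0.5), "T2")), 1,
    tolerance = 1e-9)
  expect_equal(observed_rate(
    relaxation_components(c(0.1, 1), c(0.25, 0.75), "T1")), 3.25)
  mixed <- rbind(relaxation_components(0.1, 1, "T1"),
                 relaxation_components(0.5, 1, "T2"))
  mixed$fraction <- c(0.5, 0.5)
  expect_error(observed_rate(mixed), "mix")
})

test_that("phase assignment labels short components oil, long water", {
  fit1 <- fit_inversion_recovery(make_ir_trace(t1 = c(0.06, 0.6)), 2)
  fit2 <- fit_cpmg(make_cpmg_trace(t2 = c(0.03, 0.3)), 2)
  ph <- assign_phases(fit1, fit2)
  expect_rel_equal(ph$oil$time_constant_s, c(0.06, 0.03), 1e-3)
  expect_rel_equal(ph$water$time_constant_s, c(0.6, 0.3), 1e-3)
  expect_true(all(ph$oil$phase == "oil"))
  expect_true(all(ph$water$phase == "water"))
  # 1-component reports cannot be assigned
  mono <- fit_cpmg(make_cpmg_trace(t2 = 0.1, p = 1), 1)
  expect_error(assign_phases(fit1, mono), "exactly 2")
  # equal time constants are an unbreakable tie
  tie <- fit2
  tie$components$time_constant_s <- c(0.3, 0.3)
  expect_error(assign_phases(fit1, tie), "tie")
})

test_that("trace and fit-report CSV I/O round-trips", {
  tr <- make_cpmg_trace()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path, kind = "cpmg")
  expect_equal(back$times, tr$times)
  expect_equal(back$amplitudes, tr$amplitudes)
  fit <- fit_cpmg(tr, 2)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_fit_report_csv(fit, path2)
  d <- read.csv(path2)
  expect_named(d, c("component", "which", "time_constant_s", "fraction",
                    "phase"))
  expect_equal(nrow(d), 2)
})
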