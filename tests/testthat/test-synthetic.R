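# Ground-truth emulsion simulator

test_that("phase and experiment specs validate their physics", {
  expect_error(phase_spec("oil", delta_ea = 0, tau_0 = 1e-12,
                          dipolar_prefactor_K = 1e10,
                          proton_fraction = 0.2))
  expect_error(phase_spec("oil", delta_ea = 20, tau_0 = 1e-8,
                          dipolar_prefactor_K = 1e10,
                          proton_fraction = 0.2))
  ph <- list(
    phase_spec("oil", 25, 5.4e-13, 1.2e10, 0.3),
    phase_spec("water", 15, 1.1e-11, 1.5e9, 0.3)
  )
  expect_error(emulsion_sim_spec(ph), "sum to 1")
  expect_error(emulsion_preset(temperatures_c = c(-5, 20)), "\\[0, 90\\]")
})

test_that("the Arrhenius forward law behaves as stated", {
  oil <- phase_spec("oil", 20, 1e-12, 1e10, 0.2)
  # hand evaluation at 300 K
  expect_rel_equal(tau_c_at_temperature(oil, 300),
                   1e-12 * exp(20000 / (8.314462618 * 300)), 1e-12)
  # monotone decreasing with temperature for any positive barrier
  expect_gt(tau_c_at_temperature(oil, 273), tau_c_at_temperature(oil, 363))
  # zero barrier is not representable; the smallest admissible barrier
  # still shows curvature
  tiny <- phase_spec("oil", 1e-6, 1e-12, 1e10, 0.2)
  expect_rel_equal(tau_c_at_temperature(tiny, 300), 1e-12, 1e-6)
})

test_that("true T1/T2 honor the BPP ordering at every temperature", {
  spec <- emulsion_preset(seed = 3)
  ctx <- bpp_context(spec$larmor_frequency_hz)
  for (tc in seq(0, 90, by = 10)) {
    tk <- celsius_to_kelvin(tc)
    oil <- relaxation_times_at_temperature(spec$phases$oil, tk, ctx)
    water <- relaxation_times_at_temperature(spec$phases$water, tk, ctx)
    expect_gte(oil$t1, oil$t2)
    expect_gte(water$t1, water$t2)
    # long (water) components exceed short (oil) components throughout
    expect_gt(water$t2, oil$t2)
    expect_gt(water$t1, oil$t1)
  }
  # extreme narrowing: T1 = T2 within 0.1%
  fast <- phase_spec("water", 5, 1e-13, 1e9, 0.5)
  rt <- relaxation_times_at_temperature(fast, 363, ctx)
  expect_rel_equal(rt$t1, rt$t2, 1e-3)
})

test_that("traces are seeded, reproducible, and exact when noiseless", {
  spec <- emulsion_preset(snr = Inf, seed = 5)
  tr <- simulate_ir_trace(spec, 20)
  truth <- subset(generate_dataset(spec)$ground_truth, temperature_c == 20)
  model <- 100 * (1 - 2 * (truth$fraction[1] * exp(-tr$times / truth$t1_s[1]) +
                           truth$fraction[2] * exp(-tr$times / truth$t1_s[2])))
  expect_equal(tr$amplitudes, model, tolerance = 1e-12)

  noisy <- emulsion_preset(snr = 100, seed = 5)
  a <- simulate_cpmg_trace(noisy, 20)
  b <- simulate_cpmg_trace(noisy, 20)
  expect_identical(a$amplitudes, b$amplitudes)  # same seed, same trace
  other <- simulate_cpmg_trace(emulsion_preset(snr = 100, seed = 6), 20)
  expect_false(identical(a$amplitudes, other$amplitudes))
})

test_that("datasets are bit-identical under identical spec and seed", {
  d1 <- generate_dataset(emulsion_preset(snr = 150, seed = 9))
  d2 <- generate_dataset(emulsion_preset(snr = 150, seed = 9))
  expect_identical(d1$ground_truth, d2$ground_truth)
  for (k in names(d1$traces)) {
    expect_identical(d1$traces[[k]]$ir$amplitudes,
                     d2$traces[[k]]$ir$amplitudes)
    expect_identical(d1$traces[[k]]$cpmg$amplitudes,
                     d2$traces[[k]]$cpmg$amplitudes)
  }
})

test_that("the sidecar is self-consistent with the BPP forward model", {
  spec <- emulsion_preset(seed = 2)
  ds <- generate_dataset(spec)
  gt <- ds$ground_truth
  # 10 temperatures -> 20 traces and 20 ground-truth rows (2 phases x 10)
  expect_equal(length(ds$traces), 10)
  expect_equal(nrow(gt), 20)
  for (i in seq_len(nrow(gt))) {
    ph <- spec$phases[[gt$phase[i]]]
    ctx <- bpp_context(spec$larmor_frequency_hz,
                       dipolar_prefactor_K = ph$dipolar_prefactor_K)
    expect_rel_equal(gt$t1_s[i], 1 / r1_bpp(gt$tau_c_s[i], ctx), 1e-12)
    expect_rel_equal(gt$t2_s[i], 1 / r2_bpp(gt$tau_c_s[i], ctx), 1e-12)
    # sidecar tau_c satisfies the Arrhenius law exactly
    expect_rel_equal(
      gt$tau_c_s[i],
      tau_c_at_temperature(ph, celsius_to_kelvin(gt$temperature_c[i])),
      1e-12)
  }
})

test_that("auto timing grids span [0.1 min(T), 4 max(T)] of the truth", {
  spec <- emulsion_preset(snr = Inf, seed = 4)
  ctx <- bpp_context(spec$larmor_frequency_hz)
  for (tc in c(0, 45, 90)) {
    tk <- celsius_to_kelvin(tc)
    rt <- lapply(spec$phases, relaxation_times_at_temperature, tk, ctx)
    t1 <- vapply(rt, `[[`, numeric(1), "t1")
    t2 <- vapply(rt, `[[`, numeric(1), "t2")
    ir <- simulate_ir_trace(spec, tc)
    expect_lte(min(ir$times), 0.1 * min(t1) * (1 + 1e-9))
    expect_gte(max(ir$times), 4 * max(t1) * (1 - 1e-9))
    cp <- simulate_cpmg_trace(spec, tc)
    expect_lte(min(cp$times), 0.1 * min(t2) * (1 + 1e-9))
    expect_gte(max(cp$times), 4 * max(t2) * (1 - 1e-9))
  }
})

test_that("simulated traces close the loop with the fitters", {
  spec <- emulsion_preset(snr = 200, seed = 12)
  truth <- subset(generate_dataset(spec)$ground_truth, temperature_c == 30)
  fit1 <- fit_inversion_recovery(simulate_ir_trace(spec, 30), 2)
  expect_rel_equal(sort(fit1$components$time_constant_s),
                   sort(truth$t1_s), 0.05)
  fit2 <- fit_cpmg(simulate_cpmg_trace(spec, 30), 2)
  expect_rel_equal(sort(fit2$components$time_constant_s),
                   sort(truth$t2_s), 0.05)
})

test_that("dataset export writes traces, sidecar and manifest", {
  skip_if_not_installed("jsonlite")
  spec <- emulsion_preset(snr = Inf, seed = 8,
                          temperatures_c = c(10, 50, 90))
  ds <- generate_dataset(spec)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  files <- list.files(dir)
  expect_length(grep("^ir_", files), 3)
  expect_length(grep("^cpmg_", files), 3)
  expect_true("ground_truth.csv" %in% files)
  expect_true("manifest.json" %in% files)
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt), 6)
})
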