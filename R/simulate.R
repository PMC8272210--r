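# Ground-truth emulsion simulator: two non-exchanging proton pools (oil and
# water), each with Arrhenius-activated rotational correlation times and
# BPP-governed relaxation rates, sampled by inversion-recovery and CPMG
# pulse sequences with accumulation-averaged Gaussian noise.

#' Specify one proton pool (phase) of a simulated emulsion
#'
#' @param phase `"oil"` or `"water"`.
#' @param delta_ea Activation energy of rotational motion, kJ/mol, in
#'   `(0, 60]`.
#' @param tau_0 Arrhenius pre-exponential correlation time, s, in
#'   `[1e-14, 1e-9]`.
#' @param dipolar_prefactor_K Effective dipolar constant K for this pool,
#'   s^-2 (> 0). Sets the absolute scale of the pool's relaxation rates.
#' @param proton_fraction Fraction of the sample's protons in this pool,
#'   in `(0, 1)`.
#' @return An object of class `phase_spec`.
#' @export
phase_spec <- function(phase, delta_ea, tau_0, dipolar_prefactor_K,
                       proton_fraction) {
  phase <- match.arg(phase, c("oil", "water"))
  stopifnot(is.numeric(delta_ea), delta_ea > 0, delta_ea <= 60)
  stopifnot(is.numeric(tau_0), tau_0 >= 1e-14, tau_0 <= 1e-9)
  stopifnot(is.numeric(dipolar_prefactor_K), dipolar_prefactor_K > 0)
  stopifnot(is.numeric(proton_fraction), proton_fraction > 0,
            proton_fraction < 1)
  structure(
    list(phase = phase, delta_ea = delta_ea, tau_0 = tau_0,
         dipolar_prefactor_K = dipolar_prefactor_K,
         proton_fraction = proton_fraction),
    class = "phase_spec"
  )
}

#' Correlation time of a pool at a temperature
#'
#' Forward Arrhenius law:
#' \eqn{\tau_c = \tau_0 \exp(\Delta E_a / (R T))}.
#'
#' @param phase A [phase_spec()].
#' @param temperature_k Absolute temperature(s) in kelvin (> 0).
#' @return Correlation time(s) in seconds.
#' @export
tau_c_at_temperature <- function(phase, temperature_k) {
  stopifnot(inherits(phase, "phase_spec"), all(temperature_k > 0))
  phase$tau_0 * exp(phase$delta_ea * 1000 /
                      (.constants$r_gas * temperature_k))
}

#' True T1 and T2 of a pool at a temperature
#'
#' Composes the Arrhenius law with the BPP rates:
#' `T1 = 1/r1_bpp(tau_c)`, `T2 = 1/r2_bpp(tau_c)` at this pool's
#' correlation time. `T1 >= T2` always, with equality in the
#' extreme-narrowing limit.
#'
#' @param phase A [phase_spec()].
#' @param temperature_k Absolute temperature in kelvin.
#' @param ctx A [bpp_context()]; this pool's own dipolar prefactor is used,
#'   only the frequency is taken from `ctx`.
#' @return A named list `list(t1, t2, tau_c)` in seconds.
#' @export
relaxation_times_at_temperature <- function(phase, temperature_k, ctx) {
  tau <- tau_c_at_temperature(phase, temperature_k)
  pool_ctx <- bpp_context(ctx$larmor_frequency_hz,
                          dipolar_prefactor_K = phase$dipolar_prefactor_K)
  list(t1 = 1 / r1_bpp(tau, pool_ctx), t2 = 1 / r2_bpp(tau, pool_ctx),
       tau_c = tau)
}

#' Specify a simulated emulsion relaxometry experiment
#'
#' Defaults emulate the measurement protocol of a 15 MHz low-field
#' instrument on starch-stabilized oil-in-water emulsions: temperatures
#' spanning 0-90 °C, five accumulations per sequence, and pulse-sequence
#' timing grids auto-adjusted to the true time constants at each
#' temperature (inversion-recovery delays log-spaced over
#' `[0.1 min(T1), 4 max(T1)]`; CPMG echo spacing `0.1 min(T2)` out to
#' `4 max(T2)`, capped at 1000 echoes).
#'
#' @param phases List of two [phase_spec()]s (one oil, one water) whose
#'   proton fractions sum to 1.
#' @param temperatures_c Measurement temperatures in °C, within `[0, 90]`.
#' @param larmor_frequency_hz Spectrometer frequency (Hz), default 15 MHz.
#' @param ir_delays Optional fixed inversion-recovery delay grid (s); if
#'   `NULL`, chosen per temperature by the adequacy rule above.
#' @param cpmg_echo_times Optional fixed CPMG echo-time grid (s); if
#'   `NULL`, chosen per temperature.
#' @param snr Amplitude signal-to-noise ratio: equilibrium magnetization
#'   over single-shot noise sd. `Inf` for noiseless traces.
#' @param n_accumulations Accumulated scans per trace (noise sd shrinks by
#'   its square root); default 5.
#' @param seed Integer RNG seed; every trace drawn from the spec is a
#'   deterministic function of (seed, temperature, sequence).
#' @param n_ir_delays Number of inversion-recovery delays when auto-chosen.
#' @param temperature_jitter_c Optional uniform temperature error half-width
#'   in °C (e.g. 0.5 to emulate ±0.5 °C regulation); 0 disables it.
#' @param metadata Named list of condition labels (`starch`,
#'   `concentration_g_per_g`, `fat`); carried through to output tables,
#'   never used numerically.
#' @return An object of class `emulsion_sim_spec`.
#' @seealso [emulsion_preset()] for a ready-made two-phase parameterization.
#' @export
emulsion_sim_spec <- function(phases,
                              temperatures_c = seq(0, 90, length.out = 10),
                              larmor_frequency_hz = 15e6,
                              ir_delays = NULL, cpmg_echo_times = NULL,
                              snr = 200, n_accumulations = 5, seed = 1,
                              n_ir_delays = 32,
                              temperature_jitter_c = 0,
                              metadata = list(starch = "synthetic",
                                              concentration_g_per_g = 0.12,
                                              fat = "synthetic")) {
  stopifnot(is.list(phases), length(phases) == 2,
            all(vapply(phases, inherits, logical(1), "phase_spec")))
  labels <- vapply(phases, `[[`, character(1), "phase")
  if (!setequal(labels, c("oil", "water")))
    stop("phases must contain exactly one oil and one water pool")
  fr <- sum(vapply(phases, `[[`, numeric(1), "proton_fraction"))
  if (abs(fr - 1) > 1e-9)
    stop("proton fractions across phases must sum to 1 (got ", fr, ")")
  stopifnot(is.numeric(temperatures_c), length(temperatures_c) >= 1)
  if (any(temperatures_c < 0 | temperatures_c > 90))
    stop("temperatures must lie within [0, 90] degrees Celsius")
  stopifnot(is.numeric(snr), snr > 0)
  stopifnot(n_accumulations >= 1, n_ir_delays >= 8)
  names(phases) <- labels
  structure(
    list(phases = phases, temperatures_c = as.numeric(temperatures_c),
         larmor_frequency_hz = larmor_frequency_hz,
         ir_delays = ir_delays, cpmg_echo_times = cpmg_echo_times,
         snr = snr, n_accumulations = as.integer(n_accumulations),
         seed = as.integer(seed), n_ir_delays = as.integer(n_ir_delays),
         temperature_jitter_c = temperature_jitter_c,
         metadata = metadata),
    class = "emulsion_sim_spec"
  )
}

#' @export
print.emulsion_sim_spec <- function(x, ...) {
  cat("emulsion_sim_spec\n")
  for (ph in x$phases)
    cat(sprintf(
      "  %-5s: delta_Ea %.1f kJ/mol, tau_0 %.3g s, K %.3g s^-2, p %.2f\n",
      ph$phase, ph$delta_ea, ph$tau_0, ph$dipolar_prefactor_K,
      ph$proton_fraction))
  cat(sprintf("  %d temperatures in [%.1f, %.1f] C, f = %.3g MHz\n",
              length(x$temperatures_c), min(x$temperatures_c),
              max(x$temperatures_c), x$larmor_frequency_hz / 1e6))
  cat(sprintf("  snr %s, %d accumulation(s), seed %d\n",
              format(x$snr), x$n_accumulations, x$seed))
  invisible(x)
}

#' Paper-like two-phase emulsion preset
#'
#' A ready-made oil-in-water parameterization: oil pool with activation
#' energy 25 kJ/mol and water pool with 15 kJ/mol, pre-exponentials and
#' dipolar prefactors chosen so that over 0-90 °C the oil T2 sits in the
#' tens of milliseconds and the water T2 in the hundreds of milliseconds,
#' the T1 components of the two pools stay resolvable (ratio >= 3), and
#' the correlation times remain identifiable from the R2/R1 ratio
#' (\eqn{\omega\tau_c \gtrsim 0.15} even at 90 °C). Proton fractions are
#' 0.2 oil / 0.8 water, matching a 1/4 oil-to-water composition. The
#' preset is an approximate regime, not ground truth for any measured
#' sample.
#'
#' @param delta_ea_oil,delta_ea_water Activation energies (kJ/mol).
#' @param ... Passed on to [emulsion_sim_spec()] (temperatures, snr, seed,
#'   ...).
#' @return An `emulsion_sim_spec`.
#' @examples
#' spec <- emulsion_preset(snr = Inf, seed = 7)
#' @export
emulsion_preset <- function(delta_ea_oil = 25, delta_ea_water = 15, ...) {
  phases <- list(
    phase_spec("oil", delta_ea = delta_ea_oil, tau_0 = 5.4e-13,
               dipolar_prefactor_K = 1.2e10, proton_fraction = 0.2),
    phase_spec("water", delta_ea = delta_ea_water, tau_0 = 1.1e-11,
               dipolar_prefactor_K = 1.5e9, proton_fraction = 0.8)
  )
  emulsion_sim_spec(phases = phases, ...)
}

# run expr with a local deterministic RNG stream, restoring global state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# per-trace substream seed: deterministic in (spec seed, temperature, kind),
# kept below 2^31
.trace_seed <- function(spec, temperature_c, kind) {
  k <- if (kind == "inversion_recovery") 1L else 2L
  (abs(spec$seed) * 7919 + round(temperature_c * 100) * 13 + k) %% 2147483629L
}

.spec_truth <- function(spec, temperature_c) {
  ctx <- bpp_context(spec$larmor_frequency_hz)
  tk <- celsius_to_kelvin(temperature_c)
  rows <- lapply(spec$phases, function(ph) {
    rt <- relaxation_times_at_temperature(ph, tk, ctx)
    data.frame(phase = ph$phase, fraction = ph$proton_fraction,
               tau_c_s = rt$tau_c, t1_s = rt$t1, t2_s = rt$t2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# pulse-sequence timing grids adjusted to the true time constants, spanning
# [0.1 min(T), 4 max(T)]
.ir_grid <- function(spec, truth) {
  if (!is.null(spec$ir_delays)) return(spec$ir_delays)
  exp(seq(log(0.1 * min(truth$t1_s)), log(4 * max(truth$t1_s)),
          length.out = spec$n_ir_delays))
}

.cpmg_grid <- function(spec, truth) {
  if (!is.null(spec$cpmg_echo_times)) return(spec$cpmg_echo_times)
  n <- min(1000L, as.integer(ceiling(40 * max(truth$t2_s) /
                                       min(truth$t2_s))))
  te <- 4 * max(truth$t2_s) / n
  te * seq_len(n)
}

.noise_sd <- function(spec, m0) {
  if (!is.finite(spec$snr)) return(0)
  m0 / (spec$snr * sqrt(spec$n_accumulations))
}

.sim_temperature <- function(spec, temperature_c) {
  if (spec$temperature_jitter_c > 0)
    temperature_c + stats::runif(1, -spec$temperature_jitter_c,
                                 spec$temperature_jitter_c)
  else temperature_c
}

#' Simulate one inversion-recovery trace
#'
#' \eqn{M(\tau) = M_0[1 - 2\sum_{phases} p\, e^{-\tau/T_1}]} plus additive
#' Gaussian noise of sd \eqn{M_0/(\mathrm{snr}\sqrt{n_{acc}})}. The noise
#' stream is a deterministic function of (spec seed, temperature,
#' sequence), so the same spec always yields the same trace.
#'
#' @param spec An [emulsion_sim_spec()].
#' @param temperature_c Temperature in °C (one of the interesting range;
#'   need not be in `spec$temperatures_c`).
#' @param m0 Equilibrium magnetization amplitude (arbitrary units).
#' @return A [signal_trace()] of kind `"inversion_recovery"`.
#' @export
simulate_ir_trace <- function(spec, temperature_c, m0 = 100) {
  stopifnot(inherits(spec, "emulsion_sim_spec"))
  .with_seed(.trace_seed(spec, temperature_c, "inversion_recovery"), {
    t_eff <- .sim_temperature(spec, temperature_c)
    truth <- .spec_truth(spec, t_eff)
    delays <- .ir_grid(spec, truth)
    if (any(diff(delays) <= 0)) stop("ir_delays must be increasing")
    clean <- m0 * (1 - 2 * rowSums(vapply(
      seq_len(nrow(truth)),
      function(i) truth$fraction[i] * exp(-delays / truth$t1_s[i]),
      numeric(length(delays)))))
    sd <- .noise_sd(spec, m0)
    amp <- clean + if (sd > 0) stats::rnorm(length(delays), 0, sd) else 0
    signal_trace(delays, amp, kind = "inversion_recovery",
                 n_accumulations = spec$n_accumulations,
                 noise_sigma = if (sd > 0) sd else NULL)
  })
}

#' Simulate one CPMG echo train
#'
#' \eqn{A(t) = M_0\sum_{phases} p\, e^{-t/T_2}} plus the same seeded
#' Gaussian noise model as [simulate_ir_trace()].
#'
#' @inheritParams simulate_ir_trace
#' @return A [signal_trace()] of kind `"cpmg"`.
#' @export
simulate_cpmg_trace <- function(spec, temperature_c, m0 = 100) {
  stopifnot(inherits(spec, "emulsion_sim_spec"))
  .with_seed(.trace_seed(spec, temperature_c, "cpmg"), {
    t_eff <- .sim_temperature(spec, temperature_c)
    truth <- .spec_truth(spec, t_eff)
    echoes <- .cpmg_grid(spec, truth)
    if (any(diff(echoes) <= 0)) stop("cpmg_echo_times must be increasing")
    clean <- m0 * rowSums(vapply(
      seq_len(nrow(truth)),
      function(i) truth$fraction[i] * exp(-echoes / truth$t2_s[i]),
      numeric(length(echoes))))
    sd <- .noise_sd(spec, m0)
    amp <- clean + if (sd > 0) stats::rnorm(length(echoes), 0, sd) else 0
    signal_trace(echoes, amp, kind = "cpmg",
                 n_accumulations = spec$n_accumulations,
                 noise_sigma = if (sd > 0) sd else NULL)
  })
}

#' Generate a full temperature-series emulsion dataset
#'
#' One inversion-recovery and one CPMG trace per temperature, plus a
#' ground-truth sidecar recording the true correlation time, T1, T2 and
#' proton fraction of each phase at each temperature (for recovery
#' scoring). Identical spec (including seed) always yields a bit-identical
#' dataset.
#'
#' @param spec An [emulsion_sim_spec()].
#' @param m0 Equilibrium magnetization amplitude.
#' @return An object of class `emulsion_dataset`: a list with `spec`,
#'   `traces` (per temperature: `$ir`, `$cpmg`) and `ground_truth` (data
#'   frame with columns `temperature_c`, `phase`, `fraction`, `tau_c_s`,
#'   `t1_s`, `t2_s`).
#' @export
generate_dataset <- function(spec, m0 = 100) {
  stopifnot(inherits(spec, "emulsion_sim_spec"))
  traces <- list()
  gt <- list()
  for (tc in spec$temperatures_c) {
    key <- sprintf("%.2fC", tc)
    traces[[key]] <- list(
      temperature_c = tc,
      ir = simulate_ir_trace(spec, tc, m0),
      cpmg = simulate_cpmg_trace(spec, tc, m0)
    )
    truth <- .spec_truth(spec, tc)
    gt[[key]] <- cbind(temperature_c = tc, truth)
  }
  gt <- do.call(rbind, gt)
  rownames(gt) <- NULL
  structure(list(spec = spec, traces = traces, ground_truth = gt),
            class = "emulsion_dataset")
}

#' @export
print.emulsion_dataset <- function(x, ...) {
  cat(sprintf(
    "emulsion_dataset: %d temperature(s), %d traces, seed %d\n",
    length(x$traces), 2 * length(x$traces), x$spec$seed))
  invisible(x)
}

#' Write a dataset to a directory of CSV files
#'
#' Writes one trace CSV per (temperature, sequence), the ground-truth
#' sidecar CSV, and a JSON manifest of the generating spec and seed.
#'
#' @param dataset An `emulsion_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "emulsion_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(dataset$traces)) {
    entry <- dataset$traces[[key]]
    write_trace_csv(entry$ir, file.path(dir, paste0("ir_", key, ".csv")))
    write_trace_csv(entry$cpmg, file.path(dir, paste0("cpmg_", key, ".csv")))
  }
  utils::write.csv(dataset$ground_truth,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    spec <- dataset$spec
    manifest <- list(
      phases = lapply(spec$phases, function(p) p[names(p)]),
      temperatures_c = spec$temperatures_c,
      larmor_frequency_hz = spec$larmor_frequency_hz,
      snr = if (is.finite(spec$snr)) spec$snr else "Inf",
      n_accumulations = spec$n_accumulations,
      seed = spec$seed,
      metadata = spec$metadata
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
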