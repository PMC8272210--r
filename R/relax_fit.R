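# Multiexponential analysis of inversion-recovery (T1) and CPMG (T2) traces.
#
# The fits use variable projection: for a candidate set of time constants the
# amplitudes enter the model linearly and are solved exactly by least
# squares, so the nonlinear search runs only over the (log) time constants.
# Initialization is a deterministic log-spaced grid search, which makes the
# whole procedure reproducible; refinement uses stats::nlminb under bounds.

#' Construct a relaxation signal trace
#'
#' Container for one acquired (or simulated) decay/recovery curve: an
#' inversion-recovery magnetization curve (180-tau-90, samples T1) or a CPMG
#' echo train (90-tau-180n, samples T2).
#'
#' @param times Acquisition delays (inversion recovery) or echo times (CPMG)
#'   in seconds; strictly increasing, at least 8 points.
#' @param amplitudes Signal amplitudes in arbitrary units, same length.
#' @param kind `"inversion_recovery"` or `"cpmg"`.
#' @param n_accumulations Number of accumulated scans averaged into the
#'   trace (>= 1).
#' @param noise_sigma Optional known/estimated amplitude noise standard
#'   deviation (scalar, or one value per point) used for inverse-variance
#'   weighting of the fit.
#' @return An object of class `signal_trace`.
#' @examples
#' tr <- signal_trace(seq(0.01, 2, length.out = 20),
#'                    100 * exp(-seq(0.01, 2, length.out = 20) / 0.3),
#'                    kind = "cpmg")
#' @export
signal_trace <- function(times, amplitudes,
                         kind = c("inversion_recovery", "cpmg"),
                         n_accumulations = 1, noise_sigma = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(times), is.numeric(amplitudes))
  if (length(times) != length(amplitudes))
    stop("times and amplitudes must have equal length")
  if (length(times) < 8)
    stop("a signal trace needs at least 8 points, got ", length(times))
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (!is.numeric(n_accumulations) || n_accumulations < 1)
    stop("n_accumulations must be >= 1")
  if (!is.null(noise_sigma)) {
    stopifnot(is.numeric(noise_sigma), all(noise_sigma > 0))
    if (!length(noise_sigma) %in% c(1L, length(times)))
      stop("noise_sigma must be scalar or one value per point")
  }
  structure(
    list(times = as.numeric(times), amplitudes = as.numeric(amplitudes),
         kind = kind, n_accumulations = as.integer(n_accumulations),
         noise_sigma = noise_sigma),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("signal_trace (%s): %d points, t in [%.4g, %.4g] s, %d acc.\n",
              x$kind, length(x$times), min(x$times), max(x$times),
              x$n_accumulations))
  invisible(x)
}

#' Construct a relaxation component table
#'
#' One discrete exponential proton pool per row: its time constant (T1 or
#' T2), its proton fraction, and its phase label.
#'
#' @param time_constant_s Time constants in seconds (> 0).
#' @param fraction Proton fractions in `[0, 1]`, summing to 1.
#' @param which `"T1"` or `"T2"` (recycled).
#' @param phase `"oil"`, `"water"` or `"unassigned"` (recycled).
#' @return A data frame with columns `which`, `time_constant_s`, `fraction`,
#'   `phase`, sorted ascending by time constant.
#' @examples
#' relaxation_components(c(0.03, 0.3), c(0.2, 0.8), which = "T2")
#' @export
relaxation_components <- function(time_constant_s, fraction,
                                  which = "T2", phase = "unassigned") {
  stopifnot(all(time_constant_s > 0), all(fraction >= 0), all(fraction <= 1))
  if (abs(sum(fraction) - 1) > 1e-9)
    stop("component fractions must sum to 1 (got ", sum(fraction), ")")
  which <- match.arg(which, c("T1", "T2"))
  phase <- rep_len(match.arg(phase, c("oil", "water", "unassigned"),
                             several.ok = FALSE), length(time_constant_s))
  out <- data.frame(which = which, time_constant_s = time_constant_s,
                    fraction = fraction, phase = phase,
                    stringsAsFactors = FALSE)
  out[order(out$time_constant_s), , drop = FALSE]
}

# design matrix for the variable-projection linear sub-problem.
# CPMG:  A(t)   = sum_i b_i exp(-t/T_i),                b_i = A0 p_i
# IR:    M(tau) = sum_i b_i (1/(2 alpha) - exp(-tau/T_i)), b_i = 2 alpha M0 p_i
# Both enforce sum(p) = 1 by construction; IR additionally pins the
# equilibrium value to the inversion efficiency alpha.
.vp_design <- function(times, tvec, kind, alpha) {
  E <- exp(-outer(times, tvec, "/"))
  if (kind == "inversion_recovery") 0.5 / alpha - E else E
}

.vp_solve <- function(times, y, tvec, kind, alpha, w) {
  X <- .vp_design(times, tvec, kind, alpha)
  if (!is.null(w)) {
    X <- X * w
    y <- y * w
  }
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  b[is.na(b)] <- 0
  list(b = b, rss = sum(fit$residuals^2))
}

.vp_rss <- function(log_t, times, y, kind, alpha, w) {
  .vp_solve(times, y, exp(log_t), kind, alpha, w)$rss
}

# deterministic initialization: coarse log grid over time constants, all
# ascending n-tuples, keep the best few by projected RSS
.vp_grid_starts <- function(times, y, n, kind, alpha, w,
                            n_grid = 16, n_keep = 2) {
  lo <- log(times[1] / 10)
  hi <- log(10 * times[length(times)])
  cand <- seq(lo, hi, length.out = n_grid)
  combos <- utils::combn(cand, n)
  rss <- apply(combos, 2, function(lt)
    .vp_rss(lt, times, y, kind, alpha, w))
  keep <- order(rss)[seq_len(min(n_keep, ncol(combos)))]
  lapply(keep, function(j) combos[, j])
}

.vp_fit <- function(trace, n, kind, alpha) {
  times <- trace$times
  y <- trace$amplitudes
  w <- if (is.null(trace$noise_sigma)) NULL else 1 / rep_len(
    trace$noise_sigma, length(times))
  lo <- log(times[1] / 10)
  hi <- log(10 * times[length(times)])
  starts <- .vp_grid_starts(times, y, n, kind, alpha, w)
  best <- NULL
  for (s in starts) {
    res <- stats::nlminb(
      start = s,
      objective = .vp_rss,
      lower = rep(lo, n), upper = rep(hi, n),
      times = times, y = y, kind = kind, alpha = alpha, w = w,
      control = list(iter.max = 500, eval.max = 1000,
                     rel.tol = 1e-14, x.tol = 1e-12)
    )
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  tvec <- sort(exp(best$par))
  sol <- .vp_solve(times, y, tvec, kind, alpha, w)
  list(tvec = tvec, b = sol$b, rss = sol$rss,
       converged = best$convergence == 0)
}

.aicc <- function(rss, n_obs, k, y_scale) {
  # floor the mean squared residual so numerically-zero residuals from
  # nested exact fits compare as ties (penalty then decides)
  msr <- max(rss / n_obs, (1e-9 * y_scale)^2)
  n_obs * log(msr) + 2 * k + 2 * k * (k + 1) / max(n_obs - k - 1, 1)
}

.fit_report <- function(trace, n, kind, alpha) {
  res <- .vp_fit(trace, n, kind, alpha)
  b <- res$b
  total <- sum(b)
  if (total <= 0)
    return(structure(
      list(components = NULL, m0 = NA_real_, alpha = alpha,
           residual_rms = sqrt(res$rss / length(trace$times)),
           n_components = n, model_scores = NULL, converged = FALSE,
           kind = kind),
      class = "relax_fit"))
  p <- b / total
  if (any(p < 0)) {
    warning("negative component amplitude; fractions clipped to [0, 1]",
            call. = FALSE)
    p <- pmax(p, 0)
    p <- p / sum(p)
  }
  m0 <- if (kind == "inversion_recovery") total / (2 * alpha) else total
  which <- if (kind == "inversion_recovery") "T1" else "T2"
  if (n >= 2) {
    tr <- res$tvec[-1] / res$tvec[-n]
    if (any(tr < 1.2))
      warning(sprintf(
        "adjacent time constants differ by less than 20%% (ratio %.3g); ",
        min(tr)), "the components are effectively collapsed", call. = FALSE)
  }
  comps <- data.frame(which = which, time_constant_s = res$tvec,
                      fraction = p, phase = "unassigned",
                      stringsAsFactors = FALSE)
  n_obs <- length(trace$times)
  score <- .aicc(res$rss, n_obs, 2 * n, max(abs(trace$amplitudes)))
  structure(
    list(components = comps, m0 = m0, alpha = alpha,
         residual_rms = sqrt(res$rss / n_obs), n_components = n,
         model_scores = stats::setNames(score, paste0("n", n)),
         converged = res$converged, kind = kind),
    class = "relax_fit"
  )
}

#' @export
print.relax_fit <- function(x, ...) {
  cat(sprintf("relax_fit (%s): %d component(s), residual rms %.4g%s\n",
              x$kind, x$n_components, x$residual_rms,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$components))
    print(format(x$components, digits = 5), row.names = FALSE)
  invisible(x)
}

#' Fit a multiexponential inversion-recovery curve
#'
#' Least-squares fit of
#' \deqn{M(\tau) = M_0\left[1 - 2\alpha \sum_i p_i e^{-\tau/T_{1i}}\right],
#'   \qquad \sum_i p_i = 1,}
#' with the inversion efficiency \eqn{\alpha} fixed at 1 (ideal 180° pulse)
#' by default, or profiled over `[0.8, 1]` with `fit_alpha = TRUE`.
#' Amplitudes are solved linearly for each candidate set of time constants
#' (variable projection); the time constants are refined by a bounded
#' quasi-Newton search from a deterministic log-grid initialization.
#'
#' @param trace A [signal_trace()] of kind `"inversion_recovery"`.
#' @param n_components Number of exponential pools, 1 to 3 (default 2: an
#'   oil and a water pool).
#' @param fit_alpha If `TRUE`, profile the inversion efficiency over
#'   `[0.8, 1]` instead of fixing it at 1.
#' @return An object of class `relax_fit` with fields `components` (sorted
#'   ascending by T1), `m0`, `alpha`, `residual_rms`, `n_components`,
#'   `model_scores` (small-sample information criterion), `converged`.
#' @seealso [fit_cpmg()], [select_n_components()], [assign_phases()]
#' @export
fit_inversion_recovery <- function(trace, n_components = 2,
                                   fit_alpha = FALSE) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$kind != "inversion_recovery")
    stop("trace kind is '", trace$kind, "', expected 'inversion_recovery'")
  if (!n_components %in% 1:3)
    stop("n_components must be 1, 2 or 3")
  if (length(trace$times) < 4 * n_components)
    stop(sprintf(
      "need at least %d points for %d component(s), trace has %d",
      4 * n_components, n_components, length(trace$times)))
  if (!fit_alpha)
    return(.fit_report(trace, n_components, "inversion_recovery", 1))
  obj <- function(a) .fit_report(trace, n_components,
                                 "inversion_recovery", a)$residual_rms
  a_opt <- stats::optimize(obj, lower = 0.8, upper = 1, tol = 1e-6)$minimum
  .fit_report(trace, n_components, "inversion_recovery", a_opt)
}

#' Fit a multiexponential CPMG echo decay
#'
#' Least-squares fit of
#' \deqn{A(t) = A_0 \sum_i p_i e^{-t/T_{2i}}, \qquad \sum_i p_i = 1,}
#' by the same variable-projection procedure as
#' [fit_inversion_recovery()].
#'
#' @param trace A [signal_trace()] of kind `"cpmg"` whose amplitudes decay
#'   overall.
#' @param n_components Number of exponential pools, 1 to 3 (default 2).
#' @return A `relax_fit` object (components sorted ascending by T2).
#' @export
fit_cpmg <- function(trace, n_components = 2) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$kind != "cpmg")
    stop("trace kind is '", trace$kind, "', expected 'cpmg'")
  if (!n_components %in% 1:3)
    stop("n_components must be 1, 2 or 3")
  if (length(trace$times) < 4 * n_components)
    stop(sprintf(
      "need at least %d points for %d component(s), trace has %d",
      4 * n_components, n_components, length(trace$times)))
  y <- trace$amplitudes
  k <- max(2L, ceiling(length(y) / 10))
  if (stats::sd(y) == 0 || mean(utils::head(y, k)) <= mean(utils::tail(y, k)))
    stop("CPMG amplitudes do not decay overall; refusing to fit a ",
         "relaxation model to a non-decaying trace")
  .fit_report(trace, n_components, "cpmg", 1)
}

#' Choose the number of exponential components
#'
#' Fits 1 to `max_components` pools and returns the count minimizing a
#' small-sample corrected information criterion (AICc on the residual sum
#' of squares); ties break toward fewer components. Intended as an opt-in
#' diagnostic — emulsion analyses default to exactly two pools (oil and
#' water).
#'
#' @param trace A [signal_trace()].
#' @param max_components 2 or 3.
#' @return The selected component count (integer).
#' @export
select_n_components <- function(trace, max_components = 2) {
  stopifnot(inherits(trace, "signal_trace"))
  if (!max_components %in% 2:3)
    stop("max_components must be 2 or 3")
  fitter <- if (trace$kind == "cpmg") fit_cpmg else fit_inversion_recovery
  scores <- vapply(seq_len(max_components), function(n) {
    if (length(trace$times) < 4 * n) return(Inf)
    suppressWarnings(fitter(trace, n)$model_scores[[1]])
  }, numeric(1))
  as.integer(which.min(scores))  # which.min takes the first (fewest) on ties
}

#' Observed fast-exchange relaxation rate of a component mixture
#'
#' The measured relaxation rate of a multi-pool system in fast exchange is
#' the fraction-weighted mean of the pool rates,
#' \eqn{1/T = \sum_i p_i / T_i}.
#'
#' @param components A component table as returned in a `relax_fit` (or by
#'   [relaxation_components()]); all rows must share the same `which` and
#'   fractions must sum to 1.
#' @return The weighted mean rate in s^-1.
#' @examples
#' observed_rate(relaxation_components(c(0.1, 1), c(0.25, 0.75), "T1"))
#' @export
observed_rate <- function(components) {
  stopifnot(is.data.frame(components),
            all(c("which", "time_constant_s", "fraction") %in%
                  names(components)))
  if (length(unique(components$which)) != 1)
    stop("components mix T1 and T2 entries; the weighted rate is only ",
         "defined within one relaxation kind")
  if (abs(sum(components$fraction) - 1) > 1e-6)
    stop("component fractions must sum to 1")
  sum(components$fraction / components$time_constant_s)
}

#' Assign oil and water phases to fitted two-pool components
#'
#' In a two-phase oil-in-water emulsion the short T1 and T2 components are
#' attributed to oil protons and the long components to the water phase.
#' Both fits must have exactly two components; equal time constants are a
#' tie the rule cannot break and raise an error.
#'
#' @param fit_t1 A `relax_fit` from [fit_inversion_recovery()] with 2
#'   components.
#' @param fit_t2 A `relax_fit` from [fit_cpmg()] with 2 components.
#' @return A list with elements `oil` and `water`, each a component table
#'   holding that phase's T1 and T2 rows (phase labels recorded).
#' @export
assign_phases <- function(fit_t1, fit_t2) {
  grab <- function(fit, label) {
    stopifnot(inherits(fit, "relax_fit"))
    comps <- fit$components
    if (is.null(comps) || nrow(comps) != 2)
      stop("phase assignment needs exactly 2 ", label, " components ",
           "(got ", if (is.null(comps)) 0 else nrow(comps), "); ",
           "map components to phases explicitly for other counts")
    if (comps$time_constant_s[1] == comps$time_constant_s[2])
      stop("the two ", label, " time constants are equal; short/long phase ",
           "assignment is undefined for a tie")
    comps[order(comps$time_constant_s), , drop = FALSE]
  }
  c1 <- grab(fit_t1, "T1")
  c2 <- grab(fit_t2, "T2")
  if (c1$which[1] != "T1" || c2$which[1] != "T2")
    stop("fit_t1 must be an inversion-recovery fit and fit_t2 a CPMG fit")
  oil <- rbind(c1[1, ], c2[1, ])
  water <- rbind(c1[2, ], c2[2, ])
  oil$phase <- "oil"
  water$phase <- "water"
  rownames(oil) <- rownames(water) <- NULL
  list(oil = oil, water = water)
}

#' Read a signal trace from CSV
#'
#' Expects columns `time_s` and `amplitude`.
#'
#' @param path CSV file path.
#' @param kind Trace kind, `"inversion_recovery"` or `"cpmg"`.
#' @param ... Passed to [signal_trace()].
#' @return A `signal_trace`.
#' @export
read_trace_csv <- function(path, kind, ...) {
  d <- utils::read.csv(path)
  miss <- setdiff(c("time_s", "amplitude"), names(d))
  if (length(miss))
    stop("trace CSV is missing column(s): ", paste(miss, collapse = ", "))
  signal_trace(d$time_s, d$amplitude, kind = kind, ...)
}

#' Write a signal trace to CSV
#'
#' @param trace A `signal_trace`.
#' @param path Output CSV path (columns `time_s`, `amplitude`).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  utils::write.csv(
    data.frame(time_s = trace$times, amplitude = trace$amplitudes),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a fit report's component table to CSV
#'
#' @param fit A `relax_fit`.
#' @param path Output CSV path (columns `component`, `which`,
#'   `time_constant_s`, `fraction`, `phase`).
#' @return `path`, invisibly.
#' @export
write_fit_report_csv <- function(fit, path) {
  stopifnot(inherits(fit, "relax_fit"), !is.null(fit$components))
  out <- cbind(component = seq_len(nrow(fit$components)), fit$components)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
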