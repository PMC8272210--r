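# Bloembergen-Purcell-Pound (BPP) dipolar relaxation: forward evaluation of
# the R1/R2 rates for a single mean correlation time, and the inversions used
# to recover the correlation time from measured rates or from their ratio.

#' Spectrometer / dipolar-coupling context for the BPP equations
#'
#' Bundles the quantities the BPP relaxation equations need: the Larmor
#' (spectrometer) frequency \eqn{f}, the angular frequency
#' \eqn{\omega = 2\pi f}, and optionally the lumped dipolar prefactor
#' \deqn{K = \frac{\mu_0^2}{16\pi^2}\,\gamma^4\,\left(\frac{h}{2\pi}\right)^2
#'   \frac{1}{r_0^6}}
#' computed from the internuclear distance `r0` (or supplied directly as
#' `dipolar_prefactor_K`). `K` is only needed to evaluate absolute rates;
#' the R2/R1 ratio is independent of it.
#'
#' @param larmor_frequency_hz Spectrometer frequency in Hz. Defaults to
#'   `15e6` (a 15 MHz low-field instrument).
#' @param r0 Optional effective internuclear (proton-proton) distance in
#'   metres; if given, the dipolar prefactor is computed from it.
#' @param dipolar_prefactor_K Optional dipolar prefactor in s^-2, overriding
#'   computation from `r0`. If both are given they must agree to relative
#'   1e-9.
#' @return An object of class `bpp_context` with fields
#'   `larmor_frequency_hz`, `angular_frequency`, `dipolar_prefactor_K`
#'   (possibly `NA`), and `r0` (possibly `NA`).
#' @examples
#' bpp_context()                      # ratio-based work, no K needed
#' bpp_context(r0 = 1.8e-10)          # absolute rates via a typical H-H pair
#' @export
bpp_context <- function(larmor_frequency_hz = 15e6, r0 = NULL,
                        dipolar_prefactor_K = NULL) {
  stopifnot(is.numeric(larmor_frequency_hz), length(larmor_frequency_hz) == 1)
  if (!is.finite(larmor_frequency_hz) || larmor_frequency_hz <= 0)
    stop("larmor_frequency_hz must be a positive finite number")
  K_from_r0 <- NA_real_
  if (!is.null(r0)) {
    stopifnot(is.numeric(r0), length(r0) == 1, r0 > 0)
    K_from_r0 <- dipolar_prefactor(r0)
  }
  K <- if (!is.null(dipolar_prefactor_K)) {
    stopifnot(is.numeric(dipolar_prefactor_K), length(dipolar_prefactor_K) == 1,
              dipolar_prefactor_K > 0)
    if (!is.null(r0) &&
        abs(dipolar_prefactor_K - K_from_r0) > 1e-9 * K_from_r0)
      stop("dipolar_prefactor_K disagrees with the value recomputed from r0")
    dipolar_prefactor_K
  } else K_from_r0
  structure(
    list(
      larmor_frequency_hz = larmor_frequency_hz,
      angular_frequency = 2 * pi * larmor_frequency_hz,
      dipolar_prefactor_K = K,
      r0 = if (is.null(r0)) NA_real_ else r0
    ),
    class = "bpp_context"
  )
}

#' @export
print.bpp_context <- function(x, ...) {
  cat("BPP context\n")
  cat(sprintf("  Larmor frequency : %.6g MHz\n", x$larmor_frequency_hz / 1e6))
  cat(sprintf("  omega            : %.6g rad/s\n", x$angular_frequency))
  if (is.finite(x$dipolar_prefactor_K))
    cat(sprintf("  dipolar K        : %.6g s^-2%s\n", x$dipolar_prefactor_K,
                if (is.finite(x$r0)) sprintf(" (r0 = %.3g m)", x$r0) else ""))
  else
    cat("  dipolar K        : not set (ratio-based methods only)\n")
  invisible(x)
}

#' Dipolar prefactor from an internuclear distance
#'
#' Computes \eqn{K = (\mu_0^2/16\pi^2)\gamma^4 (h/2\pi)^2 / r_0^6} (s^-2)
#' from the CODATA constants and a proton-proton distance.
#'
#' @param r0 Internuclear distance in metres.
#' @return The lumped dipolar constant K in s^-2.
#' @examples
#' dipolar_prefactor(1.8e-10)
#' @export
dipolar_prefactor <- function(r0) {
  stopifnot(is.numeric(r0), all(r0 > 0))
  cst <- .constants
  hbar <- cst$h / (2 * pi)
  (cst$mu0^2 / (16 * pi^2)) * cst$gamma_h^4 * hbar^2 / r0^6
}

.require_K <- function(ctx) {
  if (!is.finite(ctx$dipolar_prefactor_K))
    stop("dipolar prefactor K is not set in this bpp_context; either ",
         "construct it with r0/dipolar_prefactor_K, or use the K-free ",
         "ratio_r2_r1()/tau_c_from_ratio() route instead")
  ctx$dipolar_prefactor_K
}

.check_tau <- function(tau_c) {
  if (!is.numeric(tau_c) || any(!is.finite(tau_c)) || any(tau_c <= 0))
    stop("tau_c must be positive and finite")
}

#' Spin-lattice relaxation rate R1 under the BPP model
#'
#' Evaluates
#' \deqn{R_1 = \frac{6}{20} K \left[\frac{\tau_c}{1+(\omega\tau_c)^2} +
#'   \frac{4\tau_c}{1+(2\omega\tau_c)^2}\right]}
#' for a single mean rotational correlation time.
#'
#' @param tau_c Correlation time(s) in seconds (positive).
#' @param ctx A [bpp_context()] with the dipolar prefactor set.
#' @return R1 in s^-1 (vectorized over `tau_c`).
#' @seealso [r2_bpp()], [ratio_r2_r1()], [tau_c_from_r1()]
#' @examples
#' ctx <- bpp_context(r0 = 1.8e-10)
#' r1_bpp(1e-9, ctx)
#' @export
r1_bpp <- function(tau_c, ctx) {
  .check_tau(tau_c)
  K <- .require_K(ctx)
  x <- ctx$angular_frequency * tau_c
  (6 / 20) * K * (tau_c / (1 + x^2) + 4 * tau_c / (1 + (2 * x)^2))
}

#' Spin-spin relaxation rate R2 under the BPP model
#'
#' Evaluates
#' \deqn{R_2 = \frac{3}{20} K \left[3\tau_c +
#'   \frac{5\tau_c}{1+(\omega\tau_c)^2} +
#'   \frac{2\tau_c}{1+(2\omega\tau_c)^2}\right].}
#' The secular \eqn{3\tau_c} term makes R2 monotone increasing in the
#' correlation time, so R2 >= R1 always, with equality in the
#' extreme-narrowing limit \eqn{\omega\tau_c \ll 1}.
#'
#' @inheritParams r1_bpp
#' @return R2 in s^-1 (vectorized over `tau_c`).
#' @examples
#' ctx <- bpp_context(r0 = 1.8e-10)
#' r2_bpp(1e-9, ctx) / r1_bpp(1e-9, ctx)
#' @export
r2_bpp <- function(tau_c, ctx) {
  .check_tau(tau_c)
  K <- .require_K(ctx)
  x <- ctx$angular_frequency * tau_c
  (3 / 20) * K * (3 * tau_c + 5 * tau_c / (1 + x^2) +
                    2 * tau_c / (1 + (2 * x)^2))
}

#' R2/R1 ratio under the BPP model (prefactor-free)
#'
#' The dipolar prefactor K cancels in the ratio, leaving
#' \deqn{\frac{R_2}{R_1} = \frac{1}{2}\,
#'   \frac{3 + 5/(1+x^2) + 2/(1+4x^2)}{1/(1+x^2) + 4/(1+4x^2)}, \quad
#'   x = \omega\tau_c,}
#' a strictly increasing function of the correlation time with limit 1 as
#' \eqn{x \to 0}. This is the quantity inverted to recover the correlation
#' time from measured T1/T2 pairs without knowing the internuclear distance.
#'
#' @inheritParams r1_bpp
#' @param ctx A [bpp_context()]; only the frequency is used, K is not needed.
#' @return The dimensionless ratio R2/R1 (>= 1), vectorized over `tau_c`.
#' @examples
#' ctx <- bpp_context()
#' ratio_r2_r1(1 / ctx$angular_frequency, ctx)  # ~2.269 at omega*tau = 1
#' @export
ratio_r2_r1 <- function(tau_c, ctx) {
  .check_tau(tau_c)
  x2 <- (ctx$angular_frequency * tau_c)^2
  0.5 * (3 + 5 / (1 + x2) + 2 / (1 + 4 * x2)) /
    (1 / (1 + x2) + 4 / (1 + 4 * x2))
}

#' Correlation time from a measured R2/R1 ratio
#'
#' Inverts [ratio_r2_r1()] by bisection on the logarithm of the correlation
#' time; the ratio is strictly increasing so the root is unique within the
#' bracket. Measured ratios marginally below 1 (possible under noise, since
#' the physical ratio cannot be below 1) are clamped to `1 + 1e-9` and
#' flagged; ratios below 0.9 are treated as data pathology and abort.
#'
#' @param ratio Measured R2/R1 (equivalently T1/T2) ratio.
#' @param ctx A [bpp_context()]; K is not required.
#' @param bracket Length-2 search interval for the correlation time in
#'   seconds. Must bracket the root.
#' @param temperature_k Optional absolute temperature to record on the
#'   result.
#' @param tol Relative tolerance on the correlation time (default 1e-10).
#' @return A list of class `correlation_time` with fields `tau_c` (s),
#'   `temperature_k`, `clamped` (logical) and `ratio` (the ratio actually
#'   inverted).
#' @examples
#' ctx <- bpp_context()
#' tau_c_from_ratio(2.269231, ctx)$tau_c  # ~1.06e-8 s at 15 MHz
#' @export
tau_c_from_ratio <- function(ratio, ctx, bracket = c(1e-13, 1e-5),
                             temperature_k = NA_real_, tol = 1e-10) {
  stopifnot(is.numeric(ratio), length(ratio) == 1, is.finite(ratio))
  stopifnot(length(bracket) == 2, all(bracket > 0), bracket[1] < bracket[2])
  clamped <- FALSE
  if (ratio < 1) {
    if (ratio < 0.9)
      stop(sprintf(
        "R2/R1 ratio %.4g is far below the physical minimum of 1; ",
        ratio), "the trace or fit is noise-inconsistent")
    ratio <- 1 + 1e-9
    clamped <- TRUE
  }
  f <- function(log_tau) ratio_r2_r1(exp(log_tau), ctx) - ratio
  lo <- log(bracket[1]); hi <- log(bracket[2])
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0)
    stop(sprintf(
      "bracket [%.3g, %.3g] s does not bracket the ratio %.6g: ",
      bracket[1], bracket[2], ratio),
      "ratio_r2_r1 at the endpoints is ",
      sprintf("%.6g and %.6g", flo + ratio, fhi + ratio))
  # bisection on log(tau): relative tolerance on tau is additive on the log
  while ((hi - lo) > tol / 2) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  tau <- exp((lo + hi) / 2)
  structure(
    list(tau_c = tau, temperature_k = temperature_k, clamped = clamped,
         ratio = ratio),
    class = "correlation_time"
  )
}

#' @export
print.correlation_time <- function(x, ...) {
  cat(sprintf("correlation time tau_c = %.6g s", x$tau_c))
  if (is.finite(x$temperature_k)) cat(sprintf(" at %.2f K", x$temperature_k))
  if (isTRUE(x$clamped)) cat("  [ratio clamped to 1+1e-9]")
  cat("\n")
  invisible(x)
}

# location of the R1 maximum in omega*tau (solved once per call; cheap)
.r1_argmax_x <- function(ctx) {
  g <- function(lx) {
    x <- exp(lx)
    x / (1 + x^2) + 4 * x / (1 + 4 * x^2)  # r1 * omega / (0.3 K), in x
  }
  opt <- stats::optimize(g, lower = log(1e-3), upper = log(1e3),
                         maximum = TRUE, tol = 1e-14)
  exp(opt$maximum)
}

#' Correlation time from an absolute R1 rate
#'
#' Inverts the BPP R1 expression. R1 is not monotone in the correlation
#' time: it rises to a maximum near \eqn{\omega\tau_c \approx 0.62} and
#' falls beyond it, so every attainable rate has two roots and the caller
#' must choose a `branch`: `"fast"` (motional-narrowing side,
#' \eqn{\omega\tau_c} below the maximum) or `"slow"` (above it). Requires
#' the dipolar prefactor.
#'
#' @param r1 Measured spin-lattice rate in s^-1.
#' @param ctx A [bpp_context()] with the dipolar prefactor set.
#' @param branch `"fast"` or `"slow"`; no default — the choice is physical
#'   information the data alone cannot supply.
#' @param temperature_k Optional absolute temperature to record.
#' @return A `correlation_time` object (see [tau_c_from_ratio()]).
#' @examples
#' ctx <- bpp_context(r0 = 1.8e-10)
#' tau_c_from_r1(r1_bpp(1e-9, ctx), ctx, branch = "fast")$tau_c
#' @export
tau_c_from_r1 <- function(r1, ctx, branch, temperature_k = NA_real_) {
  stopifnot(is.numeric(r1), length(r1) == 1, is.finite(r1), r1 > 0)
  K <- .require_K(ctx)
  if (missing(branch))
    stop("branch must be given explicitly: \"fast\" (omega*tau below the ",
         "R1 maximum) or \"slow\" (above it); there is no safe default")
  branch <- match.arg(branch, c("fast", "slow"))
  w <- ctx$angular_frequency
  x_star <- .r1_argmax_x(ctx)
  tau_star <- x_star / w
  r1_max <- r1_bpp(tau_star, ctx)
  if (r1 > r1_max * (1 + 1e-12))
    stop(sprintf(
      "r1 = %.6g s^-1 exceeds the maximum attainable BPP rate %.6g s^-1 ",
      r1, r1_max), sprintf(
      "at omega*tau = %.4g for this frequency and prefactor", x_star))
  r1 <- min(r1, r1_max)  # guard the bracketing when r1 sits on the maximum
  f <- function(lt) r1_bpp(exp(lt), ctx) - r1
  interval <- if (branch == "fast") {
    lo <- log(tau_star) - 60 * log(2)
    c(lo, log(tau_star))
  } else {
    c(log(tau_star), log(tau_star) + 60 * log(2))
  }
  root <- stats::uniroot(f, interval = interval, tol = 1e-14)$root
  structure(
    list(tau_c = exp(root), temperature_k = temperature_k, clamped = FALSE,
         ratio = NA_real_),
    class = "correlation_time"
  )
}
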