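# Activation energies of rotational motion: ordinary least squares of
# ln(tau_c) on 1/T, slope * R = delta_Ea.

#' Fit the Arrhenius temperature law to correlation times
#'
#' Rotational motion crossing an energy barrier follows
#' \deqn{\tau_c = \tau_0 \exp\!\left(\frac{\Delta E_a}{R T}\right),}
#' so \eqn{\ln\tau_c} is linear in \eqn{1/T} with slope
#' \eqn{\Delta E_a / R}. This fits that line by ordinary least squares and
#' reports the activation energy in kJ/mol with its regression standard
#' error.
#'
#' @param tau_c Correlation times in seconds (> 0). May also be a list of
#'   `correlation_time` objects carrying their own temperatures, in which
#'   case `temperature_k` is taken from them.
#' @param temperature_k Absolute temperatures in kelvin, same length as
#'   `tau_c` (ignored when `tau_c` is a list of `correlation_time`).
#' @param phase Phase label to record (`"oil"`, `"water"` or
#'   `"unassigned"`).
#' @param weights Optional regression weights on the \eqn{\ln\tau_c} scale
#'   (e.g. inverse variances propagated from upstream fits).
#' @return An object of class `arrhenius_fit`: `delta_ea` and `delta_ea_se`
#'   (kJ/mol), `tau_0` (s), `r_squared`, `n_points`, `phase`, and the
#'   underlying `lm` fit as `model`.
#' @examples
#' Tk <- seq(273, 363, length.out = 10)
#' tau <- 1e-12 * exp(20000 / (8.314462618 * Tk))
#' fit_arrhenius(tau, Tk)
#' @export
fit_arrhenius <- function(tau_c, temperature_k = NULL, phase = "unassigned",
                          weights = NULL) {
  if (is.list(tau_c) && all(vapply(tau_c, inherits, logical(1),
                                   "correlation_time"))) {
    temperature_k <- vapply(tau_c, `[[`, numeric(1), "temperature_k")
    tau_c <- vapply(tau_c, `[[`, numeric(1), "tau_c")
  }
  phase <- match.arg(phase, c("oil", "water", "unassigned"))
  stopifnot(is.numeric(tau_c), is.numeric(temperature_k),
            length(tau_c) == length(temperature_k))
  if (length(tau_c) < 3)
    stop("an Arrhenius fit needs at least 3 points, got ", length(tau_c))
  if (anyDuplicated(temperature_k))
    stop("temperatures must be distinct")
  if (any(!is.finite(temperature_k)) || any(temperature_k <= 0))
    stop("temperatures must be positive and finite (kelvin)")
  bad <- !is.finite(suppressWarnings(log(tau_c)))
  if (any(bad))
    stop("non-finite ln(tau_c) at temperature(s) ",
         paste(format(temperature_k[bad]), collapse = ", "), " K")
  inv_t <- 1 / temperature_k
  ln_tau <- log(tau_c)
  model <- stats::lm(ln_tau ~ inv_t, weights = weights)
  # summary.lm warns on an exactly collinear (noiseless) fit; the SE it
  # returns (~0) is still the right answer for that case
  sm <- suppressWarnings(summary(model))
  slope <- stats::coef(model)[["inv_t"]]
  slope_se <- sm$coefficients["inv_t", "Std. Error"]
  structure(
    list(
      delta_ea = slope * .constants$r_gas / 1000,
      delta_ea_se = slope_se * .constants$r_gas / 1000,
      tau_0 = exp(stats::coef(model)[["(Intercept)"]]),
      r_squared = sm$r.squared,
      n_points = length(tau_c),
      phase = phase,
      model = model
    ),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "Arrhenius fit (%s phase): delta_Ea = %.1f +/- %.1f kJ/mol\n",
    x$phase, x$delta_ea, x$delta_ea_se))
  cat(sprintf("  tau_0 = %.4g s, R^2 = %.4f, n = %d\n",
              x$tau_0, x$r_squared, x$n_points))
  invisible(x)
}

#' Assemble an activation-energy results table
#'
#' Collects per-phase Arrhenius fits for one or more emulsion conditions
#' into the long-format table used for reporting: one row per
#' (starch, concentration, fat, phase), with the activation energy and its
#' standard error in kJ/mol plus a display string rounded half-up to one
#' decimal ("25.7 ± 0.6").
#'
#' @param fits A list of `arrhenius_fit` objects (each carrying its phase
#'   label).
#' @param metadata A data frame with one row per fit and columns `starch`,
#'   `concentration_g_per_g`, `fat` (the concentration is metadata only;
#'   nothing is computed from it).
#' @return A data frame with columns `starch`, `concentration_g_per_g`,
#'   `fat`, `phase`, `delta_ea_kj_mol`, `se_kj_mol`, `display`.
#' @export
activation_energy_table <- function(fits, metadata = NULL) {
  cols <- c("starch", "concentration_g_per_g", "fat", "phase",
            "delta_ea_kj_mol", "se_kj_mol", "display")
  if (length(fits) == 0) {
    out <- data.frame(starch = character(), concentration_g_per_g = numeric(),
                      fat = character(), phase = character(),
                      delta_ea_kj_mol = numeric(), se_kj_mol = numeric(),
                      display = character(), stringsAsFactors = FALSE)
    return(out[, cols])
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "arrhenius_fit")))
  if (is.null(metadata))
    metadata <- data.frame(starch = NA_character_,
                           concentration_g_per_g = NA_real_,
                           fat = NA_character_)[rep(1, length(fits)), ]
  stopifnot(is.data.frame(metadata), nrow(metadata) == length(fits))
  miss <- setdiff(c("starch", "concentration_g_per_g", "fat"),
                  names(metadata))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  out <- cbind(
    metadata[, c("starch", "concentration_g_per_g", "fat"), drop = FALSE],
    data.frame(
      phase = vapply(fits, `[[`, character(1), "phase"),
      delta_ea_kj_mol = vapply(fits, `[[`, numeric(1), "delta_ea"),
      se_kj_mol = vapply(fits, `[[`, numeric(1), "delta_ea_se"),
      stringsAsFactors = FALSE
    )
  )
  key <- interaction(out$starch, out$concentration_g_per_g, out$fat,
                     out$phase, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (starch, concentration, fat, phase) entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  out$display <- sprintf("%.1f ± %.1f",
                         round_half_up(out$delta_ea_kj_mol, 1),
                         round_half_up(out$se_kj_mol, 1))
  rownames(out) <- NULL
  out[, cols]
}

#' Write an activation-energy table to CSV
#'
#' Full precision is kept in the CSV; the `display` column carries the
#' one-decimal rounded presentation.
#'
#' @param table A table from [activation_energy_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_activation_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Format an activation-energy table as aligned text
#'
#' @param table A table from [activation_energy_table()].
#' @return A character vector of lines.
#' @export
format_activation_table <- function(table) {
  if (nrow(table) == 0) return("(no activation energies)")
  lines <- sprintf("%-10s %6s %-6s %-6s  %s",
                   table$starch,
                   formatC(table$concentration_g_per_g, format = "g"),
                   table$fat, table$phase, table$display)
  c(sprintf("%-10s %6s %-6s %-6s  %s", "starch", "conc", "fat", "phase",
            "delta_Ea (kJ/mol)"), lines)
}
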