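# Physical constants are data, not magic numbers: everything the dipolar
# relaxation model needs lives in this one table (CODATA 2018 values).

.constants <- list(
  mu0     = 1.25663706212e-6,  # vacuum permeability, T m / A
  gamma_h = 2.6752218744e8,    # proton magnetogyric ratio, rad / (s T)
  h       = 6.62607015e-34,    # Planck constant, J s
  r_gas   = 8.314462618        # molar gas constant, J / (mol K)
)

#' Physical constants used by the relaxation model
#'
#' Returns the CODATA 2018 values of the constants entering the dipolar
#' relaxation prefactor and the Arrhenius law: the vacuum permeability
#' \eqn{\mu_0}, the proton magnetogyric ratio \eqn{\gamma}, the Planck
#' constant \eqn{h} and the molar gas constant \eqn{R}.
#'
#' @return A data frame with columns `symbol`, `value`, `unit`,
#'   `description`, one row per constant.
#' @examples
#' codata_constants()
#' @export
codata_constants <- function() {
  data.frame(
    symbol = c("mu0", "gamma_h", "h", "r_gas"),
    value = unlist(.constants, use.names = FALSE),
    unit = c("T m A-1", "rad s-1 T-1", "J s", "J mol-1 K-1"),
    description = c(
      "vacuum permeability",
      "proton magnetogyric ratio",
      "Planck constant",
      "molar gas constant"
    ),
    stringsAsFactors = FALSE
  )
}

#' Convert Celsius to kelvin
#'
#' Temperatures are carried in kelvin internally; Celsius is accepted at the
#' I/O boundary and converted with \eqn{T(K) = T(°C) + 273.15}.
#'
#' @param temperature_c Temperature(s) in degrees Celsius.
#' @return Temperature(s) in kelvin.
#' @examples
#' celsius_to_kelvin(c(0, 90))
#' @export
celsius_to_kelvin <- function(temperature_c) {
  stopifnot(is.numeric(temperature_c))
  temperature_c + 273.15
}

# round half up (away from zero for positives), the display convention used
# for percentages and activation energies; base round() rounds half to even
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
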