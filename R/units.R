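# Spectroscopic unit system: energies are quoted in wavenumbers (cm^-1),
# time in picoseconds, and internally hbar = 1 so that energies become
# angular frequencies in rad/ps.

#' Physical constants of the spectroscopic unit system
#'
#' The package works in spectroscopy units: energies in wavenumbers
#' (cm\eqn{^{-1}}), time in picoseconds, and internally \eqn{\hbar = 1} so
#' that an energy of 1 cm\eqn{^{-1}} corresponds to the angular frequency
#' \eqn{2\pi c \cdot 1\,\mathrm{cm^{-1}}} in rad/ps.
#'
#' @return A list with `c_cm_per_ps`, the speed of light in cm/ps
#'   (0.0299792458), and `kB_wavenumber_per_K`, the Boltzmann constant in
#'   cm\eqn{^{-1}}/K (0.69503480).
#' @examples
#' unit_system()
#' @export
unit_system <- function() {
  list(c_cm_per_ps = 0.0299792458, kB_wavenumber_per_K = 0.69503480)
}

#' Convert a wavenumber to an angular frequency
#'
#' An energy quoted as a wavenumber \eqn{\tilde\nu} (cm\eqn{^{-1}})
#' corresponds to the angular frequency \eqn{\omega = 2\pi c \tilde\nu}.
#' With \eqn{c} in cm/ps the result is in rad/ps, the package's internal
#' \eqn{\hbar = 1} energy unit.
#'
#' @param x Wavenumber(s) in cm\eqn{^{-1}}.
#' @return Angular frequency in rad/ps.
#' @examples
#' wavenumber_to_angular_frequency(1)   # 0.18836...
#' wavenumber_to_angular_frequency(50)  # bath cutoff 50 cm^-1
#' @seealso [angular_frequency_to_wavenumber()]
#' @export
wavenumber_to_angular_frequency <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x * 2 * pi * 0.0299792458
}

#' Convert an angular frequency back to a wavenumber
#'
#' Inverse of [wavenumber_to_angular_frequency()].
#'
#' @param w Angular frequency in rad/ps.
#' @return Wavenumber in cm\eqn{^{-1}}.
#' @export
angular_frequency_to_wavenumber <- function(w) {
  stopifnot(is.numeric(w), all(is.finite(w)))
  w / (2 * pi * 0.0299792458)
}

#' Thermal energy in wavenumbers
#'
#' Returns \eqn{k_B T} expressed in cm\eqn{^{-1}}. At the spectroscopic
#' reference temperature 77 K this is about 53.52 cm\eqn{^{-1}}.
#'
#' @param temperature Temperature in kelvin; must be strictly positive.
#' @return \eqn{k_B T} in cm\eqn{^{-1}}.
#' @examples
#' thermal_energy_wavenumber(77)
#' @export
thermal_energy_wavenumber <- function(temperature) {
  stopifnot(is.numeric(temperature), length(temperature) >= 1,
            all(is.finite(temperature)))
  if (any(temperature <= 0)) {
    stop("temperature must be strictly positive (got ",
         paste(temperature[temperature <= 0], collapse = ", "), ")")
  }
  0.69503480 * temperature
}
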