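#' Arrhenius rate model
#'
#' Attempt-time prefactor and temperature for converting free-energy
#' barriers into transition time scales, \eqn{\tau = \tau_0
#' e^{\Delta F^\ddagger / k_B T}}.  The default \eqn{\tau_0} = 1 ps is a
#' typical molecular attempt time; the resulting times are order-of-
#' magnitude estimates, not rate-theory derivations.
#'
#' @param tau0 Prefactor in seconds (> 0; default 1e-12).
#' @param temperature Temperature in kelvin (default 300).
#' @return A `rate_model`.
#' @export
rate_model <- function(tau0 = 1e-12, temperature = 300) {
  stopifnot(tau0 > 0, temperature > 0)
  structure(list(tau0 = tau0, temperature = temperature),
            class = "rate_model")
}

#' Barrier-to-timescale conversion
#'
#' @param barrier Free-energy barrier in kJ/mol (>= 0).
#' @param model A [rate_model()].
#' @return Expected transition time in seconds.
#' @examples
#' arrhenius_time(75)   # ~ 1e1 s:  seconds scale
#' arrhenius_time(100)  # ~ 3e5 s:  hours-to-days scale
#' @export
arrhenius_time <- function(barrier, model = rate_model()) {
  stopifnot(inherits(model, "rate_model"))
  if (any(barrier < 0)) stop("barrier must be non-negative")
  model$tau0 * exp(barrier / kT(model$temperature))
}

#' Photon energy of a wavelength
#'
#' \eqn{E = N_A h c / \lambda} expressed per mole:
#' \eqn{N_A h c} = 119626.57 kJ nm/mol.  The red/far-red absorption band of
#' bilin chromophores (660-700 nm) maps to roughly 171-181 kJ/mol.
#'
#' @param wavelength Wavelength in nm (> 0).
#' @return Energy in kJ/mol.
#' @examples
#' photon_energy(660)  # 181.3 kJ/mol
#' @export
photon_energy <- function(wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  119626.57 / wavelength
}
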