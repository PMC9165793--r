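#' Create a thermodynamic context
#'
#' Defaults to R = 8.314 J mol^-1 K^-1 at T = 310 K (body temperature).
#' `normalisedContext()` returns the RT = 1 convenience context in which
#' chemical potentials are reported directly in RT units.
#'
#' @param R ideal gas constant (J mol^-1 K^-1).
#' @param T absolute temperature (K).
#' @return a [ThermoContext-class].
#' @examples
#' ctx <- thermoContext()
#' ctx@RT
#' @export
thermoContext <- function(R = 8.314, T = 310) {
  new("ThermoContext", R = R, T = T, RT = R * T)
}

#' @rdname thermoContext
#' @export
normalisedContext <- function() new("ThermoContext", R = 1, T = 1, RT = 1)

#' Chemical potential of a species
#'
#' Constitutive relation of the species storage component:
#' u = RT * ln(Kq * q). Undefined at zero amount.
#'
#' @param Kq species thermodynamic constant (> 0).
#' @param q amount (> 0).
#' @param ctx a [ThermoContext-class].
#' @return potential in J mol^-1 (or RT units under [normalisedContext()]).
#' @examples
#' chemicalPotential(2, 3, normalisedContext())  # log(6)
#' @export
chemicalPotential <- function(Kq, q, ctx = thermoContext()) {
  if (any(!is.finite(Kq)) || any(Kq <= 0))
    bgStop("bgDomainError", "Kq must be positive")
  if (any(!is.finite(q)) || any(q <= 0))
    bgStop("bgDomainError",
           "chemical potential is undefined at non-positive amounts")
  ctx@RT * log(Kq * q)
}
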