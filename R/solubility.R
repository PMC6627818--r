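#' Seawater oxygen solubility per unit partial pressure
#'
#' Oxygen solubility coefficient \eqn{\beta} (mg O2 per mm Hg per L) used to
#' convert a PO2 decline in a sealed respirometer into an oxygen mass.
#' Air-saturated oxygen concentration follows the Weiss (1970) seawater
#' parameterization (Deep-Sea Res. 17:721-735), converted from mL L^-1 (STP) to
#' mg L^-1; the saturating oxygen partial pressure is the atmospheric O2 mole
#' fraction (0.20946) times total pressure minus water vapour pressure, the
#' latter from Weiss & Price (1980, Mar. Chem. 8:347-359).
#'
#' \deqn{\beta(T, S) = C_{sat}(T, S) / [0.20946 (P_{atm} - p_{H2O}(T, S))]}
#'
#' \eqn{\beta} is strictly decreasing in both temperature and salinity over the
#' supported range.
#'
#' @param temp Water temperature, degrees Celsius (0-40).
#' @param salinity Salinity, practical salinity units / ppt (0-40).
#' @param atm_pressure Total atmospheric pressure, mm Hg. Default 760.
#' @return Oxygen solubility in mg O2 mmHg^-1 L^-1 (vectorized over inputs).
#' @examples
#' o2_solubility(15, 18)
#' o2_solubility(c(5, 30), 18)  # falls with temperature
#' @seealso [o2_saturation_concentration()], [water_vapour_pressure()]
#' @export
o2_solubility <- function(temp, salinity, atm_pressure = 760) {
  check_ts_range(temp, salinity)
  csat <- o2_saturation_concentration(temp, salinity)
  po2_sat <- 0.20946 * (atm_pressure - water_vapour_pressure(temp, salinity))
  csat / po2_sat
}

#' Air-saturated oxygen concentration in seawater
#'
#' Weiss (1970) fit to the Carpenter/Murray-Riley oxygen solubility data,
#' returning the concentration of dissolved oxygen in equilibrium with
#' water-saturated air at 760 mm Hg total pressure. The native units of the fit
#' (mL O2 L^-1 at STP) are converted to mg L^-1 using the real-gas molar volume
#' of oxygen (22.392 L mol^-1, i.e. 1 mL O2 = 1.42905 mg).
#'
#' @inheritParams o2_solubility
#' @return Saturation concentration, mg O2 L^-1.
#' @export
o2_saturation_concentration <- function(temp, salinity) {
  check_ts_range(temp, salinity)
  tk100 <- (temp + 273.15) / 100
  ln_ml <- -173.4292 + 249.6339 / tk100 + 143.3483 * log(tk100) -
    21.8492 * tk100 +
    salinity * (-0.033096 + 0.014259 * tk100 - 0.0017 * tk100^2)
  exp(ln_ml) * 1.42905
}

#' Water vapour pressure over seawater
#'
#' Weiss & Price (1980) parameterization, converted from atmospheres to mm Hg.
#'
#' @inheritParams o2_solubility
#' @return Vapour pressure, mm Hg.
#' @export
water_vapour_pressure <- function(temp, salinity) {
  tk <- temp + 273.15
  exp(24.4543 - 67.4509 * (100 / tk) - 4.8489 * log(tk / 100) -
        0.000544 * salinity) * 760
}

check_ts_range <- function(temp, salinity) {
  if (any(!is.finite(temp)) || any(temp < 0) || any(temp > 40))
    stop("temperature must be finite and within 0-40 degrees C", call. = FALSE)
  if (any(!is.finite(salinity)) || any(salinity < 0) || any(salinity > 40))
    stop("salinity must be finite and within 0-40 ppt", call. = FALSE)
  invisible(TRUE)
}
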