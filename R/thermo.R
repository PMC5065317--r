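# Physical-chemistry utilities: thermal voltage, Nernst slope, proton
# reversal potential. CODATA constants; all potentials in mV.

#' @keywords internal
.GAS_CONSTANT <- 8.314462618   # J mol^-1 K^-1
#' @keywords internal
.FARADAY <- 96485.33212        # C mol^-1

#' Recording conditions
#'
#' Bundles the solution pH on each side of the membrane and the bath
#' temperature. These determine the proton reversal potential and the
#' pH_o-dependent position of the gating curves.
#'
#' @param ph_i Intracellular (pipette) pH.
#' @param ph_o Extracellular (bath) pH.
#' @param temperature Absolute temperature in kelvin. Default 293.15 K
#'   (~20 degrees C, a typical room-temperature recording).
#' @return An object of class `recording_conditions`.
#' @examples
#' recording_conditions(ph_i = 6.5, ph_o = 6.5)
#' @export
recording_conditions <- function(ph_i, ph_o, temperature = 293.15) {
  stopifnot(is.numeric(ph_i), length(ph_i) == 1L,
            is.numeric(ph_o), length(ph_o) == 1L,
            is.numeric(temperature), length(temperature) == 1L)
  if (!(ph_i > 0 && ph_i < 14)) {
    stop(errorCondition("ph_i must lie in (0, 14)",
                        class = c("hvgate_invalid_argument", "error", "condition")))
  }
  if (!(ph_o > 0 && ph_o < 14)) {
    stop(errorCondition("ph_o must lie in (0, 14)",
                        class = c("hvgate_invalid_argument", "error", "condition")))
  }
  if (!(temperature > 0)) {
    stop(errorCondition("temperature must be positive (kelvin)",
                        class = c("hvgate_invalid_argument", "error", "condition")))
  }
  structure(list(ph_i = ph_i, ph_o = ph_o, temperature = temperature),
            class = "recording_conditions")
}

#' @export
print.recording_conditions <- function(x, ...) {
  cat(sprintf("Recording conditions: pH_i %.2f / pH_o %.2f, T = %.2f K (E_H = %+.1f mV)\n",
              x$ph_i, x$ph_o, x$temperature, proton_reversal(x)))
  invisible(x)
}

#' Thermal voltage RT/F
#'
#' Returns RT/F in millivolts; approximately 25.3 mV at 20 degrees C.
#'
#' @param temperature Absolute temperature in kelvin.
#' @return Thermal voltage in mV.
#' @examples
#' thermal_voltage(293.15)  # ~25.3 mV
#' @export
thermal_voltage <- function(temperature = 293.15) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop(errorCondition("temperature must be positive (kelvin)",
                        class = c("hvgate_invalid_argument", "error", "condition")))
  }
  1000 * .GAS_CONSTANT * temperature / .FARADAY
}

#' Nernst slope per pH unit
#'
#' The slope of the Nernstian reversal potential with respect to a
#' one-unit change in transmembrane pH gradient:
#' `ln(10) * RT/F`, about 58.2 mV/pH unit at 20 degrees C.
#'
#' @inheritParams thermal_voltage
#' @return Slope in mV per pH unit.
#' @export
nernst_slope <- function(temperature = 293.15) {
  thermal_voltage(temperature) * log(10)
}

#' Proton reversal potential
#'
#' Nernst potential for a proton-selective conductance,
#' `E_H = nernst_slope(T) * (pH_i - pH_o)` in mV. Positive when the
#' extracellular side is more acidic than the cytoplasm.
#'
#' @param conditions A [recording_conditions()] object.
#' @return Reversal potential in mV.
#' @examples
#' proton_reversal(recording_conditions(6.5, 5.5))  # ~ +58 mV
#' @export
proton_reversal <- function(conditions) {
  stopifnot(inherits(conditions, "recording_conditions"))
  nernst_slope(conditions$temperature) * (conditions$ph_i - conditions$ph_o)
}

#' Effective gating valence from a Boltzmann slope factor
#'
#' Converts a fitted slope factor dx (mV) into an apparent gating charge
#' z_G = (RT/F) / dx, in elementary charges.
#'
#' @param slope_dx Boltzmann slope factor in mV (positive).
#' @inheritParams thermal_voltage
#' @return Apparent gating valence in units of e0.
#' @examples
#' gating_valence(42.1)  # ~0.6 e0
#' @export
gating_valence <- function(slope_dx, temperature = 293.15) {
  if (!is.numeric(slope_dx) || any(!is.finite(slope_dx)) || any(slope_dx <= 0)) {
    stop(errorCondition("slope_dx must be positive (mV)",
                        class = c("hvgate_invalid_argument", "error", "condition")))
  }
  thermal_voltage(temperature) / slope_dx
}
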