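# Validation of the first-derivative V_PEAK estimator on synthetic
# Boltzmann G-V relations whose midpoints shift 40 mV per pH_o unit —
# the in-silico check that V_PEAK tracks the position of the gating
# curve when its plateaus are not reached.

#' Validate the derivative-Gaussian V_PEAK estimator on shifted curves
#'
#' Generates noiseless Boltzmann G-V relations (one per pH_o) for either
#' the depolarization-activated (`"aq"`) or hyperpolarization-activated
#' (`"sh"`) branch of the validation parameter set (midpoints separated
#' by 40 mV across one pH unit, amplitudes halved at the higher pH),
#' takes the numerical derivative, fits a Gaussian to each |dG/dV|-V
#' relation, and regresses the fitted V_PEAK on pH.
#'
#' @param branch `"aq"` (default) or `"sh"`.
#' @param voltages Sampling grid, mV (default -200..+200 in 10 mV steps,
#'   wide enough to cover both plateaus of the aq branch).
#' @param window Gaussian fit window, mV (default: the full grid).
#' @return List: `per_ph` (data.frame with `ph_o`, `v_half_true`,
#'   `v_peak`), `slope_mv_per_ph`, `slope_magnitude` (rounded to the
#'   nearest integer).
#' @export
validate_vpeak_method <- function(branch = c("aq", "sh"),
                                  voltages = seq(-200, 200, 10),
                                  window = range(voltages)) {
  branch <- match.arg(branch)
  sim <- hv1_fixtures()$legend_fits$sim_validation
  if (branch == "aq") {
    v_half <- sim$gaq_v_half; dx <- sim$gaq_dx; g_max <- sim$gaq_g_max
    polarity <- "depolarization"
  } else {
    v_half <- sim$gsh_v_half; dx <- sim$gsh_dx; g_max <- sim$gsh_g_max
    polarity <- "hyperpolarization"
  }
  v_peak <- vapply(seq_along(sim$ph_o), function(i) {
    g <- boltzmann_curve(voltages, v_half[i], dx, y_max = g_max[i],
                         polarity = polarity)
    d <- numeric_derivative(voltages, g)
    fit_gaussian_peak(d$v, abs(d$dgdv), window = window)$v_peak
  }, 0)
  per_ph <- data.frame(ph_o = sim$ph_o, v_half_true = v_half, v_peak = v_peak)
  lf <- fit_line(sim$ph_o, v_peak)
  list(per_ph = per_ph, slope_mv_per_ph = lf$slope,
       slope_magnitude = round(abs(lf$slope)))
}
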