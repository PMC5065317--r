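# Conductance transforms and leak handling: chord conductance from
# current, linear leak estimation over a stated voltage window, leak
# subtraction, and amplitude normalization.

#' Chord conductance from current
#'
#' `G = I / (V - E_rev)` in nS (pA / mV). Points inside a guard band
#' around the reversal potential are undefined: they are returned as
#' `NA` and flagged via the `"undefined"` attribute, never interpolated.
#'
#' @param i Current(s), pA.
#' @param v Membrane potential(s), mV.
#' @param e_rev Reversal potential, mV.
#' @param guard_mv Half-width of the exclusion band around `e_rev`
#'   (default 1 mV).
#' @return Conductance(s) in nS with logical attribute `undefined`.
#' @export
conductance_from_current <- function(i, v, e_rev, guard_mv = 1) {
  if (length(i) != length(v)) .hv_err("i and v must have equal length")
  undef <- abs(v - e_rev) < guard_mv
  g <- ifelse(undef, NA_real_, i / (v - e_rev))
  if (any(undef)) {
    warning(warningCondition(
      sprintf("%d point(s) within %g mV of E_rev flagged as undefined", sum(undef), guard_mv),
      class = c("hvgate_undefined_point", "warning", "condition")))
  }
  structure(g, undefined = undef)
}

#' Add chord conductance to an `iv_table`
#'
#' Fills the `g_step` column with `i_step / (V - e_rev)`.
#'
#' @param iv An `iv_table`.
#' @param e_rev Reversal potential, mV.
#' @inheritParams conductance_from_current
#' @return The table with `g_step` populated (NA in the guard band).
#' @export
add_g_step <- function(iv, e_rev, guard_mv = 1) {
  g <- suppressWarnings(conductance_from_current(iv$i_step, iv$step_voltage,
                                                 e_rev, guard_mv))
  iv$g_step <- as.numeric(g)
  attr(iv, "provenance") <- c(attr(iv, "provenance"), list(e_rev = e_rev))
  iv
}

#' Linear leak estimate over a voltage window
#'
#' Ordinary least squares line through `(V, I_STEP)` restricted to the
#' stated window; the slope is the leak conductance in nS.
#'
#' @param iv An `iv_table` (or data.frame with `step_voltage`, `i_step`).
#' @param window Two-element voltage window `(lo, hi)` in mV; the
#'   default 0..+50 mV targets the flat segment of a U-shaped relation.
#' @return A `leak_estimate`: `g_leak` (nS), `i_offset` (pA at 0 mV),
#'   `window`, `n_points`.
#' @export
estimate_leak <- function(iv, window = c(0, 50)) {
  if (diff(window) <= 0) .hv_err("leak window must be non-degenerate")
  sel <- iv$step_voltage >= window[1] & iv$step_voltage <= window[2]
  if (sum(sel) < 2L) .hv_err("need at least 2 points in the leak window")
  cf <- stats::coef(stats::lm(i_step ~ step_voltage, data = iv[sel, ]))
  structure(list(g_leak = unname(cf[2]), i_offset = unname(cf[1]),
                 window = window, n_points = sum(sel)),
            class = "leak_estimate")
}

#' @export
print.leak_estimate <- function(x, ...) {
  cat(sprintf("Leak: g = %.3g nS, offset = %.3g pA (window %g..%g mV, n = %d)\n",
              x$g_leak, x$i_offset, x$window[1], x$window[2], x$n_points))
  invisible(x)
}

#' Subtract a linear leak from an `iv_table`
#'
#' Removes `g_leak * V + i_offset` from the current columns and `g_leak`
#' from `g_step`. The input table is not modified.
#'
#' @param iv An `iv_table`.
#' @param leak A `leak_estimate` (or list with `g_leak`, `i_offset`).
#' @param columns Current columns to correct (default `i_step`, `i_tail`).
#' @return A leak-subtracted copy of the table.
#' @export
subtract_leak <- function(iv, leak, columns = c("i_step", "i_tail")) {
  i_leak <- leak$g_leak * iv$step_voltage + leak$i_offset
  for (cl in intersect(columns, names(iv))) iv[[cl]] <- iv[[cl]] - i_leak
  if ("g_step" %in% names(iv) && any(is.finite(iv$g_step))) {
    iv$g_step <- iv$g_step - leak$g_leak
  }
  attr(iv, "provenance") <- c(attr(iv, "provenance"),
                              list(leak_subtracted = unclass(leak)))
  iv
}

#' Normalize amplitudes to the value at a reference voltage
#'
#' Pure helper used before averaging across cells: divides `values` by
#' the value at the grid point closest to `v_ref`.
#'
#' @param v Voltages, mV.
#' @param values Amplitudes (currents or conductances).
#' @param v_ref Reference voltage, mV (default +100).
#' @return Rescaled values.
#' @export
normalize_at <- function(v, values, v_ref = 100) {
  ref <- values[which.min(abs(v - v_ref))]
  if (ref == 0) .hv_err("reference amplitude is zero; cannot normalize")
  values / ref
}
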