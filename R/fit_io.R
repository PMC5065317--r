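# Fit-result serialization: one-line legend-style summaries, JSON
# bundles, and a flat CSV-ready summary table.

#' One-line, figure-legend-style summary of a fit result
#'
#' @param fit A `boltzmann_fit`, `gaussian_fit`, `linear_fit`,
#'   `exp_fit`, or `leak_estimate`.
#' @return A character scalar.
#' @export
fit_summary_line <- function(fit) {
  if (inherits(fit, "boltzmann_fit")) {
    sprintf("Boltzmann (%s): y_max = %.3g, y_min = %.3g, V_0.5 = %.1f mV, dx = %.1f%s",
            fit$polarity, fit$y_max, fit$y_min, fit$v_half, fit$slope_dx,
            if (length(fit$constraints)) paste0(" [fixed: ", paste(fit$constraints, collapse = ", "), "]")
            else "")
  } else if (inherits(fit, "gaussian_fit")) {
    sprintf("Gaussian: A = %.3g, omega = %.1f, V_PEAK = %+.1f mV (window %g..%g mV)%s",
            fit$area_a, fit$omega, fit$v_peak, fit$window[1], fit$window[2],
            if (length(fit$constraints)) paste0(" [fixed: ", paste(fit$constraints, collapse = ", "), "]")
            else "")
  } else if (inherits(fit, "linear_fit")) {
    sprintf("Linear: slope = %.3g, intercept = %.3g, R = %.2f (n = %d)",
            fit$slope, fit$intercept, fit$pearson_r, fit$n)
  } else if (inherits(fit, "exp_fit")) {
    sprintf("Exponential: I0 = %.3g pA, A = %.3g pA, tau = %.3g ms, I_TAIL = %.3g pA",
            fit$i0, fit$amplitude, fit$tau, fit$i_tail)
  } else if (inherits(fit, "leak_estimate")) {
    sprintf("Leak: g = %.3g nS, offset = %.3g pA (window %g..%g mV)",
            fit$g_leak, fit$i_offset, fit$window[1], fit$window[2])
  } else {
    .hv_err("unsupported fit class")
  }
}

#' Serialize fit results to JSON
#'
#' Writes one or more fit results (parameters, constraints, windows,
#' residual sums) to a JSON file.
#'
#' @param fits A single fit object or a named list of them.
#' @param path Output path.
#' @export
write_fit_json <- function(fits, path) {
  if (!is.list(fits) || !is.null(attr(fits, "class"))) fits <- list(fit = fits)
  payload <- lapply(fits, function(f) c(list(class = class(f)[1]), unclass(f)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Flat summary table of fit results
#'
#' @param fits Named list of fit objects.
#' @return data.frame with one row per fit: name, class, key parameters
#'   and a legend-style summary string.
#' @export
fits_summary_table <- function(fits) {
  stopifnot(is.list(fits))
  if (is.null(names(fits))) names(fits) <- paste0("fit", seq_along(fits))
  grab <- function(f, field) if (!is.null(f[[field]])) f[[field]] else NA_real_
  data.frame(
    name = names(fits),
    class = vapply(fits, function(f) class(f)[1], ""),
    v_half = vapply(fits, grab, 0, "v_half"),
    slope_dx = vapply(fits, grab, 0, "slope_dx"),
    v_peak = vapply(fits, grab, 0, "v_peak"),
    omega = vapply(fits, grab, 0, "omega"),
    y_max = vapply(fits, grab, 0, "y_max"),
    slope = vapply(fits, grab, 0, "slope"),
    pearson_r = vapply(fits, grab, 0, "pearson_r"),
    rss = vapply(fits, grab, 0, "rss"),
    summary = vapply(fits, fit_summary_line, ""),
    row.names = NULL
  )
}
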