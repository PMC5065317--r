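# First-derivative analysis: numerical dG/dV on a (possibly nonuniform)
# voltage grid and a Gaussian fit whose center V_PEAK estimates the
# Boltzmann midpoint when the G-V curve is truncated (the derivative of
# a logistic peaks at its midpoint).

#' Numerical derivative of a G-V relation
#'
#' Central differences on the measurement grid (nonuniform-grid
#' three-point weights at interior points, one-sided two-point
#' differences at the ends); the derivative is reported at the
#' measurement voltages.
#'
#' @param v Voltages, mV (strictly increasing after sorting; duplicates
#'   are an error).
#' @param g Conductances, nS.
#' @return data.frame with columns `v` (mV) and `dgdv` (nS/mV).
#' @export
numeric_derivative <- function(v, g) {
  if (length(v) != length(g)) .hv_err("v and g must have equal length")
  if (length(v) < 3L) .hv_err("need at least 3 points")
  ord <- order(v)
  v <- v[ord]; g <- g[ord]
  if (any(diff(v) == 0)) .hv_err("duplicate voltages")
  n <- length(v)
  d <- numeric(n)
  d[1] <- (g[2] - g[1]) / (v[2] - v[1])
  d[n] <- (g[n] - g[n - 1]) / (v[n] - v[n - 1])
  i <- 2:(n - 1)
  h0 <- v[i] - v[i - 1]
  h1 <- v[i + 1] - v[i]
  d[i] <- (h0^2 * g[i + 1] - h1^2 * g[i - 1] + (h1^2 - h0^2) * g[i]) /
    (h0 * h1 * (h0 + h1))
  data.frame(v = v, dgdv = d)
}

.gauss_model <- function(v, baseline, area_a, omega, v_peak) {
  baseline + (area_a / (omega * sqrt(pi / 2))) * exp(-2 * (v - v_peak)^2 / omega^2)
}

#' Gaussian fit to a dG/dV-V relation (V_PEAK estimator)
#'
#' Least-squares fit of the area-form Gaussian
#' `dG/dV = (dG/dV)_0 + (A / (omega * sqrt(pi/2))) * exp(-2 (V - V_PEAK)^2 / omega^2)`
#' over a stated voltage window. The center `v_peak` estimates the
#' position of the underlying G-V relation even when neither plateau is
#' reached. The width `omega` may be held fixed (e.g. constrained to the
#' value fitted on a better-determined dataset).
#'
#' @param v Voltages, mV.
#' @param dgdv Derivative values, nS/mV.
#' @param window Two-element voltage window `(lo, hi)` in mV over which
#'   to fit (default: the full data range).
#' @param fixed_omega Optional width (mV) held exactly during the fit.
#' @param fixed_baseline Optional baseline held exactly during the fit.
#' @return A `gaussian_fit`: `baseline`, `area_a`, `omega` (mV),
#'   `v_peak` (mV), `window`, `constraints`, `rss`, `n_points`,
#'   `flagged` (TRUE when convergence is suspect or `v_peak` falls
#'   outside the window extended by one width).
#' @export
fit_gaussian_peak <- function(v, dgdv, window = range(v), fixed_omega = NULL,
                              fixed_baseline = NULL) {
  sel <- is.finite(v) & is.finite(dgdv) & v >= window[1] & v <= window[2]
  if (sum(sel) < 5L) .hv_err("need at least 5 points in the fit window")
  vv <- v[sel]; yy <- dgdv[sel]
  ord <- order(vv); vv <- vv[ord]; yy <- yy[ord]

  base0 <- if (is.null(fixed_baseline)) (yy[1] + yy[length(yy)]) / 2 else fixed_baseline
  idx <- which.max(abs(yy - base0))
  v_peak0 <- vv[idx]
  height0 <- yy[idx] - base0
  # width from the half-height span, if resolvable
  half <- abs(yy - base0) >= abs(height0) / 2
  w_span <- diff(range(vv[half]))
  omega0 <- if (!is.null(fixed_omega)) fixed_omega
            else if (is.finite(w_span) && w_span > 0) w_span / 1.177
            else diff(range(vv)) / 4
  a0 <- height0 * omega0 * sqrt(pi / 2)

  fixed <- c(if (!is.null(fixed_omega)) c(omega = fixed_omega),
             if (!is.null(fixed_baseline)) c(baseline = fixed_baseline))
  par_names <- c("baseline", "area_a", "omega", "v_peak")
  free <- setdiff(par_names, names(fixed))
  p0 <- c(baseline = base0, area_a = a0, omega = omega0, v_peak = v_peak0)
  full <- function(par_free) { p <- p0; p[free] <- par_free; p[names(fixed)] <- fixed; p }
  resid_fn <- function(par_free) {
    p <- full(par_free)
    yy - .gauss_model(vv, p[["baseline"]], p[["area_a"]], p[["omega"]], p[["v_peak"]])
  }
  lower <- c(baseline = -Inf, area_a = -Inf, omega = 1e-6, v_peak = -Inf)[free]
  fit <- minpack.lm::nls.lm(par = p0[free], lower = lower, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 5)) {
    stop(errorCondition(
      sprintf("Gaussian fit failed to converge: %s", fit$message),
      class = c("hvgate_fit_failure", "error", "condition")))
  }
  p <- full(fit$par)
  flagged <- p[["v_peak"]] < window[1] - p[["omega"]] ||
    p[["v_peak"]] > window[2] + p[["omega"]]
  structure(list(baseline = unname(p[["baseline"]]), area_a = unname(p[["area_a"]]),
                 omega = unname(p[["omega"]]), v_peak = unname(p[["v_peak"]]),
                 window = window, constraints = names(fixed),
                 rss = sum(fit$fvec^2), n_points = length(vv),
                 flagged = flagged),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(fit_summary_line(x), "\n")
  invisible(x)
}

#' @export
predict.gaussian_fit <- function(object, v, ...) {
  .gauss_model(v, object$baseline, object$area_a, object$omega, object$v_peak)
}
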