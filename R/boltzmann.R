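# Boltzmann conductance-voltage fitting. Slope factors are always
# stored positive; gating direction is an explicit polarity flag mapped
# to the sign inside the exponential. Any parameter may be held fixed,
# and several datasets may be fit jointly with shared parameters.

#' Evaluate a Boltzmann activation curve
#'
#' `y(V) = (y_max - y_min) / (1 + exp(s (V - v_half)/dx)) + y_min`,
#' `s = +1` for hyperpolarization-activated (falling) and `-1` for
#' depolarization-activated (rising) curves. `y_max` is the plateau on
#' the activated side.
#'
#' @param v Voltages, mV.
#' @param v_half Midpoint, mV.
#' @param slope_dx Slope factor, mV (> 0).
#' @param y_max,y_min Plateau amplitudes.
#' @param polarity `"depolarization"` or `"hyperpolarization"`.
#' @return Curve values at `v`.
#' @export
boltzmann_curve <- function(v, v_half, slope_dx, y_max = 1, y_min = 0,
                            polarity = c("depolarization", "hyperpolarization")) {
  polarity <- match.arg(polarity)
  s <- if (polarity == "hyperpolarization") 1 else -1
  (y_max - y_min) / (1 + exp(s * (v - v_half) / slope_dx)) + y_min
}

.boltz_params <- c("v_half", "slope_dx", "y_max", "y_min")

.boltz_start <- function(v, y, polarity) {
  ord <- order(v); v <- v[ord]; y <- y[ord]
  k <- max(1L, min(3L, length(v) %/% 4L))
  y_lo_v <- mean(y[seq_len(k)])            # plateau at most negative V
  y_hi_v <- mean(y[seq(length(y) - k + 1L, length(y))])
  if (polarity == "depolarization") {
    y_max0 <- y_hi_v; y_min0 <- y_lo_v
  } else {
    y_max0 <- y_lo_v; y_min0 <- y_hi_v
  }
  mid <- (y_max0 + y_min0) / 2
  v_half0 <- v[which.min(abs(y - mid))]
  slope_emp <- max(abs(diff(y) / diff(v)))
  dx0 <- if (is.finite(slope_emp) && slope_emp > 0) {
    abs(y_max0 - y_min0) / (4 * slope_emp)
  } else {
    diff(range(v)) / 10
  }
  dx0 <- min(max(dx0, 1e-2), 10 * diff(range(v)))
  c(v_half = v_half0, slope_dx = dx0, y_max = y_max0, y_min = y_min0)
}

#' Fit a Boltzmann function to (voltage, amplitude) data
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of
#' [boltzmann_curve()]. Any subset of `v_half`, `slope_dx`, `y_max`,
#' `y_min` may be constrained to a supplied value; constrained
#' parameters are returned exactly as supplied.
#'
#' @param v Voltages, mV.
#' @param y Amplitudes (tail current, pA, or conductance, nS).
#' @param polarity Gating direction of the curve (see [boltzmann_curve()]).
#' @param constraints Named list of fixed parameter values, e.g.
#'   `list(v_half = -189)`.
#' @param start Optional named vector of starting values for free
#'   parameters (defaults are data-driven).
#' @return A `boltzmann_fit`: fitted `v_half`, `slope_dx`, `y_max`,
#'   `y_min`, `polarity`, `constraints` (names of fixed parameters),
#'   `rss`, `n_points`, `flagged`.
#' @examples
#' v <- seq(-60, 120, 10)
#' y <- boltzmann_curve(v, 26.3, 16.3, y_max = 1)
#' fit_boltzmann(v, y, "depolarization")
#' @export
fit_boltzmann <- function(v, y, polarity = c("depolarization", "hyperpolarization"),
                          constraints = list(), start = NULL) {
  polarity <- match.arg(polarity)
  keep <- is.finite(v) & is.finite(y)
  v <- v[keep]; y <- y[keep]
  if (!all(names(constraints) %in% .boltz_params)) {
    .hv_err(sprintf("unknown constraint(s): %s",
                    paste(setdiff(names(constraints), .boltz_params), collapse = ", ")))
  }
  free <- setdiff(.boltz_params, names(constraints))
  if (length(v) < max(length(free), 2L)) .hv_err("not enough points for the free parameters")

  p0 <- .boltz_start(v, y, polarity)
  if (!is.null(start)) p0[names(start)] <- start
  full <- function(par_free) {
    p <- p0
    p[free] <- par_free
    p[names(constraints)] <- unlist(constraints)
    p
  }
  resid_fn <- function(par_free) {
    p <- full(par_free)
    y - boltzmann_curve(v, p[["v_half"]], p[["slope_dx"]], p[["y_max"]],
                        p[["y_min"]], polarity)
  }
  lower <- c(v_half = -Inf, slope_dx = 1e-6, y_max = -Inf, y_min = -Inf)[free]
  fit <- minpack.lm::nls.lm(par = p0[free], lower = lower, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 5)) {
    stop(errorCondition(
      sprintf("Boltzmann fit failed to converge: %s", fit$message),
      class = c("hvgate_fit_failure", "error", "condition")))
  }
  p <- full(fit$par)
  flat <- diff(range(y)) < 1e-12 * max(1, max(abs(y)))
  flagged <- flat || p[["slope_dx"]] <= 2e-6
  structure(list(v_half = unname(p[["v_half"]]), slope_dx = unname(p[["slope_dx"]]),
                 y_max = unname(p[["y_max"]]), y_min = unname(p[["y_min"]]),
                 polarity = polarity, constraints = names(constraints),
                 rss = sum(fit$fvec^2), n_points = length(v),
                 flagged = flagged),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(fit_summary_line(x), "\n")
  invisible(x)
}

#' @export
predict.boltzmann_fit <- function(object, v, ...) {
  boltzmann_curve(v, object$v_half, object$slope_dx, object$y_max,
                  object$y_min, object$polarity)
}

#' Joint Boltzmann fit of several datasets with shared parameters
#'
#' Fits one Boltzmann per dataset by a single least-squares problem in
#' which the parameters named in `share` take a common value across
#' datasets (e.g. a shared slope factor across pH conditions).
#' `constraints` fixes parameters (shared or per-dataset) to supplied
#' values.
#'
#' @param datasets List of data.frames/lists, each with elements `v`
#'   and `y`.
#' @param polarity Common gating polarity.
#' @param share Character vector of parameter names
#'   (`"v_half"`, `"slope_dx"`, `"y_max"`, `"y_min"`) shared across datasets.
#' @param constraints Named list of fixed values (applied to every
#'   dataset; a shared parameter may also be fixed).
#' @return List of `boltzmann_fit` objects (one per dataset, shared
#'   parameters identical across them) with attribute `rss` (joint).
#' @export
fit_boltzmann_joint <- function(datasets, polarity = c("depolarization", "hyperpolarization"),
                                share = "slope_dx", constraints = list()) {
  polarity <- match.arg(polarity)
  stopifnot(length(datasets) >= 1L)
  share <- intersect(share, .boltz_params)
  fixed <- names(constraints)
  n <- length(datasets)
  starts <- lapply(datasets, function(d) .boltz_start(d$v, d$y, polarity))

  # parameter vector layout: shared free params, then per-dataset free params
  shared_free <- setdiff(share, fixed)
  per_free <- setdiff(.boltz_params, union(share, fixed))
  par0 <- c(
    stats::setNames(colMeans(do.call(rbind, starts))[shared_free], shared_free),
    unlist(lapply(seq_len(n), function(i) {
      stats::setNames(starts[[i]][per_free], paste0(per_free, ".", i))
    }))
  )
  assemble <- function(par, i) {
    p <- starts[[i]]
    p[fixed] <- unlist(constraints)
    if (length(shared_free)) p[shared_free] <- par[shared_free]
    if (length(per_free)) p[per_free] <- par[paste0(per_free, ".", i)]
    p
  }
  resid_fn <- function(par) {
    unlist(lapply(seq_len(n), function(i) {
      p <- assemble(par, i)
      datasets[[i]]$y - boltzmann_curve(datasets[[i]]$v, p[["v_half"]],
                                        p[["slope_dx"]], p[["y_max"]],
                                        p[["y_min"]], polarity)
    }))
  }
  lower <- rep(-Inf, length(par0))
  names(lower) <- names(par0)
  lower[grepl("^slope_dx", names(lower))] <- 1e-6
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 1000))
  if (fit$info %in% c(0, 5)) {
    stop(errorCondition(
      sprintf("joint Boltzmann fit failed to converge: %s", fit$message),
      class = c("hvgate_fit_failure", "error", "condition")))
  }
  out <- lapply(seq_len(n), function(i) {
    p <- assemble(fit$par, i)
    ri <- datasets[[i]]$y - boltzmann_curve(datasets[[i]]$v, p[["v_half"]],
                                            p[["slope_dx"]], p[["y_max"]],
                                            p[["y_min"]], polarity)
    structure(list(v_half = unname(p[["v_half"]]), slope_dx = unname(p[["slope_dx"]]),
                   y_max = unname(p[["y_max"]]), y_min = unname(p[["y_min"]]),
                   polarity = polarity,
                   constraints = union(fixed, paste0("shared:", share)),
                   rss = sum(ri^2), n_points = length(datasets[[i]]$v),
                   flagged = FALSE),
              class = "boltzmann_fit")
  })
  attr(out, "rss") <- sum(fit$fvec^2)
  out
}
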