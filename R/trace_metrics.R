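# Per-sweep measurements: step current, mono-exponentially extrapolated
# instantaneous tail current, tail-derived reversal potential, and the
# operational activation threshold V_THR.

#' Step current from a single trace
#'
#' @param time,current Trace arrays (ms, pA).
#' @param window Two-element `(start, end)` in ms delimiting the step
#'   epoch (start inclusive, end exclusive).
#' @param policy `"peak"` (default): signed current of largest magnitude
#'   within the window; `"steady"`: mean over the final 10% of the window.
#' @return Current in pA.
#' @export
i_step_from_trace <- function(time, current, window, policy = c("peak", "steady")) {
  policy <- match.arg(policy)
  sel <- time >= window[1] & time < window[2]
  if (!any(sel)) .hv_err("empty step window")
  i <- current[sel]
  if (policy == "peak") {
    i[which.max(abs(i))]
  } else {
    t_sel <- time[sel]
    tail_sel <- t_sel >= window[2] - 0.1 * (window[2] - window[1])
    mean(i[tail_sel])
  }
}

#' Step currents for every sweep in a sweep set
#'
#' Applies [i_step_from_trace()] to the test-step epoch of each sweep.
#'
#' @param sweeps A `sweep_set`.
#' @inheritParams i_step_from_trace
#' @return Numeric vector, one I_STEP (pA) per step voltage.
#' @export
measure_i_step <- function(sweeps, policy = c("peak", "steady")) {
  stopifnot(inherits(sweeps, "sweep_set"))
  policy <- match.arg(policy)
  ep <- .protocol_epochs(sweeps$protocol)
  apply(sweeps$currents, 2, function(i) {
    i_step_from_trace(sweeps$time_ms, i,
                      c(ep[["baseline_end"]], ep[["step_end"]]), policy)
  })
}

# crude log-linear time-constant guess over a decaying segment
.tau_guess <- function(t, i, t0) {
  i_inf <- mean(utils::tail(i, max(3L, ceiling(length(i) * 0.1))))
  dev <- i - i_inf
  keep <- abs(dev) > 0.05 * max(abs(dev))
  if (sum(keep) < 3L || max(abs(dev)) == 0) return(NA_real_)
  fit <- stats::lm(log(abs(dev[keep])) ~ I(t[keep] - t0))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) NA_real_ else -1 / slope
}

#' Mono-exponential tail-current fit
#'
#' Fits `I(t) = I0 + A * exp(-(t - tail_onset)/tau)` over `fit_window`
#' by nonlinear least squares and extrapolates to the instant of the
#' voltage change: the reported instantaneous tail current is `I0 + A`.
#'
#' @param time,current Trace arrays (ms, pA).
#' @param tail_onset Time of the step-to-tail transition, ms.
#' @param fit_window Two-element `(start, end)` in ms. Default: starts
#'   two samples after `tail_onset` (skipping the instantaneous-jump
#'   sample) and ends at `tail_onset + 5 * tau_guess`.
#' @return An object of class `exp_fit`: `i0` (plateau, pA), `amplitude`
#'   (pA), `tau` (ms), `i_tail` (`i0 + amplitude`), `rss`, `window`,
#'   `flagged` (TRUE if tau ran to a bound or convergence is suspect).
#' @export
fit_tail_exponential <- function(time, current, tail_onset, fit_window = NULL) {
  dt <- stats::median(diff(time))
  in_tail <- time >= tail_onset
  if (sum(in_tail) < 5L) .hv_err("tail epoch holds fewer than 5 samples")
  if (is.null(fit_window)) {
    tau0 <- .tau_guess(time[in_tail], current[in_tail], tail_onset)
    if (!is.finite(tau0)) tau0 <- (max(time) - tail_onset) / 5
    fit_window <- c(tail_onset + 2 * dt,
                    min(max(time), tail_onset + 5 * tau0))
  }
  sel <- time >= fit_window[1] & time <= fit_window[2]
  if (sum(sel) < 5L) .hv_err("tail fit window holds fewer than 5 samples")
  t <- time[sel]; i <- current[sel]

  i0_start <- mean(utils::tail(i, max(3L, ceiling(length(i) * 0.1))))
  tau_start <- .tau_guess(t, i, tail_onset)
  if (!is.finite(tau_start)) tau_start <- (fit_window[2] - fit_window[1]) / 3
  a_start <- (i[1] - i0_start) / exp(-(t[1] - tail_onset) / tau_start)
  if (!is.finite(a_start)) a_start <- i[1] - i0_start

  resid_fn <- function(par) {
    i - (par[1] + par[2] * exp(-(t - tail_onset) / par[3]))
  }
  tau_lo <- dt / 10
  tau_hi <- 100 * (fit_window[2] - fit_window[1])
  fit <- minpack.lm::nls.lm(
    par = c(i0 = i0_start, A = a_start, tau = tau_start),
    lower = c(-Inf, -Inf, tau_lo), upper = c(Inf, Inf, tau_hi),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 5)) {
    stop(errorCondition(
      sprintf("tail exponential fit failed to converge (info %d): %s",
              fit$info, fit$message),
      class = c("hvgate_fit_failure", "error", "condition")))
  }
  par <- fit$par
  flagged <- par[["tau"]] <= tau_lo * 1.001 || par[["tau"]] >= tau_hi * 0.999
  structure(list(i0 = par[["i0"]], amplitude = par[["A"]], tau = par[["tau"]],
                 i_tail = par[["i0"]] + par[["A"]],
                 rss = sum(fit$fvec^2), window = fit_window,
                 flagged = flagged),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Tail fit: I0 = %.3g pA, A = %.3g pA, tau = %.3g ms -> instantaneous I_TAIL = %.3g pA%s\n",
              x$i0, x$amplitude, x$tau, x$i_tail,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Build a per-voltage measurement table from a sweep set
#'
#' Measures I_STEP during each test step and the instantaneous tail
#' current (mono-exponential extrapolation) after it, yielding one row
#' per step voltage. The `g_step` column is left `NA` until conductance
#' is computed (see [conductance_from_current()]).
#'
#' @param sweeps A `sweep_set`.
#' @param i_step_policy Passed to [measure_i_step()].
#' @param tail_fit_window Optional explicit fit window (ms) shared by
#'   all sweeps; by default each sweep chooses its own (see
#'   [fit_tail_exponential()]).
#' @return An `iv_table`: data.frame with columns `step_voltage`,
#'   `i_step`, `i_tail`, `i_tail_tau`, `g_step`; the recording
#'   conditions and measurement windows travel as attributes.
#' @export
sweep_iv_table <- function(sweeps, i_step_policy = "peak", tail_fit_window = NULL) {
  stopifnot(inherits(sweeps, "sweep_set"))
  ep <- .protocol_epochs(sweeps$protocol)
  i_step <- measure_i_step(sweeps, i_step_policy)
  tails <- lapply(seq_len(ncol(sweeps$currents)), function(j) {
    fit_tail_exponential(sweeps$time_ms, sweeps$currents[, j],
                         tail_onset = ep[["step_end"]],
                         fit_window = tail_fit_window)
  })
  out <- data.frame(step_voltage = sweeps$protocol$step_voltages,
                    i_step = unname(i_step),
                    i_tail = vapply(tails, `[[`, 0, "i_tail"),
                    i_tail_tau = vapply(tails, `[[`, 0, "tau"),
                    g_step = NA_real_)
  out <- out[order(out$step_voltage), ]
  rownames(out) <- NULL
  structure(out,
            class = c("iv_table", "data.frame"),
            conditions = sweeps$conditions,
            provenance = list(i_step_policy = i_step_policy,
                              step_window = unname(ep[1:2]),
                              tail_onset = unname(ep[["step_end"]])))
}

#' Reversal potential from instantaneous tail currents
#'
#' For a sweep set in which the activating step is fixed and the tail
#' voltage varies, fits each tail mono-exponentially, extrapolates to
#' the instant of repolarization, and locates the zero crossing of
#' instantaneous I_TAIL versus tail voltage.
#'
#' @param sweeps A `sweep_set` whose protocol carries one tail voltage
#'   per step; the tail voltages must bracket the zero crossing.
#' @param method `"interpolate"` (default): linear interpolation between
#'   the bracketing points; `"fit"`: zero of a linear fit over all points.
#' @return Reversal potential in mV.
#' @export
estimate_erev_from_tails <- function(sweeps, method = c("interpolate", "fit")) {
  method <- match.arg(method)
  stopifnot(inherits(sweeps, "sweep_set"))
  ep <- .protocol_epochs(sweeps$protocol)
  v_tails <- rep_len(sweeps$protocol$v_tail, length(sweeps$protocol$step_voltages))
  i_tail <- vapply(seq_len(ncol(sweeps$currents)), function(j) {
    fit_tail_exponential(sweeps$time_ms, sweeps$currents[, j],
                         tail_onset = ep[["step_end"]])$i_tail
  }, 0)
  ord <- order(v_tails)
  v <- v_tails[ord]; i <- i_tail[ord]
  if (method == "fit") {
    cf <- stats::coef(stats::lm(i ~ v))
    return(unname(-cf[1] / cf[2]))
  }
  sign_change <- which(i[-length(i)] * i[-1] <= 0 & (i[-length(i)] != 0 | i[-1] != 0))
  if (!length(sign_change)) {
    if (any(i == 0)) return(v[which(i == 0)[1]])
    stop(errorCondition("tail currents do not bracket a zero crossing",
                        class = c("hvgate_no_bracket", "error", "condition")))
  }
  k <- sign_change[1]
  v[k] + (0 - i[k]) * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
}

#' Operational activation threshold V_THR
#'
#' A reproducible surrogate for the by-eye threshold call: the smallest
#' step voltage at which the leak-subtracted tail current exceeds both a
#' noise-relative criterion (`k * baseline_sd`) and a
#' fraction-of-maximum criterion (`f * max|i_tail|`), and stays above it
#' at every larger voltage.
#'
#' @param iv An `iv_table` (or data.frame) with ascending `step_voltage`
#'   and a leak-subtracted `i_tail` column.
#' @param baseline_sd Baseline current noise, pA.
#' @param k Noise multiplier (default 3).
#' @param f Fraction of the maximal tail amplitude (default 0.02).
#' @return Threshold voltage in mV.
#' @export
estimate_vthr <- function(iv, baseline_sd = 0, k = 3, f = 0.02) {
  v <- iv$step_voltage
  if (is.unsorted(v, strictly = TRUE)) .hv_err("step voltages must be strictly ascending")
  a <- abs(iv$i_tail)
  thr <- max(k * baseline_sd, f * max(a))
  if (max(a) == 0 || !any(a > thr)) {
    stop(errorCondition("tail currents never exceed the activation criterion",
                        class = c("hvgate_not_activated", "error", "condition")))
  }
  above <- a > thr
  persists <- rev(cumprod(rev(above))) == 1  # TRUE where above here and at all larger V
  if (!any(persists)) {
    stop(errorCondition("tail currents never exceed the activation criterion persistently",
                        class = c("hvgate_not_activated", "error", "condition")))
  }
  v[which(persists)[1]]
}

#' Write / read an `iv_table` as CSV with a JSON provenance side-car
#'
#' Columns: `step_voltage`, `i_step`, `i_tail`, `i_tail_tau`, `g_step`.
#'
#' @param iv An `iv_table`.
#' @param path Base path without extension.
#' @export
write_iv_table <- function(iv, path) {
  utils::write.csv(as.data.frame(iv), paste0(path, ".csv"), row.names = FALSE)
  cond <- attr(iv, "conditions")
  jsonlite::write_json(list(conditions = if (!is.null(cond)) unclass(cond),
                            provenance = attr(iv, "provenance")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_iv_table
#' @export
read_iv_table <- function(path) {
  tab <- utils::read.csv(paste0(path, ".csv"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  cond <- if (!is.null(meta$conditions)) {
    recording_conditions(meta$conditions$ph_i, meta$conditions$ph_o,
                         meta$conditions$temperature)
  }
  structure(tab, class = c("iv_table", "data.frame"),
            conditions = cond, provenance = meta$provenance)
}
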