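# Two-conductance decomposition of a U-shaped, leak-subtracted G-V
# relation into a hyperpolarization-activated (SH) and a
# depolarization-activated (AQ) Boltzmann component.

#' Decompose a U-shaped G-V relation into two Boltzmann components
#'
#' Joint least-squares fit of
#' `G(V) = G_SHmax / (1 + exp((V - v1)/dx1)) + G_AQmax / (1 + exp(-(V - v2)/dx2))`
#' — a falling (hyperpolarization-activated) plus a rising
#' (depolarization-activated) component. Five seeded, jittered restarts
#' guard against component swapping and bad local minima; components
#' are identified by polarity. A component whose fitted maximum
#' collapses toward zero is flagged rather than silently reported.
#'
#' @param v Voltages, mV (should span both activation ranges).
#' @param g Leak-subtracted conductances, nS.
#' @param init Optional named starting values
#'   (`g_sh`, `v_half_sh`, `dx_sh`, `g_aq`, `v_half_aq`, `dx_aq`,
#'   and `offset` when `offset = TRUE`).
#' @param n_starts Number of jittered restarts (default 5).
#' @param seed Seed for the restart jitter.
#' @param offset If TRUE, a free additive constant is included (useful
#'   when decomposing tail-current relations that carry a
#'   voltage-independent leak pedestal).
#' @return A `two_conductance_fit`: `sh` and `aq` (`boltzmann_fit`
#'   objects with `y_min = 0`), `ratio` (`G_AQmax / G_SHmax`), `rss`,
#'   `offset` (0 unless fitted), `collapsed` (character vector naming
#'   collapsed components, empty if none).
#' @export
decompose_two_conductances <- function(v, g, init = NULL, n_starts = 5, seed = 1L,
                                       offset = FALSE) {
  keep <- is.finite(v) & is.finite(g)
  v <- v[keep]; g <- g[keep]
  if (length(v) < (6L + offset)) .hv_err("need more points than free parameters")
  ord <- order(v); v <- v[ord]; g <- g[ord]
  span <- diff(range(v))

  c0 <- if (offset) min(g) else 0
  p0 <- c(g_sh = max(g[1] - c0, 1e-3), v_half_sh = stats::quantile(v, 0.2, names = FALSE),
          dx_sh = span / 12,
          g_aq = max(g[length(g)] - c0, 1e-3), v_half_aq = stats::quantile(v, 0.8, names = FALSE),
          dx_aq = span / 12)
  if (offset) p0 <- c(p0, offset = c0)
  if (!is.null(init)) p0[names(init)] <- unlist(init)

  model <- function(p) {
    (if (offset) p[["offset"]] else 0) +
      p[["g_sh"]] / (1 + exp((v - p[["v_half_sh"]]) / p[["dx_sh"]])) +
      p[["g_aq"]] / (1 + exp(-(v - p[["v_half_aq"]]) / p[["dx_aq"]]))
  }
  lower <- c(g_sh = 0, v_half_sh = -Inf, dx_sh = 0.1,
             g_aq = 0, v_half_aq = -Inf, dx_aq = 0.1)
  if (offset) lower <- c(lower, offset = -Inf)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  best <- NULL
  for (k in seq_len(max(1L, n_starts))) {
    pk <- p0
    if (k > 1L) {  # jitter: multiplicative on amplitudes/slopes, additive on midpoints
      pk[c("g_sh", "g_aq", "dx_sh", "dx_aq")] <-
        pk[c("g_sh", "g_aq", "dx_sh", "dx_aq")] * exp(stats::rnorm(4, 0, 0.3))
      pk[c("v_half_sh", "v_half_aq")] <-
        pk[c("v_half_sh", "v_half_aq")] + stats::rnorm(2, 0, span / 10)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pk, lower = lower, fn = function(p) g - model(p),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info %in% c(0, 5)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  if (is.null(best)) {
    stop(errorCondition("two-conductance decomposition failed to converge from any start",
                        class = c("hvgate_fit_failure", "error", "condition")))
  }
  p <- best$par
  g_scale <- max(abs(g))
  collapsed <- c(if (p[["g_sh"]] < 1e-3 * g_scale) "sh",
                 if (p[["g_aq"]] < 1e-3 * g_scale) "aq")
  mk <- function(gmax, vh, dx, pol) {
    structure(list(v_half = unname(vh), slope_dx = unname(dx),
                   y_max = unname(gmax), y_min = 0, polarity = pol,
                   constraints = "y_min", rss = best$rss,
                   n_points = length(v), flagged = FALSE),
              class = "boltzmann_fit")
  }
  structure(list(sh = mk(p[["g_sh"]], p[["v_half_sh"]], p[["dx_sh"]], "hyperpolarization"),
                 aq = mk(p[["g_aq"]], p[["v_half_aq"]], p[["dx_aq"]], "depolarization"),
                 ratio = unname(p[["g_aq"]] / p[["g_sh"]]),
                 rss = best$rss,
                 offset = if (offset) unname(p[["offset"]]) else 0,
                 collapsed = collapsed),
            class = "two_conductance_fit")
}

#' @export
print.two_conductance_fit <- function(x, ...) {
  cat("Two-conductance decomposition:\n  SH: ")
  cat(fit_summary_line(x$sh), "\n  AQ: ")
  cat(fit_summary_line(x$aq), "\n")
  cat(sprintf("  G_AQmax/G_SHmax = %.3g%s\n", x$ratio,
              if (length(x$collapsed)) paste0(" [collapsed: ",
                                              paste(x$collapsed, collapse = ", "), "]")
              else ""))
  invisible(x)
}
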