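# Whole-cell sweep simulator: two independent Boltzmann-gated proton
# conductances (opposite polarity) plus ohmic leak, first-order gating
# kinetics integrated with the exact exponential update per sample.

#' Steady-state open probability of a gated conductance
#'
#' Boltzmann activation curve with an explicit polarity flag:
#' `p = 1 / (1 + exp(s * (V - V_eff) / dx))` with `s = +1` for a
#' hyperpolarization-activated and `s = -1` for a
#' depolarization-activated conductance. The effective midpoint shifts
#' with extracellular pH: `V_eff = v_half + ph_shift_slope * (pH_o - ph_o_ref)`.
#'
#' @param spec A gated [conductance_spec()] (not ohmic).
#' @param v Membrane potential(s), mV.
#' @param ph_o Extracellular pH; defaults to the spec's reference pH_o
#'   (no shift).
#' @return Open probability in [0, 1], vectorized over `v`.
#' @examples
#' aq <- conductance_spec("AQ", 22.2, v_half = 26.3, slope_dx = 16.3,
#'                        polarity = "depolarization",
#'                        tau_act = 20, tau_deact = 8)
#' open_probability(aq, 26.3)  # 0.5 at the midpoint
#' @export
open_probability <- function(spec, v, ph_o = spec$ph_o_ref) {
  stopifnot(inherits(spec, "conductance_spec"))
  if (spec$is_ohmic) .hv_err("open_probability is undefined for an ohmic leak")
  s <- if (spec$polarity == "hyperpolarization") 1 else -1
  v_eff <- spec$v_half + spec$ph_shift_slope * (ph_o - spec$ph_o_ref)
  1 / (1 + exp(s * (v - v_eff) / spec$slope_dx))
}

# instantaneous blocked fraction; outward-only application is handled
# at the current-assembly stage
.block_fraction <- function(block, v) {
  if (is.null(block)) return(rep(0, length(v)))
  block$max_block_fraction / (1 + exp(-(v - block$v_block_half) / block$k_block))
}

# gating trajectory for one gated conductance across the three epochs;
# exact exponential relaxation toward p_inf(V) within each epoch.
# Boundary samples belong to the *new* epoch (voltage has switched) with
# zero elapsed relaxation, which reproduces the instantaneous jump.
.gate_trajectory <- function(spec, times, epochs, v_hold, v_step, v_tail, ph_o) {
  p_hold <- open_probability(spec, v_hold, ph_o)
  p_step <- open_probability(spec, v_step, ph_o)
  p_tail <- open_probability(spec, v_tail, ph_o)
  relax <- function(m0, p_inf, dt) {
    tau <- if (p_inf > m0) spec$tau_act else spec$tau_deact
    p_inf + (m0 - p_inf) * exp(-dt / tau)
  }
  m <- numeric(length(times))
  in_base <- times < epochs[["baseline_end"]]
  in_step <- !in_base & times < epochs[["step_end"]]
  in_tail <- !in_base & !in_step
  m[in_base] <- p_hold
  m0_step <- p_hold  # holding is long; gate assumed equilibrated
  m[in_step] <- relax(m0_step, p_step, times[in_step] - epochs[["baseline_end"]])
  m0_tail <- relax(m0_step, p_step, epochs[["step_end"]] - epochs[["baseline_end"]])
  m[in_tail] <- relax(m0_tail, p_tail, times[in_tail] - epochs[["step_end"]])
  m
}

#' Simulate a family of voltage-clamp sweeps
#'
#' Builds one current trace per test step. Each gated conductance
#' relaxes mono-exponentially toward its steady-state open probability
#' (time constant `tau_act` when opening, `tau_deact` when closing);
#' current is assembled as
#' `I(t) = sum_g g_max * m_g(t) * (1 - b(V)) * (V - E_H) + g_leak * (V - E_leak)`
#' with the block fraction `b(V)` applied only where the unblocked gated
#' term is outward (positive). `E_H` is the Nernstian proton reversal
#' for the supplied conditions. Optional additive white Gaussian noise.
#'
#' @param specs List of [conductance_spec()] objects (gated and/or ohmic).
#' @param protocol A [step_protocol()].
#' @param conditions A [recording_conditions()].
#' @param noise_sd Current noise standard deviation, pA (0 = noiseless).
#' @param seed Integer RNG seed used when `noise_sd > 0`; recorded in the
#'   metadata either way so runs are reproducible.
#' @return A `sweep_set`: list with elements `time_ms` (shared time
#'   base), `currents` (samples x steps matrix, pA), `protocol`,
#'   `conditions`, and `metadata` (model parameters, noise, seed).
#' @export
simulate_sweep_set <- function(specs, protocol, conditions, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(protocol, "step_protocol"),
            inherits(conditions, "recording_conditions"))
  if (inherits(specs, "conductance_spec")) specs <- list(specs)
  if (!length(specs) || !all(vapply(specs, inherits, TRUE, "conductance_spec"))) {
    .hv_err("specs must be a list of conductance_spec objects")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    .hv_err("noise_sd must be a non-negative scalar (pA)")
  }
  gated <- Filter(function(s) !s$is_ohmic, specs)
  taus <- unlist(lapply(gated, function(s) c(s$tau_act, s$tau_deact)))
  if (length(taus) && protocol$sample_interval > min(taus) / 5) {
    warning(warningCondition(
      sprintf("sample_interval (%g ms) is coarse relative to the fastest gating tau (%g ms)",
              protocol$sample_interval, min(taus)),
      class = c("hvgate_coarse_sampling", "warning", "condition")))
  }

  epochs <- .protocol_epochs(protocol)
  times <- seq(0, epochs[["sweep_end"]], by = protocol$sample_interval)
  e_h <- proton_reversal(conditions)
  nv <- length(protocol$step_voltages)
  v_tails <- rep_len(protocol$v_tail, nv)

  currents <- matrix(0, nrow = length(times), ncol = nv)
  for (j in seq_len(nv)) {
    v_step <- protocol$step_voltages[j]
    v_of_t <- ifelse(times < epochs[["baseline_end"]], protocol$v_hold,
                     ifelse(times < epochs[["step_end"]], v_step, v_tails[j]))
    i_tot <- numeric(length(times))
    for (s in specs) {
      if (s$is_ohmic) {
        i_tot <- i_tot + s$g_max * (v_of_t - s$e_rev_leak)
      } else {
        m <- .gate_trajectory(s, times, epochs, protocol$v_hold, v_step,
                              v_tails[j], conditions$ph_o)
        i_raw <- s$g_max * m * (v_of_t - e_h)
        b <- .block_fraction(s$block, v_of_t)
        i_tot <- i_tot + ifelse(i_raw > 0, i_raw * (1 - b), i_raw)
      }
    }
    currents[, j] <- i_tot
  }
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    currents <- currents + matrix(stats::rnorm(length(currents), 0, noise_sd),
                                  nrow = nrow(currents))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  colnames(currents) <- sprintf("%g", protocol$step_voltages)
  structure(list(time_ms = times, currents = currents,
                 protocol = protocol, conditions = conditions,
                 metadata = list(
                   specs = lapply(specs, .spec_to_list),
                   noise_sd = noise_sd, seed = seed, e_h_mv = e_h)),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("Sweep set: %d sweeps x %d samples (dt = %g ms), pH_i %.1f / pH_o %.1f, noise sd = %g pA\n",
              ncol(x$currents), nrow(x$currents), x$protocol$sample_interval,
              x$conditions$ph_i, x$conditions$ph_o, x$metadata$noise_sd))
  invisible(x)
}

#' Ready-made channel-variant parameter sets
#'
#' Returns named model parameterizations for the channel variants the
#' analyses exercise, each with a 1.5 nS ohmic leak and symmetric pH 6.5
#' recording conditions:
#' \describe{
#'   \item{wt}{a single depolarization-activated conductance (G_AQ) with
#'     slow kinetics; midpoint placed so the operational tail-current
#'     threshold falls near +7 mV.}
#'   \item{r1h}{G_AQ (22.2 nS, V_0.5 +29.4 mV, dx 24.9) plus the
#'     hyperpolarization-activated shuttle conductance G_SH
#'     (4.6 nS, V_0.5 -189 mV, dx 42.1).}
#'   \item{r1h_n4r}{as `r1h` but G_AQ gates at V_0.5 +26.3 mV, dx 16.3
#'     and carries an instantaneous outward-only block, leaving inward
#'     tail currents intact.}
#'   \item{d185a_r1h, d185h_r1h}{as `r1h` with the G_AQ midpoint shifted
#'     +65 and +105 mV respectively.}
#' }
#'
#' @return Named list; each element is `list(specs, conditions)`.
#' @export
reference_parameter_sets <- function() {
  leak <- conductance_spec("LEAK", g_max = 1.5, is_ohmic = TRUE)
  cond <- recording_conditions(ph_i = 6.5, ph_o = 6.5)
  sh <- conductance_spec("SH", g_max = 4.6, v_half = -189, slope_dx = 42.1,
                         polarity = "hyperpolarization",
                         tau_act = 25, tau_deact = 12)
  aq_r1h <- conductance_spec("AQ", g_max = 22.2, v_half = 29.4, slope_dx = 24.9,
                             polarity = "depolarization",
                             tau_act = 20, tau_deact = 8)
  aq_n4r <- conductance_spec("AQ", g_max = 22.2, v_half = 26.3, slope_dx = 16.3,
                             polarity = "depolarization",
                             tau_act = 20, tau_deact = 8,
                             block = block_spec(v_block_half = -60, k_block = 10,
                                                max_block_fraction = 1))
  shift_aq <- function(spec, dv) { spec$v_half <- spec$v_half + dv; spec }
  aq_wt <- conductance_spec("AQ", g_max = 20, v_half = 70, slope_dx = 16.2,
                            polarity = "depolarization",
                            tau_act = 300, tau_deact = 50)
  list(
    wt        = list(specs = list(aq_wt, leak), conditions = cond),
    r1h       = list(specs = list(sh, aq_r1h, leak), conditions = cond),
    r1h_n4r   = list(specs = list(sh, aq_n4r, leak), conditions = cond),
    d185a_r1h = list(specs = list(sh, shift_aq(aq_r1h, 65), leak), conditions = cond),
    d185h_r1h = list(specs = list(sh, shift_aq(aq_r1h, 105), leak), conditions = cond)
  )
}
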