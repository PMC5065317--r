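# Step-protocol and conductance-specification constructors plus their
# JSON/YAML descriptor IO. Units: mV, ms, nS throughout (pA = nS * mV).

.hv_err <- function(msg, class = "hvgate_invalid_argument") {
  stop(errorCondition(msg, class = c(class, "error", "condition")))
}

#' Voltage-step protocol
#'
#' Describes the three-epoch stimulus used throughout: hold at `v_hold`
#' for `pre_step_baseline` ms, step to each of `step_voltages` for
#' `step_duration` ms, then repolarize to `v_tail` for `tail_duration` ms.
#' `v_tail` may be a single voltage (the usual tail protocol) or one
#' voltage per step (a tail family used to measure the reversal
#' potential from instantaneous tail currents).
#'
#' @param v_hold Holding potential, mV.
#' @param step_voltages Test-step potentials, mV (non-empty).
#' @param step_duration Test-step duration, ms.
#' @param v_tail Tail potential(s), mV; length 1 or `length(step_voltages)`.
#' @param tail_duration Tail duration, ms.
#' @param sample_interval Sampling interval, ms; must resolve the
#'   shortest epoch (at most min(durations)/10).
#' @param pre_step_baseline Pre-step baseline duration, ms.
#' @return An object of class `step_protocol`.
#' @examples
#' step_protocol(v_hold = -60, step_voltages = seq(-130, 70, 10),
#'               step_duration = 200, v_tail = -90, tail_duration = 100)
#' @export
step_protocol <- function(v_hold, step_voltages, step_duration,
                          v_tail, tail_duration,
                          sample_interval = 1, pre_step_baseline = 10) {
  if (length(step_voltages) < 1L) .hv_err("step_voltages must be non-empty")
  if (!all(c(step_duration, tail_duration, pre_step_baseline, sample_interval) > 0)) {
    .hv_err("durations and sample_interval must be positive")
  }
  if (sample_interval > min(step_duration, tail_duration, pre_step_baseline) / 10) {
    .hv_err("sample_interval too coarse: must be <= min(durations)/10")
  }
  if (!(length(v_tail) %in% c(1L, length(step_voltages)))) {
    .hv_err("v_tail must have length 1 or one entry per step voltage")
  }
  structure(list(v_hold = v_hold,
                 step_voltages = as.numeric(step_voltages),
                 step_duration = step_duration,
                 v_tail = as.numeric(v_tail),
                 tail_duration = tail_duration,
                 sample_interval = sample_interval,
                 pre_step_baseline = pre_step_baseline),
            class = "step_protocol")
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf("Step protocol: hold %g mV (%g ms) -> steps [%g..%g] mV x %g ms -> tail %s mV x %g ms; dt = %g ms\n",
              x$v_hold, x$pre_step_baseline,
              min(x$step_voltages), max(x$step_voltages), x$step_duration,
              paste(unique(range(x$v_tail)), collapse = ".."), x$tail_duration,
              x$sample_interval))
  invisible(x)
}

# epoch boundary times (ms): baseline ends, step ends, sweep ends
.protocol_epochs <- function(protocol) {
  t1 <- protocol$pre_step_baseline
  t2 <- t1 + protocol$step_duration
  t3 <- t2 + protocol$tail_duration
  c(baseline_end = t1, step_end = t2, sweep_end = t3)
}

#' Voltage-dependent open-channel block
#'
#' An instantaneous (state-free) blocking function applied to outward
#' current only, emulating a tethered cationic blocker that occludes the
#' permeation pathway at depolarized potentials and is relieved
#' immediately upon hyperpolarization. Block fraction is
#' `max_block_fraction / (1 + exp(-(V - v_block_half)/k_block))`.
#'
#' @param v_block_half Midpoint of the block curve, mV.
#' @param k_block Steepness of the block curve, mV (> 0).
#' @param max_block_fraction Maximal blocked fraction in [0, 1].
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(v_block_half, k_block, max_block_fraction) {
  if (!(k_block > 0)) .hv_err("k_block must be positive")
  if (max_block_fraction < 0 || max_block_fraction > 1) {
    .hv_err("max_block_fraction must lie in [0, 1]")
  }
  structure(list(v_block_half = v_block_half, k_block = k_block,
                 max_block_fraction = max_block_fraction,
                 direction = "outward-only"),
            class = "block_spec")
}

#' One gated (or ohmic leak) conductance
#'
#' Parameters of a single conductance in the simulator: a maximal
#' conductance `g_max` (the product of channel number and unitary
#' conductance), a Boltzmann activation curve (midpoint `v_half` at the
#' reference pH_o, slope factor `slope_dx` > 0, explicit gating
#' `polarity`), first-order activation/deactivation time constants, a
#' pH_o-dependent shift of the midpoint, and an optional outward-only
#' block. Ohmic leak conductances set `is_ohmic = TRUE` and ignore the
#' gating fields.
#'
#' @param label Identifier, e.g. "AQ", "SH", "LEAK".
#' @param g_max Maximal conductance, nS (>= 0).
#' @param v_half Boltzmann midpoint at `ph_o_ref`, mV.
#' @param slope_dx Boltzmann slope factor, mV (> 0).
#' @param polarity `"depolarization"` or `"hyperpolarization"` —
#'   which direction of voltage change opens the conductance.
#' @param tau_act,tau_deact Activation/deactivation time constants, ms.
#' @param ph_shift_slope Midpoint shift per pH_o unit, mV (default -40:
#'   alkalinizing the bath by one unit shifts gating ~40 mV negative).
#' @param ph_o_ref Reference pH_o at which `v_half` is stated.
#' @param block Optional [block_spec()].
#' @param is_ohmic If TRUE the conductance is a voltage-independent leak
#'   reversing at `e_rev_leak`.
#' @param e_rev_leak Leak reversal potential, mV (ohmic only).
#' @return An object of class `conductance_spec`.
#' @examples
#' conductance_spec("AQ", g_max = 22.2, v_half = 26.3, slope_dx = 16.3,
#'                  polarity = "depolarization", tau_act = 20, tau_deact = 8)
#' conductance_spec("LEAK", g_max = 1.5, is_ohmic = TRUE)
#' @export
conductance_spec <- function(label, g_max, v_half = NA_real_, slope_dx = NA_real_,
                             polarity = c("depolarization", "hyperpolarization"),
                             tau_act = NA_real_, tau_deact = NA_real_,
                             ph_shift_slope = -40, ph_o_ref = 6.5,
                             block = NULL, is_ohmic = FALSE, e_rev_leak = 0) {
  if (!(g_max >= 0)) .hv_err("g_max must be non-negative")
  if (!is_ohmic) {
    polarity <- match.arg(polarity)
    if (!(is.finite(slope_dx) && slope_dx > 0)) .hv_err("slope_dx must be positive")
    if (!is.finite(v_half)) .hv_err("v_half required for a gated conductance")
    if (!(is.finite(tau_act) && tau_act > 0 && is.finite(tau_deact) && tau_deact > 0)) {
      .hv_err("tau_act and tau_deact must be positive for a gated conductance")
    }
  } else {
    polarity <- NA_character_
  }
  if (!is.null(block) && !inherits(block, "block_spec")) {
    .hv_err("block must be a block_spec or NULL")
  }
  structure(list(label = label, g_max = g_max, v_half = v_half,
                 slope_dx = slope_dx, polarity = polarity,
                 tau_act = tau_act, tau_deact = tau_deact,
                 ph_shift_slope = ph_shift_slope, ph_o_ref = ph_o_ref,
                 block = block, is_ohmic = is_ohmic, e_rev_leak = e_rev_leak),
            class = "conductance_spec")
}

#' @export
print.conductance_spec <- function(x, ...) {
  if (x$is_ohmic) {
    cat(sprintf("<%s> ohmic leak: g = %g nS, E_rev = %g mV\n",
                x$label, x$g_max, x$e_rev_leak))
  } else {
    cat(sprintf("<%s> %s-activated: g_max = %g nS, V_0.5 = %g mV, dx = %g mV, tau = %g/%g ms%s\n",
                x$label, x$polarity, x$g_max, x$v_half, x$slope_dx,
                x$tau_act, x$tau_deact,
                if (is.null(x$block)) "" else " [outward block]"))
  }
  invisible(x)
}

# --- descriptor IO ---------------------------------------------------------

.spec_to_list <- function(spec) {
  out <- unclass(spec)
  if (!is.null(out$block)) out$block <- unclass(out$block)
  out
}

.spec_from_list <- function(x) {
  blk <- NULL
  if (!is.null(x$block)) {
    blk <- block_spec(x$block$v_block_half, x$block$k_block, x$block$max_block_fraction)
  }
  conductance_spec(label = x$label, g_max = x$g_max,
                   v_half = x$v_half %||% NA_real_,
                   slope_dx = x$slope_dx %||% NA_real_,
                   polarity = if (isTRUE(x$is_ohmic)) "depolarization" else x$polarity,
                   tau_act = x$tau_act %||% NA_real_,
                   tau_deact = x$tau_deact %||% NA_real_,
                   ph_shift_slope = x$ph_shift_slope %||% -40,
                   ph_o_ref = x$ph_o_ref %||% 6.5,
                   block = blk,
                   is_ohmic = isTRUE(x$is_ohmic),
                   e_rev_leak = x$e_rev_leak %||% 0)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Write / read a simulation descriptor (protocol + model parameters)
#'
#' Serializes a protocol, recording conditions and a list of conductance
#' specifications to a JSON or YAML file (format chosen by extension:
#' `.json`, `.yml`/`.yaml`), and reads such a descriptor back.
#'
#' @param specs List of [conductance_spec()] objects.
#' @param protocol A [step_protocol()].
#' @param conditions A [recording_conditions()].
#' @param path Output (or input) file path.
#' @return `write_descriptor` returns `path` invisibly;
#'   `read_descriptor` returns `list(specs, protocol, conditions)`.
#' @export
write_descriptor <- function(specs, protocol, conditions, path) {
  payload <- list(
    protocol = unclass(protocol),
    conditions = unclass(conditions),
    conductances = lapply(specs, .spec_to_list)
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(payload, path)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_descriptor
#' @export
read_descriptor <- function(path) {
  payload <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  p <- payload$protocol
  protocol <- step_protocol(v_hold = p$v_hold,
                            step_voltages = unlist(p$step_voltages),
                            step_duration = p$step_duration,
                            v_tail = unlist(p$v_tail),
                            tail_duration = p$tail_duration,
                            sample_interval = p$sample_interval,
                            pre_step_baseline = p$pre_step_baseline)
  cc <- payload$conditions
  conditions <- recording_conditions(cc$ph_i, cc$ph_o, cc$temperature)
  specs <- lapply(payload$conductances, .spec_from_list)
  list(specs = specs, protocol = protocol, conditions = conditions)
}
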