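# Shared builders for simulated recordings used across the test files.

aq_spec <- function(g_max = 22.2, v_half = 26.3, slope_dx = 16.3,
                    tau_act = 20, tau_deact = 8, ...) {
  conductance_spec("AQ", g_max = g_max, v_half = v_half, slope_dx = slope_dx,
                   polarity = "depolarization", tau_act = tau_act,
                   tau_deact = tau_deact, ...)
}

sh_spec <- function(g_max = 4.6, v_half = -189, slope_dx = 42.1,
                    tau_act = 25, tau_deact = 12, ...) {
  conductance_spec("SH", g_max = g_max, v_half = v_half, slope_dx = slope_dx,
                   polarity = "hyperpolarization", tau_act = tau_act,
                   tau_deact = tau_deact, ...)
}

leak_spec <- function(g = 1.5) conductance_spec("LEAK", g_max = g, is_ohmic = TRUE)

std_protocol <- function(step_voltages = seq(-130, 70, 10), v_hold = -60,
                         step_duration = 200, v_tail = -90,
                         tail_duration = 100, sample_interval = 1) {
  step_protocol(v_hold = v_hold, step_voltages = step_voltages,
                step_duration = step_duration, v_tail = v_tail,
                tail_duration = tail_duration, sample_interval = sample_interval)
}

sym_ph <- function() recording_conditions(ph_i = 6.5, ph_o = 6.5)
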