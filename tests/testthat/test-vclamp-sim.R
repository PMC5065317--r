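test_that("open probability has the right midpoint, limits and pH shift", {
  aq <- aq_spec()
  expect_equal(open_probability(aq, 26.3), 0.5)
  expect_equal(open_probability(aq, 1e4), 1)
  expect_equal(open_probability(aq, -1e4), 0)
  sh <- sh_spec()
  expect_equal(open_probability(sh, -189), 0.5)
  expect_equal(open_probability(sh, 1e4), 0)
  # inverse of the logistic: p = 0.9 at v_half + dx ln 9
  expect_equal(open_probability(aq, 26.3 + 16.3 * log(9)), 0.9)
  # one pH_o unit up shifts the midpoint by the configured -40 mV
  expect_equal(open_probability(aq, 26.3 - 40, ph_o = 7.5), 0.5)
  expect_error(open_probability(leak_spec(), 0), class = "hvgate_invalid_argument")
})

test_that("leak-only sweeps are exactly ohmic and time-independent", {
  p <- std_protocol()
  sw <- simulate_sweep_set(list(leak_spec(1.5)), p, sym_ph())
  for (j in seq_along(p$step_voltages)) {
    ep <- c(p$pre_step_baseline, p$pre_step_baseline + p$step_duration)
    in_step <- sw$time_ms >= ep[1] & sw$time_ms < ep[2]
    expect_equal(unique(sw$currents[in_step, j]), 1.5 * p$step_voltages[j])
  }
})

test_that("instantaneous tail amplitude matches the closed-form g*m*(V-E_H)", {
  aq <- aq_spec()
  p <- std_protocol(step_voltages = seq(-40, 80, 20))
  sw <- simulate_sweep_set(list(aq), p, sym_ph())
  onset <- p$pre_step_baseline + p$step_duration
  i_onset <- sw$currents[which(sw$time_ms == onset), ]
  p0 <- open_probability(aq, p$v_hold)
  for (j in seq_along(p$step_voltages)) {
    p_inf <- open_probability(aq, p$step_voltages[j])
    tau <- if (p_inf > p0) aq$tau_act else aq$tau_deact
    m_end <- p_inf + (p0 - p_inf) * exp(-p$step_duration / tau)
    expect_equal(unname(i_onset[j]), aq$g_max * m_end * (p$v_tail - 0),
                 tolerance = 1e-12)
  }
})

test_that("two opposite conductances produce a U-shaped G_STEP-V relation", {
  sw <- simulate_sweep_set(list(sh_spec(), aq_spec(v_half = 29.4, slope_dx = 24.9),
                                leak_spec()),
                           std_protocol(step_voltages = seq(-240, 200, 20)),
                           sym_ph())
  iv <- sweep_iv_table(sw)
  iv <- add_g_step(iv, 0)
  g <- iv$g_step[is.finite(iv$g_step)]
  k <- which.min(g)
  expect_gt(k, 1)
  expect_lt(k, length(g))
  # apparent maxima at the two ends are unequal
  expect_gt(max(g[seq(k, length(g))]), 2 * max(g[seq_len(k)]))
})

test_that("implied gating variables stay within [0, 1] for any step pattern", {
  aq <- aq_spec(g_max = 10)
  p <- std_protocol(step_voltages = c(-150, -20, 35, 120), v_hold = -100,
                    v_tail = -120)
  sw <- simulate_sweep_set(list(aq), p, sym_ph())
  ep <- c(p$pre_step_baseline, p$pre_step_baseline + p$step_duration,
          p$pre_step_baseline + p$step_duration + p$tail_duration)
  v_of_t <- function(j) ifelse(sw$time_ms < ep[1], p$v_hold,
                               ifelse(sw$time_ms < ep[2], p$step_voltages[j], p$v_tail))
  for (j in seq_along(p$step_voltages)) {
    drive <- v_of_t(j) - 0
    m <- sw$currents[, j] / (aq$g_max * drive)
    m <- m[abs(drive) > 1]
    expect_true(all(m >= -1e-12 & m <= 1 + 1e-12))
  }
})

test_that("noiseless simulation is invariant under sample-interval refinement", {
  specs <- list(sh_spec(), aq_spec(), leak_spec())
  p1 <- std_protocol(step_voltages = c(-150, 40), sample_interval = 1)
  p2 <- std_protocol(step_voltages = c(-150, 40), sample_interval = 0.5)
  s1 <- simulate_sweep_set(specs, p1, sym_ph())
  s2 <- simulate_sweep_set(specs, p2, sym_ph())
  common <- match(s1$time_ms, s2$time_ms)
  rel <- abs(s2$currents[common, ] - s1$currents) /
    pmax(abs(s1$currents), 1e-6)
  expect_lt(max(rel), 0.005)  # exact exponential update: step-size free
})

test_that("outward-only block leaves inward currents untouched", {
  blk <- block_spec(v_block_half = -60, k_block = 10, max_block_fraction = 1)
  p <- std_protocol(step_voltages = seq(-120, 80, 20))
  cond <- recording_conditions(6.5, 5.5)  # E_H = +58.2 mV
  s_free <- simulate_sweep_set(list(aq_spec()), p, cond)
  s_blk <- simulate_sweep_set(list(aq_spec(block = blk)), p, cond)
  e_h <- proton_reversal(cond)
  for (j in seq_along(p$step_voltages)) {
    if (p$step_voltages[j] < e_h) {
      ep <- c(p$pre_step_baseline, p$pre_step_baseline + p$step_duration)
      in_step <- s_free$time_ms >= ep[1] & s_free$time_ms < ep[2]
      expect_equal(s_blk$currents[in_step, j], s_free$currents[in_step, j])
    }
  }
  # and outward current is suppressed
  i_free <- measure_i_step(s_free)
  i_blk <- measure_i_step(s_blk)
  hi <- which.max(p$step_voltages)
  expect_lt(i_blk[hi] / i_free[hi], 0.05)
})

test_that("simulation is reproducible for a fixed seed and warns on coarse sampling", {
  p <- std_protocol(step_voltages = c(-100, 50))
  s1 <- simulate_sweep_set(list(aq_spec(), leak_spec()), p, sym_ph(),
                           noise_sd = 5, seed = 7)
  s2 <- simulate_sweep_set(list(aq_spec(), leak_spec()), p, sym_ph(),
                           noise_sd = 5, seed = 7)
  expect_identical(s1$currents, s2$currents)
  s3 <- simulate_sweep_set(list(aq_spec(), leak_spec()), p, sym_ph(),
                           noise_sd = 5, seed = 8)
  expect_false(identical(s1$currents, s3$currents))
  expect_warning(
    simulate_sweep_set(list(aq_spec(tau_act = 3, tau_deact = 3), leak_spec()),
                       p, sym_ph()),
    class = "hvgate_coarse_sampling")
  expect_error(simulate_sweep_set(list(aq_spec()), p, sym_ph(), noise_sd = -1),
               class = "hvgate_invalid_argument")
})

test_that("sweep sets round-trip through CSV + JSON bit-exactly", {
  p <- std_protocol(step_voltages = c(-120, -10, 60))
  sw <- simulate_sweep_set(list(sh_spec(), aq_spec(), leak_spec()), p,
                           recording_conditions(6.5, 7.5), noise_sd = 2, seed = 3)
  base <- file.path(tempdir(), "rt_sweeps")
  write_sweep_set(sw, base)
  back <- read_sweep_set(base)
  expect_identical(back$currents[, 1], sw$currents[, 1])
  expect_identical(unname(back$currents), unname(sw$currents))
  expect_identical(back$time_ms, sw$time_ms)
  expect_equal(back$protocol, sw$protocol)
  expect_equal(back$conditions$ph_o, 7.5)
})

test_that("descriptor files round-trip through JSON and YAML", {
  specs <- list(sh_spec(), aq_spec(block = block_spec(-60, 10, 1)), leak_spec())
  p <- std_protocol(step_voltages = c(-100, 0, 100))
  cond <- recording_conditions(6.5, 5.5)
  for (ext in c("json", "yaml")) {
    f <- file.path(tempdir(), paste0("desc.", ext))
    write_descriptor(specs, p, cond, f)
    d <- read_descriptor(f)
    expect_equal(d$protocol, p)
    expect_equal(d$conditions, cond)
    expect_equal(length(d$specs), 3L)
    expect_equal(d$specs[[2]]$block$k_block, 10)
    s1 <- simulate_sweep_set(specs, p, cond)
    s2 <- simulate_sweep_set(d$specs, d$protocol, d$conditions)
    expect_equal(s2$currents, s1$currents)
  }
})

test_that("reference parameter sets encode the documented variants", {
  refs <- reference_parameter_sets()
  expect_setequal(names(refs),
                  c("wt", "r1h", "r1h_n4r", "d185a_r1h", "d185h_r1h"))
  grab <- function(variant, label) {
    Filter(function(s) identical(s$label, label), refs[[variant]]$specs)[[1]]
  }
  sh <- grab("r1h_n4r", "SH")
  expect_equal(sh$v_half, -189)
  expect_equal(sh$slope_dx, 42.1)
  expect_equal(sh$g_max, 4.6)
  expect_equal(grab("r1h", "LEAK")$g_max, 1.5)
  expect_false(is.null(grab("r1h_n4r", "AQ")$block))
  # D185-like midpoints offset +65 / +105 from the parent
  expect_equal(grab("d185a_r1h", "AQ")$v_half - grab("r1h", "AQ")$v_half, 65)
  expect_equal(grab("d185h_r1h", "AQ")$v_half - grab("r1h", "AQ")$v_half, 105)
  # WT-like: single depolarization-activated conductance, outwardly
  # rectifying I_STEP-V with a linear inward branch
  p <- std_protocol(step_voltages = seq(-100, 150, 10))
  sw <- simulate_sweep_set(refs$wt$specs, p, refs$wt$conditions)
  iv <- sweep_iv_table(sw)
  expect_gt(max(iv$i_step), 10 * abs(min(iv$i_step)))
  inward <- iv$step_voltage <= -20
  lf <- fit_line(iv$step_voltage[inward], iv$i_step[inward])
  expect_gt(lf$pearson_r, 0.9999)
})
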