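test_that("chord conductance transform is exact and guards the reversal point", {
  expect_equal(as.numeric(conductance_from_current(0, -100, 0)), 0)
  expect_equal(as.numeric(conductance_from_current(-1000, -100, 0)), 10)
  expect_warning(g <- conductance_from_current(c(5, 50), c(0.5, 50), 0),
                 class = "hvgate_undefined_point")
  expect_true(is.na(g[1]))
  expect_equal(as.numeric(g[2]), 1)
  expect_identical(attr(g, "undefined"), c(TRUE, FALSE))
})

test_that("linear leak is estimated exactly on ohmic data and subtracts to zero", {
  v <- seq(-100, 100, 10)
  iv <- data.frame(step_voltage = v, i_step = 1.5 * v, i_tail = 1.5 * v)
  lk <- estimate_leak(iv, c(0, 50))
  expect_equal(lk$g_leak, 1.5)
  expect_equal(lk$i_offset, 0, tolerance = 1e-12)
  sub <- subtract_leak(iv, lk)
  expect_equal(max(abs(sub$i_step)), 0, tolerance = 1e-10)
  expect_equal(max(abs(sub$i_tail)), 0, tolerance = 1e-10)
  # zero-leak subtraction is the identity
  id <- subtract_leak(iv, list(g_leak = 0, i_offset = 0))
  expect_equal(id$i_step, iv$i_step)
  expect_error(estimate_leak(iv, c(200, 300)), class = "hvgate_invalid_argument")
})

test_that("leak window on the blocked-variant plateau recovers the injected leak", {
  refs <- reference_parameter_sets()
  sw <- simulate_sweep_set(refs$r1h_n4r$specs,
                           std_protocol(step_voltages = seq(-240, 200, 10)),
                           refs$r1h_n4r$conditions)
  # steady-state I-V: outward conductance is blocked, so 0..+50 mV is leak
  iv <- sweep_iv_table(sw, i_step_policy = "steady")
  lk <- estimate_leak(iv, c(0, 50))
  expect_equal(lk$g_leak, 1.5, tolerance = 0.05)
  # after subtraction the conductance at positive potentials is ~ 0
  iv2 <- subtract_leak(add_g_step(iv, 0), lk)
  expect_lt(max(abs(iv2$g_step[iv2$step_voltage >= 10])), 0.05)
})

test_that("Boltzmann fits recover noiseless parameters from jittered starts", {
  v <- seq(-120, 160, 10)
  truth <- c(v_half = 26.3, slope_dx = 16.3, y_max = 22.2, y_min = 0.4)
  y <- boltzmann_curve(v, truth[1], truth[2], truth[3], truth[4], "depolarization")
  set.seed(11)
  for (k in 1:8) {
    start <- truth * exp(rnorm(4, 0, 0.2))  # documented perturbation range
    f <- fit_boltzmann(v, y, "depolarization", start = start)
    expect_equal(f$v_half, unname(truth[1]), tolerance = 1e-6)
    expect_equal(f$slope_dx, unname(truth[2]), tolerance = 1e-6)
    expect_equal(f$y_max, unname(truth[3]), tolerance = 1e-6)
    expect_equal(f$y_min, unname(truth[4]), tolerance = 1e-6)
  }
  # falling curve, default start
  y2 <- boltzmann_curve(v, -20, 30, 4.6, 0, "hyperpolarization")
  f2 <- fit_boltzmann(v, y2, "hyperpolarization")
  expect_equal(f2$v_half, -20, tolerance = 1e-6)
  expect_equal(f2$slope_dx, 30, tolerance = 1e-6)
})

test_that("constrained Boltzmann parameters are returned exactly as supplied", {
  v <- seq(-240, 0, 10)
  y <- boltzmann_curve(v, -185, 40, 4.8, 0, "hyperpolarization")
  f <- fit_boltzmann(v, y, "hyperpolarization", constraints = list(v_half = -189))
  expect_identical(f$v_half, -189)
  expect_true("v_half" %in% f$constraints)
  f2 <- fit_boltzmann(v, y, "hyperpolarization",
                      constraints = list(slope_dx = 42.1, y_min = 0))
  expect_identical(f2$slope_dx, 42.1)
  expect_identical(f2$y_min, 0)
  expect_error(fit_boltzmann(v, y, "hyperpolarization",
                             constraints = list(nonsense = 1)),
               class = "hvgate_invalid_argument")
})

test_that("joint fits share a single slope factor across pH datasets", {
  v <- seq(-60, 160, 10)
  vh <- c(66.3, 25.0, -15.7)
  sets <- lapply(seq_along(vh), function(i) {
    list(v = v, y = boltzmann_curve(v, vh[i], 16.2, y_max = 1 - 0.1 * i))
  })
  fits <- fit_boltzmann_joint(sets, "depolarization", share = "slope_dx")
  dxs <- vapply(fits, `[[`, 0, "slope_dx")
  expect_equal(length(unique(dxs)), 1L)
  expect_equal(dxs[1], 16.2, tolerance = 1e-6)
  for (i in seq_along(vh)) expect_equal(fits[[i]]$v_half, vh[i], tolerance = 1e-6)
  # shared slope is also honoured when the datasets disagree slightly
  sets2 <- sets
  sets2[[2]]$y <- boltzmann_curve(v, 25, 18, y_max = 0.8)
  fits2 <- fit_boltzmann_joint(sets2, "depolarization", share = "slope_dx")
  expect_equal(length(unique(vapply(fits2, `[[`, 0, "slope_dx"))), 1L)
})

test_that("numerical derivatives are exact for lines and peak at (Gmax-Gmin)/4dx", {
  v <- seq(-50, 50, 7)
  d <- numeric_derivative(v, 3.2 * v + 1)
  expect_equal(d$dgdv, rep(3.2, length(v)))
  expect_equal(numeric_derivative(v, rep(2, length(v)))$dgdv, rep(0, length(v)))
  # nonuniform grid: the three-point interior formula is exact for quadratics
  vn <- c(-30, -19, -5, 4, 17, 31)
  dq <- numeric_derivative(vn, vn^2)
  expect_equal(dq$dgdv[2:5], 2 * vn[2:5])
  # dense Boltzmann: max slope (Gmax-Gmin)/(4 dx) at the midpoint within 1%
  vg <- seq(-120, 170, 1)
  g <- boltzmann_curve(vg, 25, 16.2, y_max = 22.2, y_min = 0)
  dg <- numeric_derivative(vg, g)
  expect_equal(max(dg$dgdv), 22.2 / (4 * 16.2), tolerance = 0.01)
  expect_equal(dg$v[which.max(dg$dgdv)], 25)
  expect_error(numeric_derivative(c(1, 1, 2), c(0, 1, 2)),
               class = "hvgate_invalid_argument")
})

test_that("Gaussian peak fits recover exact Gaussians and honour fixed widths", {
  v <- seq(-150, 150, 5)
  y <- 0.01 + (4.5 / (76.2 * sqrt(pi / 2))) * exp(-2 * (v - 23.3)^2 / 76.2^2)
  f <- fit_gaussian_peak(v, y)
  expect_equal(f$baseline, 0.01, tolerance = 1e-9)
  expect_equal(f$area_a, 4.5, tolerance = 1e-9)
  expect_equal(f$omega, 76.2, tolerance = 1e-9)
  expect_equal(f$v_peak, 23.3, tolerance = 1e-9)
  f2 <- fit_gaussian_peak(v, y, fixed_omega = 80)
  expect_identical(f2$omega, 80)
  expect_true("omega" %in% f2$constraints)
})

test_that("V_PEAK estimates the Boltzmann midpoint", {
  # untruncated, densely sampled: v_peak within one grid spacing of v_half
  v <- seq(-120, 160, 10)
  g <- boltzmann_curve(v, 26.3, 16.3, y_max = 22.2)
  d <- numeric_derivative(v, g)
  f <- fit_gaussian_peak(d$v, d$dgdv)
  expect_lt(abs(f$v_peak - 26.3), 10)
  # with >= 95% of both plateaus inside the window: within 2 mV
  expect_lt(abs(f$v_peak - 26.3), 2)
  # falling curve: the derivative is negative; the fit still locates the peak
  g2 <- boltzmann_curve(v, -20, 26, y_max = 1, polarity = "hyperpolarization")
  d2 <- numeric_derivative(v, g2)
  f2 <- fit_gaussian_peak(d2$v, d2$dgdv)
  expect_lt(abs(f2$v_peak - (-20)), 2)
  expect_lt(f2$area_a, 0)
})

test_that("the validation curves reproduce the printed Gaussian width", {
  # Boltzmann dx = 26 sampled in 10 mV steps: |dG/dV| fits a Gaussian of
  # width ~83 mV (as printed) when the baseline is pinned at zero
  v <- seq(-100, 100, 10)
  g <- boltzmann_curve(v, 20, 26, y_max = 0.5)
  d <- numeric_derivative(v, g)
  f <- fit_gaussian_peak(d$v, abs(d$dgdv), fixed_baseline = 0)
  expect_equal(f$omega, 83.2, tolerance = 0.01)
  expect_equal(f$v_peak, 20, tolerance = 0.01)
})

test_that("linear fits reproduce printed pH slopes and correlations", {
  # G_SH: V_PEAK vs pH_o -> -44.2 mV/pH unit at printed precision
  f1 <- fit_line(c(5.5, 6.5, 7.5), c(-157.4, -197.6, -245.7))
  expect_lt(abs(f1$slope - (-44.2)), 0.0500001)
  # G_AQ: V_0.5 vs pH_o -> -41.0 mV/pH unit
  f2 <- fit_line(c(5.5, 6.5, 7.5), c(66.3, 25.0, -15.7))
  expect_equal(f2$slope, -41.0)
  # V_PEAK vs V_THR across constructs: R = -0.84 at printed precision
  f3 <- fit_line(c(-25.0, -20.7, 40.0, 80.0),
                 c(-183.5, -188.9, -187.9, -197.5))
  expect_lt(abs(f3$pearson_r - (-0.84)), 0.0050001)
  # collinear points: |r| = 1
  f4 <- fit_line(1:5, 2 - 3 * (1:5))
  expect_equal(abs(f4$pearson_r), 1)
  # Pearson r is invariant to affine rescaling of either axis
  x <- c(1, 3, 4, 7, 11); y <- c(2, 1, 5, 8, 9)
  r0 <- fit_line(x, y)$pearson_r
  expect_equal(fit_line(10 * x - 3, y)$pearson_r, r0)
  expect_equal(fit_line(x, -2 * y + 7)$pearson_r, -r0)
  expect_error(fit_line(rep(1, 4), 1:4), class = "hvgate_invalid_argument")
})

test_that("two-conductance decomposition recovers all six generating parameters", {
  v <- seq(-240, 200, 10)
  g <- 4.6 / (1 + exp((v + 189) / 42.1)) + 22.2 / (1 + exp(-(v - 29.4) / 24.9))
  fit <- decompose_two_conductances(v, g)
  expect_equal(fit$sh$y_max, 4.6, tolerance = 1e-4)
  expect_equal(fit$sh$v_half, -189, tolerance = 1e-4)
  expect_equal(fit$sh$slope_dx, 42.1, tolerance = 1e-4)
  expect_equal(fit$aq$y_max, 22.2, tolerance = 1e-4)
  expect_equal(fit$aq$v_half, 29.4, tolerance = 1e-4)
  expect_equal(fit$aq$slope_dx, 24.9, tolerance = 1e-4)
  expect_equal(fit$ratio, 22.2 / 4.6, tolerance = 1e-4)
  expect_equal(round(fit$ratio, 1), 4.8)
  expect_length(fit$collapsed, 0)
})

test_that("decomposition flags a collapsed component on single-conductance data", {
  v <- seq(-240, 200, 10)
  g_aq_only <- 22.2 / (1 + exp(-(v - 29.4) / 24.9))
  fit <- decompose_two_conductances(v, g_aq_only)
  expect_true("sh" %in% fit$collapsed)
  expect_equal(fit$aq$v_half, 29.4, tolerance = 1e-3)
  # with an offset term the pedestal is absorbed, not forced into a component
  # the collapsed component leaves a mild offset degeneracy; 1% is enough
  fit2 <- decompose_two_conductances(v, g_aq_only + 3.7, offset = TRUE)
  expect_equal(fit2$offset, 3.7, tolerance = 0.01)
  expect_equal(fit2$aq$v_half, 29.4, tolerance = 1e-3)
})

test_that("midpoint estimators are equivariant under rigid voltage shifts", {
  v <- seq(-150, 150, 10)
  for (shift in c(-40, 25)) {
    y <- boltzmann_curve(v, 10, 18, y_max = 5)
    f0 <- fit_boltzmann(v, y, "depolarization")
    f1 <- fit_boltzmann(v + shift, y, "depolarization")
    expect_equal(f1$v_half - f0$v_half, shift, tolerance = 1e-6)
    expect_equal(f1$slope_dx, f0$slope_dx, tolerance = 1e-6)
    expect_equal(f1$y_max, f0$y_max, tolerance = 1e-6)
    d0 <- numeric_derivative(v, y)
    d1 <- numeric_derivative(v + shift, y)
    g0 <- fit_gaussian_peak(d0$v, d0$dgdv)
    g1 <- fit_gaussian_peak(d1$v, d1$dgdv)
    expect_equal(g1$v_peak - g0$v_peak, shift, tolerance = 1e-6)
    expect_equal(g1$omega, g0$omega, tolerance = 1e-6)
  }
})

test_that("fit results serialize to JSON, summary lines and a flat table", {
  v <- seq(-100, 100, 10)
  bf <- fit_boltzmann(v, boltzmann_curve(v, 10, 20), "depolarization")
  lf <- fit_line(1:4, c(1, 3, 2, 5))
  path <- file.path(tempdir(), "fits.json")
  write_fit_json(list(boltz = bf, line = lf), path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$boltz$v_half, bf$v_half, tolerance = 1e-12)
  expect_equal(back$line$slope, lf$slope, tolerance = 1e-12)
  tab <- fits_summary_table(list(boltz = bf, line = lf))
  expect_equal(nrow(tab), 2L)
  expect_match(fit_summary_line(bf), "V_0.5")
  expect_match(fit_summary_line(lf), "R =")
})
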