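# Orchestration: end-to-end in-silico reproduction (simulate -> trace
# metrics -> gating fits) across channel variants and bath pH, plus
# verification of every printed-value-derivable quantity.

# tiny FNV-1a hash for provenance stamps (no external digest dependency)
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Configuration for a reproduction run
#'
#' @param variants Names from [reference_parameter_sets()] to simulate.
#' @param ph_o Bath pH values (the pipette pH stays at 6.5).
#' @param noise_sd Current noise, pA (default 0: noiseless).
#' @param seed RNG seed, recorded in every output.
#' @param step_voltages Test-step grid, mV.
#' @param step_duration,tail_duration,sample_interval Protocol timing, ms.
#' @param v_hold,v_tail Holding and tail potentials, mV.
#' @param sh_gauss_window Voltage window (mV) for the G_SH
#'   first-derivative Gaussian fit; the upper edge is kept well below
#'   the G_AQ activation range so the rising branch does not leak into
#'   the falling-branch derivative.
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return A `run_config` list.
#' @export
reproduction_config <- function(variants = c("wt", "r1h", "r1h_n4r",
                                             "d185a_r1h", "d185h_r1h"),
                                ph_o = c(5.5, 6.5, 7.5),
                                noise_sd = 0, seed = 1L,
                                step_voltages = seq(-240, 200, 10),
                                step_duration = 200, tail_duration = 100,
                                sample_interval = 1, v_hold = -60, v_tail = -90,
                                sh_gauss_window = c(-240, -100),
                                out_dir = NULL) {
  structure(list(variants = variants, ph_o = ph_o, noise_sd = noise_sd,
                 seed = as.integer(seed), step_voltages = step_voltages,
                 step_duration = step_duration, tail_duration = tail_duration,
                 sample_interval = sample_interval, v_hold = v_hold,
                 v_tail = v_tail,
                 sh_gauss_window = sh_gauss_window, out_dir = out_dir),
            class = "run_config")
}

#' Gating analysis of one simulated (or imported) sweep set
#'
#' Runs the full trace-to-parameters chain on a sweep set: builds the
#' per-voltage table (I_STEP, extrapolated I_TAIL), computes chord
#' conductance, then analyses the two gating branches.
#'
#' The tail-current relation is the sum of a voltage-independent leak
#' pedestal (the tail potential is fixed), a falling logistic (the
#' hyperpolarization-activated conductance present at the end of
#' negative steps) and a rising logistic (the depolarization-activated
#' conductance, G_AQ). It is therefore decomposed with
#' [decompose_two_conductances()] (with a free offset); the G_AQ
#' Boltzmann parameters come from the rising component, and V_THR is
#' estimated from the tail currents after subtracting the pedestal and
#' the falling component.
#'
#' The G_SH branch uses the first-derivative Gaussian method on the
#' chord-conductance relation. Leak subtraction is unnecessary there: a
#' voltage-independent leak contributes a constant to G and vanishes
#' under d/dV (absorbed by the Gaussian baseline term).
#'
#' @param sweeps A `sweep_set`.
#' @param e_rev Reversal potential used for the conductance transform;
#'   default: the Nernstian value for the sweep set's conditions.
#' @param sh_gauss_window See [reproduction_config()].
#' @param fixed_omega Optional Gaussian width (mV) held fixed for the
#'   G_SH fit (shared-width analysis across conditions).
#' @param vthr_k,vthr_f Threshold criterion parameters, see [estimate_vthr()].
#' @param tail_window_ms Length (ms) of the tail fit window, measured
#'   from two samples after the step-to-tail transition. A short window
#'   (default 20 ms) keeps the extrapolation anchored to the fast
#'   deactivating component; a slowly relaxing second conductance then
#'   enters the fit as a quasi-constant absorbed by the plateau term
#'   instead of biasing the extrapolated amplitude.
#' @return List: `iv` (measurement table), `tail_decomp`
#'   (`two_conductance_fit` of the tail relation), `aq_fit`
#'   (`boltzmann_fit` for G_AQ tails, amplitudes in pA), `v_thr` (mV or
#'   NA), `sh_fit` (`gaussian_fit` or NULL), `dgdv`, `baseline_sd`.
#' @export
analyze_gating <- function(sweeps, e_rev = NULL,
                           sh_gauss_window = c(-240, -100),
                           fixed_omega = NULL, vthr_k = 3, vthr_f = 0.02,
                           tail_window_ms = 20) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (is.null(e_rev)) e_rev <- proton_reversal(sweeps$conditions)
  ep <- .protocol_epochs(sweeps$protocol)
  dt <- sweeps$protocol$sample_interval
  iv <- sweep_iv_table(sweeps,
                       tail_fit_window = c(ep[["step_end"]] + 2 * dt,
                                           min(ep[["sweep_end"]],
                                               ep[["step_end"]] + 2 * dt + tail_window_ms)))
  iv <- add_g_step(iv, e_rev)

  # --- G_AQ branch: decompose tails into pedestal + falling + rising logistic
  aq_fit <- NULL; v_thr <- NA_real_; baseline_sd <- NA_real_; td <- NULL
  v <- iv$step_voltage
  y <- -iv$i_tail  # inward tails positive for the amplitude-bounded fit
  td <- tryCatch(
    decompose_two_conductances(v, y, offset = TRUE),
    error = function(e) NULL)
  if (!is.null(td)) {
    sh_part <- td$sh$y_max / (1 + exp((v - td$sh$v_half) / td$sh$slope_dx))
    aq_part <- y - td$offset - sh_part
    resid <- y - td$offset - sh_part -
      td$aq$y_max / (1 + exp(-(v - td$aq$v_half) / td$aq$slope_dx))
    baseline_sd <- stats::sd(resid)
    if (!is.finite(baseline_sd)) baseline_sd <- 0
    aq_fit <- td$aq
    v_thr <- tryCatch(
      estimate_vthr(data.frame(step_voltage = v, i_tail = aq_part),
                    baseline_sd = baseline_sd, k = vthr_k, f = vthr_f),
      error = function(e) NA_real_)
  }

  # --- G_SH branch: dG_STEP/dV and Gaussian V_PEAK
  dgdv <- numeric_derivative(iv$step_voltage[is.finite(iv$g_step)],
                             iv$g_step[is.finite(iv$g_step)])
  sh_fit <- tryCatch(
    fit_gaussian_peak(dgdv$v, dgdv$dgdv,
                      window = c(max(sh_gauss_window[1], min(dgdv$v)),
                                 min(sh_gauss_window[2], max(dgdv$v))),
                      fixed_omega = fixed_omega),
    error = function(e) NULL)

  list(iv = iv, tail_decomp = td, aq_fit = aq_fit, v_thr = v_thr,
       sh_fit = sh_fit, dgdv = dgdv, baseline_sd = baseline_sd)
}

# effective (pH-shifted) midpoint of a gated spec
.v_eff <- function(spec, ph_o) {
  spec$v_half + spec$ph_shift_slope * (ph_o - spec$ph_o_ref)
}

#' Run the full in-silico reproduction
#'
#' Simulates the configured channel variants at each bath pH, runs
#' [analyze_gating()] on every sweep family (for the G_SH Gaussian the
#' width fitted at the most acidic pH, where the curve is least
#' truncated, is held fixed at the other pH values), and assembles:
#' a V_THR table, a per-variant/pH fit-parameter table, pH-slope
#' summaries, and a parameter-recovery table (configured vs fitted).
#' Deterministic for a fixed seed; per-variant failures are recorded
#' and do not abort the remaining variants.
#'
#' @param config A [reproduction_config()].
#' @return List of data.frames `vthr_table`, `fit_table`, `slope_table`,
#'   `recovery_table`, plus `errors` (named character) and `provenance`.
#'   If `config$out_dir` is set, each table is also written as CSV with
#'   a provenance comment header, plus `provenance.json`.
#' @export
run_reproduction <- function(config = reproduction_config()) {
  stopifnot(inherits(config, "run_config"))
  refs <- reference_parameter_sets()
  unknown <- setdiff(config$variants, names(refs))
  if (length(unknown)) .hv_err(paste("unknown variant(s):", paste(unknown, collapse = ", ")))

  protocol <- step_protocol(v_hold = config$v_hold,
                            step_voltages = config$step_voltages,
                            step_duration = config$step_duration,
                            v_tail = config$v_tail,
                            tail_duration = config$tail_duration,
                            sample_interval = config$sample_interval)
  fit_rows <- list(); rec_rows <- list(); slope_rows <- list()
  errors <- character(0)

  for (variant in config$variants) {
    res <- tryCatch({
      ref <- refs[[variant]]
      has_sh <- any(vapply(ref$specs, function(s) identical(s$label, "SH"), TRUE))
      per_ph <- list()
      omega_shared <- NULL
      for (ph in sort(config$ph_o)) {  # most acidic first: defines the shared width
        cond <- recording_conditions(ph_i = ref$conditions$ph_i, ph_o = ph,
                                     temperature = ref$conditions$temperature)
        sweeps <- simulate_sweep_set(ref$specs, protocol, cond,
                                     noise_sd = config$noise_sd,
                                     seed = config$seed + round(1000 * ph))
        an <- analyze_gating(sweeps,
                             sh_gauss_window = config$sh_gauss_window,
                             fixed_omega = omega_shared)
        if (has_sh && is.null(omega_shared) && !is.null(an$sh_fit)) {
          omega_shared <- an$sh_fit$omega
        }
        per_ph[[sprintf("%g", ph)]] <- an
      }
      per_ph
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[variant] <- conditionMessage(res)
      next
    }
    ref <- refs[[variant]]
    aq_spec <- Filter(function(s) identical(s$label, "AQ"), ref$specs)[[1]]
    sh_specs <- Filter(function(s) identical(s$label, "SH"), ref$specs)
    for (ph_name in names(res)) {
      ph <- as.numeric(ph_name)
      an <- res[[ph_name]]
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        variant = variant, ph_o = ph,
        aq_v_half = if (!is.null(an$aq_fit)) an$aq_fit$v_half else NA_real_,
        aq_dx = if (!is.null(an$aq_fit)) an$aq_fit$slope_dx else NA_real_,
        sh_v_peak = if (!is.null(an$sh_fit)) an$sh_fit$v_peak else NA_real_,
        sh_omega = if (!is.null(an$sh_fit)) an$sh_fit$omega else NA_real_,
        v_thr = an$v_thr)
      rec <- data.frame(
        variant = variant, ph_o = ph,
        parameter = "aq_v_half",
        true = .v_eff(aq_spec, ph),
        fitted = if (!is.null(an$aq_fit)) an$aq_fit$v_half else NA_real_)
      if (length(sh_specs)) {
        rec <- rbind(rec, data.frame(
          variant = variant, ph_o = ph, parameter = "sh_v_half",
          true = .v_eff(sh_specs[[1]], ph),
          fitted = if (!is.null(an$sh_fit)) an$sh_fit$v_peak else NA_real_))
      }
      rec_rows[[length(rec_rows) + 1L]] <- rec
    }
    # pH slopes per variant
    phs <- as.numeric(names(res))
    if (length(phs) >= 2L) {
      aq_vh <- vapply(res, function(a) if (!is.null(a$aq_fit)) a$aq_fit$v_half else NA_real_, 0)
      if (sum(is.finite(aq_vh)) >= 2L) {
        lf <- fit_line(phs[is.finite(aq_vh)], aq_vh[is.finite(aq_vh)])
        slope_rows[[length(slope_rows) + 1L]] <- data.frame(
          variant = variant, quantity = "aq_v_half",
          slope_mv_per_ph = lf$slope, pearson_r = lf$pearson_r)
      }
      if (length(sh_specs)) {
        sh_vp <- vapply(res, function(a) if (!is.null(a$sh_fit)) a$sh_fit$v_peak else NA_real_, 0)
        if (sum(is.finite(sh_vp)) >= 2L) {
          lf <- fit_line(phs[is.finite(sh_vp)], sh_vp[is.finite(sh_vp)])
          slope_rows[[length(slope_rows) + 1L]] <- data.frame(
            variant = variant, quantity = "sh_v_peak",
            slope_mv_per_ph = lf$slope, pearson_r = lf$pearson_r)
        }
      }
    }
  }

  fit_table <- if (length(fit_rows)) do.call(rbind, fit_rows) else data.frame()
  recovery_table <- if (length(rec_rows)) do.call(rbind, rec_rows) else data.frame()
  slope_table <- if (length(slope_rows)) do.call(rbind, slope_rows) else data.frame()
  vthr_table <- if (nrow(fit_table)) fit_table[, c("variant", "ph_o", "v_thr")] else data.frame()
  provenance <- list(package = "hvgate",
                     version = as.character(utils::packageVersion("hvgate")),
                     seed = config$seed,
                     config_hash = .fnv1a(unclass(config)[setdiff(names(config), "out_dir")]))

  out <- list(vthr_table = vthr_table, fit_table = fit_table,
              slope_table = slope_table, recovery_table = recovery_table,
              errors = errors, provenance = provenance)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- sprintf("# hvgate %s seed=%d config=%s", provenance$version,
                     provenance$seed, provenance$config_hash)
    for (nm in c("vthr_table", "fit_table", "slope_table", "recovery_table")) {
      f <- file.path(config$out_dir, paste0(nm, ".csv"))
      writeLines(stamp, f)
      suppressWarnings(utils::write.table(out[[nm]], f, append = TRUE, sep = ",",
                                          row.names = FALSE, qmethod = "double"))
    }
    jsonlite::write_json(provenance, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# printed-precision pass rule: the recomputed value rounds to the
# printed value at its printed decimals (half-ties allowed)
.printed_pass <- function(computed, printed, digits) {
  abs(computed - printed) <= 0.5 * 10^(-digits) + 1e-9
}

#' Recompute every printed-value-derivable quantity
#'
#' Uses only the read-only fixtures ([hv1_fixtures()]) plus the
#' package's own arithmetic/fitting to recompute ratios, pH slopes,
#' correlations, threshold shifts, the Nernst slope and the gating
#' valence, and compares each to its printed value at printed
#' precision. Failures are reported, never raised.
#'
#' @param temperature Recording temperature, K.
#' @return data.frame: `check`, `computed`, `printed`, `cmp`
#'   (`"eq"` printed-precision, `"le"`/`"ge"` bound), `pass`.
#' @export
verify_printed_values <- function(temperature = 293.15) {
  fx <- hv1_fixtures()
  lf <- fx$legend_fits
  t2 <- fx$table2
  vthr <- function(constr) t2$vthr_mv[t2$construct == constr]

  rows <- list()
  add <- function(check, computed, printed, digits = 1, cmp = "eq") {
    pass <- switch(cmp,
                   eq = .printed_pass(computed, printed, digits),
                   le = computed <= printed + 1e-9,
                   ge = computed >= printed - 1e-9)
    rows[[length(rows) + 1L]] <<- data.frame(check = check, computed = computed,
                                             printed = printed, cmp = cmp,
                                             pass = pass)
  }

  add("nernst_slope_mv_per_ph", nernst_slope(temperature), lf$nernst_mv_per_ph, 1)
  add("thermal_voltage_mv", thermal_voltage(temperature), lf$rt_f_mv, 1)
  add("gaq_gsh_ratio_constrained",
      lf$gaq_from_gstep$g_max / lf$gsh_constrained$g_max,
      lf$printed_ratio_constrained, 1)
  add("gaq_gsh_ratio_free",
      lf$gaq_from_gstep$g_max / lf$gsh_free$g_max,
      lf$printed_ratio_free, 1)
  add("gsh_vpeak_ph_slope",
      fit_line(lf$ph_series$ph_o, lf$ph_series$gsh_v_peak)$slope,
      lf$printed_slope_gsh, 1)
  add("gaq_vhalf_ph_slope",
      fit_line(lf$ph_series$ph_o, lf$ph_series$gaq_v_half)$slope,
      lf$printed_slope_gaq, 1)
  aq_constructs <- lf$gaq_gaussian$construct
  add("gaq_vpeak_vthr_pearson_r",
      fit_line(vapply(aq_constructs, vthr, 0), lf$gaq_gaussian$v_peak)$pearson_r,
      lf$printed_r_gaq, 2, cmp = "ge")
  sh_constructs <- lf$gsh_gaussian$construct
  add("gsh_vpeak_vthr_pearson_r",
      fit_line(vapply(sh_constructs, vthr, 0), lf$gsh_gaussian$v_peak)$pearson_r,
      lf$printed_r_gsh, 2)
  add("vthr_shift_r1h_vs_wt", vthr("R1H") - vthr("WT"), -32, 0)
  add("vthr_shift_d185a", vthr("D185A-R1H") - vthr("R1H"), 65, 0)
  add("vthr_shift_d185h", vthr("D185H-R1H") - vthr("R1H"), 105, 0)
  add("gating_valence_constrained_dx",
      gating_valence(lf$gsh_constrained$dx, temperature),
      lf$printed_valence_range[2], 2, cmp = "le")

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
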