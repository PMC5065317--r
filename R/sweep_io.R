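# Plain-text exchange format for sweep sets: one CSV (time_ms plus one
# current column per step voltage) with a JSON side-car carrying the
# protocol, conditions, model parameters and seed. Currents are written
# with 17 significant digits so a round trip is bit-exact.

#' Write / read a sweep set (CSV + JSON side-car)
#'
#' `write_sweep_set` writes `<path>.csv` (columns `time_ms`,
#' `step_<V>_pA` per step voltage) and `<path>.json` (protocol,
#' conditions, model metadata). `read_sweep_set` reconstructs the
#' `sweep_set`; the round trip reproduces currents bit-exactly.
#'
#' @param sweeps A `sweep_set` from [simulate_sweep_set()].
#' @param path Base path without extension.
#' @return `write_sweep_set`: the base path, invisibly.
#'   `read_sweep_set`: a `sweep_set`.
#' @export
write_sweep_set <- function(sweeps, path) {
  stopifnot(inherits(sweeps, "sweep_set"))
  df <- data.frame(time_ms = sprintf("%.17g", sweeps$time_ms),
                   check.names = FALSE)
  for (j in seq_len(ncol(sweeps$currents))) {
    nm <- sprintf("step_%s_pA", colnames(sweeps$currents)[j])
    df[[nm]] <- sprintf("%.17g", sweeps$currents[, j])
  }
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  meta <- list(protocol = unclass(sweeps$protocol),
               conditions = unclass(sweeps$conditions),
               metadata = sweeps$metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_sweep_set
#' @export
read_sweep_set <- function(path) {
  tab <- utils::read.csv(paste0(path, ".csv"), check.names = FALSE,
                         colClasses = "numeric")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  p <- meta$protocol
  protocol <- step_protocol(v_hold = p$v_hold,
                            step_voltages = unlist(p$step_voltages),
                            step_duration = p$step_duration,
                            v_tail = unlist(p$v_tail),
                            tail_duration = p$tail_duration,
                            sample_interval = p$sample_interval,
                            pre_step_baseline = p$pre_step_baseline)
  cc <- meta$conditions
  conditions <- recording_conditions(cc$ph_i, cc$ph_o, cc$temperature)
  currents <- as.matrix(tab[, -1, drop = FALSE])
  colnames(currents) <- sprintf("%g", protocol$step_voltages)
  md <- meta$metadata
  structure(list(time_ms = tab$time_ms, currents = currents,
                 protocol = protocol, conditions = conditions,
                 metadata = md),
            class = "sweep_set")
}
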