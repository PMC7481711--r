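# Reduction of simulated traces to reported quantities: per-cycle tidal
# volume, achieved PEEP, peak airway pressure, steady-state detection.

#' Airway-pressure trace for one patient
#'
#' The airway pressure is probed at the patient side of the endotracheal tube,
#' i.e. at the R_ETT/R_L junction.
#'
#' @param ts a `vent_timeseries` from [simulate_circuit()].
#' @param patient patient index (1 or 2).
#' @return Numeric vector of airway pressures (cmH2O), one per row of `ts`.
#' @export
airway_pressure <- function(ts, patient = 1) {
  stopifnot(inherits(ts, "vent_timeseries"))
  col <- paste0("p_aw", patient)
  if (!col %in% names(ts)) stop("unknown patient id: ", patient)
  ts[[col]]
}

#' Per-cycle summaries of a simulated run
#'
#' For every complete breath cycle: tidal volume (max minus min of stored lung
#' volume within the cycle, in ml), achieved PEEP (minimum airway pressure over
#' the cycle) and peak airway pressure, per patient. A cycle is flagged steady
#' when every patient's tidal volume differs from the previous cycle's by less
#' than `vt_tol`.
#'
#' @param ts a `vent_timeseries` spanning at least 2 full cycles.
#' @param schedule the [phase_schedule()] (defaults to the one recorded in
#'   `ts`).
#' @param vt_tol steadiness threshold on consecutive-cycle tidal-volume change,
#'   ml.
#' @return A data.frame with one row per cycle: `cycle`, then per patient
#'   `vt<k>_ml`, `peep<k>`, `ppeak<k>`, and `steady`.
#' @export
cycle_summaries <- function(ts, schedule = attr(ts, "schedule"), vt_tol = 0.05) {
  stopifnot(inherits(ts, "vent_timeseries"))
  np <- length(attr(ts, "netlist")$patients)
  t_end <- max(ts$t)
  n_cycles <- floor(t_end / schedule$period + 1e-9)
  if (n_cycles < 1) stop("time series shorter than one cycle")
  rows <- vector("list", n_cycles)
  for (k in seq_len(n_cycles)) {
    lo <- (k - 1) * schedule$period - 1e-9
    hi <- k * schedule$period + 1e-9
    w <- ts$t >= lo & ts$t <= hi
    row <- list(cycle = k)
    for (p in seq_len(np)) {
      vol <- ts[[paste0("vol", p)]][w]
      paw <- ts[[paste0("p_aw", p)]][w]
      row[[paste0("vt", p, "_ml")]] <- 1000 * (max(vol) - min(vol))
      row[[paste0("peep", p)]] <- min(paw)
      row[[paste0("ppeak", p)]] <- max(paw)
    }
    rows[[k]] <- as.data.frame(row)
  }
  out <- do.call(rbind, rows)
  vt_cols <- paste0("vt", seq_len(np), "_ml")
  steady <- rep(FALSE, n_cycles)
  if (n_cycles >= 2) {
    for (k in 2:n_cycles) {
      steady[k] <- all(abs(out[k, vt_cols] - out[k - 1, vt_cols]) < vt_tol)
    }
  }
  out$steady <- steady
  out
}

#' Steady-cycle summary of a configuration
#'
#' Simulates from the zero state until consecutive cycles' tidal volumes agree
#' within `vt_tol` for every patient (or `n_max_cycles` is reached, with a
#' warning), and returns the last cycle's summary.
#'
#' @param net a [netlist()].
#' @param settings a [ventilator_settings()].
#' @param n_max_cycles maximum number of cycles to simulate (>= 2).
#' @param vt_tol steadiness threshold, ml.
#' @param ... passed to [simulate_circuit()] (`rtol`, `n_out`, ...).
#' @return One-row data.frame as in [cycle_summaries()], with attribute
#'   `steady_cycle` (first steady cycle index, or NA).
#' @export
steady_state_summary <- function(net, settings, n_max_cycles = 8,
                                 vt_tol = 0.05, ...) {
  if (n_max_cycles < 2) stop("n_max_cycles must be >= 2")
  ts <- simulate_circuit(net, settings, n_cycles = n_max_cycles, ...)
  summ <- cycle_summaries(ts, vt_tol = vt_tol)
  first_steady <- if (any(summ$steady)) which(summ$steady)[1] else NA_integer_
  if (is.na(first_steady)) {
    warning("tidal volumes not steady after ", n_max_cycles, " cycles")
  }
  out <- summ[nrow(summ), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "steady_cycle") <- first_steady
  out
}

# fast internal path for tuning loops: steady tidal volumes (ml) per patient
.steady_vts <- function(net, settings, n_cycles = 6, rtol = 1e-8, n_out = 9) {
  ts <- simulate_circuit(net, settings, n_cycles = n_cycles, rtol = rtol,
                         n_out = n_out)
  summ <- cycle_summaries(ts)
  np <- length(attr(ts, "netlist")$patients)
  unlist(summ[nrow(summ), paste0("vt", seq_len(np), "_ml")])
}

#' Write experiment/summary tables to CSV with a metadata header
#'
#' Writes `# key=value` comment lines followed by the CSV table.
#'
#' @param df a data.frame.
#' @param path output file path.
#' @param meta named list of metadata values recorded as `# key=value` lines.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s=%s", k, meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
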