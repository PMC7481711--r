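# Time integration of the switched network.
#
# State variables are the compliance pressures; dP_c/dt = I_c / C with I_c from
# the instantaneous nodal solve. Integration restarts exactly at every phase
# edge so the source discontinuity is never stepped over. Check-valve
# conduction states are re-resolved at every derivative evaluation (warm-
# started from the previous consistent assignment); branch flows are continuous
# across a conduction switch, so no further event handling is needed.

#' Simulate a ventilator circuit
#'
#' Integrates the netlist under the square-wave pressure source for `n_cycles`
#' breath cycles, starting from all state variables at zero (or `init`).
#'
#' @param net a [netlist()], e.g. from [build_single()], [build_standard()],
#'   [build_modified()].
#' @param settings a [ventilator_settings()].
#' @param n_cycles number of breath cycles to simulate (>= 2; the first cycle
#'   carries the start-up transient).
#' @param rtol,atol relative/absolute integration tolerances (state scale is
#'   cmH2O).
#' @param n_out number of output samples per phase (the exact phase-edge
#'   instants are always included; row count does not affect accuracy).
#' @param init optional initial compliance pressures (cmH2O), netlist order.
#' @param method deSolve integration method.
#' @return A `vent_timeseries`: a data.frame with columns `t`, `phase`,
#'   `p_vent`, and per patient `p_aw<k>` (airway pressure at the R_ETT/R_L
#'   junction, cmH2O), `flow<k>` (flow into the lung, L/s), `vol<k>` (stored
#'   lung volume above the zero state, L), plus one 0/1 column per check valve
#'   (`cond_<name>`). Attributes: `settings`, `schedule`, `netlist`.
#' @export
simulate_circuit <- function(net, settings, n_cycles = 8, rtol = 1e-8,
                             atol = 1e-12, n_out = 25, init = NULL,
                             method = "lsoda") {
  stopifnot(inherits(net, "vent_netlist"),
            inherits(settings, "ventilator_settings"))
  if (n_cycles < 2) stop("n_cycles must be >= 2")
  sched <- phase_schedule(settings)
  cn <- .compile_netlist(net)
  np <- length(net$patients)
  y <- if (is.null(init)) numeric(length(cn$cap_idx)) else as.numeric(init)
  if (length(y) != length(cn$cap_idx)) stop("init has wrong length")
  env <- new.env(parent = emptyenv())
  env$cv <- rep(TRUE, length(cn$cv_idx))

  out_names <- c("p_vent",
                 if (np) paste0("p_aw", seq_len(np)),
                 if (np) paste0("flow", seq_len(np)),
                 if (length(cn$cv_idx)) paste0("cond_", cn$names[cn$cv_idx]))
  aw_nodes <- vapply(net$patients, `[[`, "", "aw")
  cap_of_patient <- match(vapply(net$patients, `[[`, "", "comp"), cn$cap_names)

  segs <- vector("list", 2L * n_cycles)
  t0 <- 0
  k <- 0L
  for (cyc in seq_len(n_cycles)) {
    for (ph in c("INSP", "EXP")) {
      dur <- if (ph == "INSP") sched$t_insp else sched$t_exp
      p_src <- if (ph == "INSP") settings$pip else settings$peep
      deriv <- function(t, y, parms) {
        sol <- .consistent_solve(cn, y, ph, p_src, env$cv)
        env$cv <- sol$cv_state
        dy <- sol$flows[cn$cap_idx] / cn$cap_values
        extra <- c(p_src,
                   if (np) sol$pressures[aw_nodes],
                   if (np) sol$flows[cn$cap_idx][cap_of_patient],
                   if (length(sol$cv_state)) as.numeric(sol$cv_state))
        names(extra) <- out_names
        list(dy, extra)
      }
      times <- seq(t0, t0 + dur, length.out = max(2L, n_out))
      sol <- deSolve::ode(y, times, deriv, parms = NULL, method = method,
                          rtol = rtol, atol = atol)
      k <- k + 1L
      segs[[k]] <- cbind(as.data.frame(unclass(sol)), phase = ph)
      y <- as.numeric(sol[nrow(sol), 1L + seq_along(y)])
      t0 <- t0 + dur
    }
  }
  df <- do.call(rbind, segs)
  res <- data.frame(t = df$time, phase = df$phase, p_vent = df$p_vent)
  for (p in seq_len(np)) {
    res[[paste0("p_aw", p)]] <- df[[paste0("p_aw", p)]]
    res[[paste0("flow", p)]] <- df[[paste0("flow", p)]]
    res[[paste0("vol", p)]] <- cn$cap_values[cap_of_patient[p]] *
      df[[1L + cap_of_patient[p]]]
  }
  for (nmv in out_names[startsWith(out_names, "cond_")]) res[[nmv]] <- df[[nmv]]
  rownames(res) <- NULL
  structure(res, settings = settings, schedule = sched, netlist = net,
            class = c("vent_timeseries", "data.frame"))
}

#' @export
print.vent_timeseries <- function(x, ...) {
  s <- attr(x, "settings")
  cat(sprintf("Simulated time series: %d rows, %d patient(s), %.4g s (PIP %g, PEEP %g cmH2O)\n",
              nrow(x), length(attr(x, "netlist")$patients), max(x$t), s$pip, s$peep))
  print.data.frame(utils::head(as.data.frame(x), 4))
  cat("...\n")
  invisible(x)
}

#' Plot simulated traces
#'
#' Three stacked panels: ventilator and airway pressures, delivered volume, and
#' flow, per patient.
#'
#' @param x a `vent_timeseries`.
#' @param ... ignored.
#' @export
plot.vent_timeseries <- function(x, ...) {
  np <- length(attr(x, "netlist")$patients)
  cols <- c("#1b6ca8", "#d1495b")
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$p_vent, type = "s", col = "grey40", lty = 3,
                 xlab = "", ylab = "pressure (cmH2O)",
                 ylim = range(c(x$p_vent, unlist(x[paste0("p_aw", seq_len(np))]))))
  for (p in seq_len(np)) graphics::lines(x$t, x[[paste0("p_aw", p)]], col = cols[p])
  graphics::plot(x$t, 1000 * x$vol1, type = "l", col = cols[1],
                 xlab = "", ylab = "volume (ml)")
  if (np > 1) graphics::lines(x$t, 1000 * x$vol2, col = cols[2])
  graphics::plot(x$t, x$flow1, type = "l", col = cols[1],
                 xlab = "time (s)", ylab = "flow (L/s)")
  if (np > 1) graphics::lines(x$t, x$flow2, col = cols[2])
  invisible(x)
}

#' Write a simulated time series to CSV
#'
#' Fixed header `t_s,phase,P_vent_cmH2O,P_aw1_cmH2O,P_aw2_cmH2O,flow1_L_s,
#' flow2_L_s,vol1_L,vol2_L`; single-patient runs carry NA in the patient-2
#' columns.
#'
#' @param ts a `vent_timeseries`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "vent_timeseries"))
  np <- length(attr(ts, "netlist")$patients)
  get <- function(col) if (col %in% names(ts)) ts[[col]] else NA_real_
  out <- data.frame(t_s = ts$t, phase = ts$phase, P_vent_cmH2O = ts$p_vent,
                    P_aw1_cmH2O = get("p_aw1"), P_aw2_cmH2O = get("p_aw2"),
                    flow1_L_s = get("flow1"), flow2_L_s = get("flow2"),
                    vol1_L = get("vol1"), vol2_L = get("vol2"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
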