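# shared fixtures: lung presets, settings and a compact steady-state helper

LUNG <- list(A = lung_preset("A"), B = lung_preset("B"),
             C = lung_preset("C"), D = lung_preset("D"))

ref_settings <- function(pip = 15) ventilator_settings(pip = pip)

# steady tidal volumes (ml) and achieved PEEPs for a netlist, compact run
steady_vts <- function(net, settings, n_max_cycles = 6, ...) {
  sm <- steady_state_summary(net, settings, n_max_cycles = n_max_cycles, ...)
  np <- if ("vt2_ml" %in% names(sm)) 2 else 1
  list(vt = unlist(sm[paste0("vt", seq_len(np), "_ml")], use.names = FALSE),
       peep = unlist(sm[paste0("peep", seq_len(np))], use.names = FALSE))
}

# brute-force periodic steady state of one series RC branch under the square
# wave: explicit Euler at a small fixed step, independent of both the
# closed form and the network simulator.
euler_branch_vt <- function(c_l, r_insp, r_exp, settings, n_cycles = 10,
                            dt = 2e-4) {
  sched <- phase_schedule(settings)
  v <- 0
  vmax <- -Inf
  vmin <- Inf
  last <- n_cycles * sched$period
  t <- 0
  while (t < last - dt / 2) {
    in_insp <- (t %% sched$period) < sched$t_insp - 1e-12
    p <- if (in_insp) settings$pip else settings$peep
    r <- if (in_insp) r_insp else r_exp
    v <- v + dt * (p - v) / (r * c_l)
    t <- t + dt
    if (t > last - sched$period) {
      vmax <- max(vmax, v)
      vmin <- min(vmin, v)
    }
  }
  1000 * c_l * (vmax - vmin)
}
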