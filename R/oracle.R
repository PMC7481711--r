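# Closed-form periodic steady state of a single series RC branch under the
# square-wave source: the independent analytic check for the simulator.
#
# With inspiratory time constant tau_i = r_insp * c and expiratory time
# constant tau_e = r_exp * c, let a = exp(-t_insp/tau_i), b = exp(-t_exp/tau_e)
# and dP = PIP - PEEP. The periodic steady state oscillates between
#   P_lo = PEEP + dP * a(1-b)/(1-ab)   and   P_hi = PIP - dP * (1-a)b/(1-ab) ...
# giving a swing of dP * (1-a)(1-b)/(1-ab) and hence
#   VT [ml] = 1000 * c * dP * (1-a)(1-b) / (1-ab).
# Exact for any patient whose branch is decoupled from its partner (single
# builds, valve-isolated arms of the modified splitter, and symmetric standard
# pairs where the cross path carries no flow); approximate for coupled
# asymmetric standard pairs.

#' Series RC branch specification
#'
#' @param c compliance, L/cmH2O (> 0).
#' @param r_insp total resistance of the inspiratory path, cmH2O/L/s (> 0);
#'   for the splitter topologies this is R_V + R_I + R_ETT + R_L.
#' @param r_exp total resistance of the expiratory path, cmH2O/L/s (> 0);
#'   R_E + R_ETT + R_L.
#' @return An object of class `branch_spec`, with derived time constants
#'   `tau_insp` and `tau_exp` (s).
#' @export
branch_spec <- function(c, r_insp, r_exp) {
  stopifnot(is.numeric(c), is.numeric(r_insp), is.numeric(r_exp))
  if (c <= 0) stop("compliance must be > 0")
  if (r_insp <= 0 || r_exp <= 0) stop("path resistances must be > 0")
  structure(list(c = c, r_insp = r_insp, r_exp = r_exp,
                 tau_insp = r_insp * c, tau_exp = r_exp * c),
            class = "branch_spec")
}

#' Closed-form steady-state tidal volume of a series RC branch
#'
#' @param branch a [branch_spec()].
#' @param settings a [ventilator_settings()].
#' @return Tidal volume in ml.
#' @examples
#' # healthy reference lung through the splitter tubing at default settings
#' br <- branch_spec(0.054, r_insp = 0.06 + 8 + 2, r_exp = 0.06 + 8 + 2)
#' steady_state_vt(br, ventilator_settings()) # ~490.3 ml
#' @export
steady_state_vt <- function(branch, settings) {
  stopifnot(inherits(branch, "branch_spec"),
            inherits(settings, "ventilator_settings"))
  sched <- phase_schedule(settings)
  a <- exp(-sched$t_insp / branch$tau_insp)
  b <- exp(-sched$t_exp / branch$tau_exp)
  dp <- settings$pip - settings$peep
  1000 * branch$c * dp * (1 - a) * (1 - b) / (1 - a * b)
}

#' Closed-form tidal volume for a lung behind the splitter tubing
#'
#' Convenience wrapper: builds the [branch_spec()] with
#' `r_insp = r_v + r_i + r_ett + r_l` and `r_exp = r_e + r_ett + r_l` and
#' evaluates [steady_state_vt()].
#'
#' @param lung a [lung_model()].
#' @param settings a [ventilator_settings()].
#' @param splitter a [splitter_config()].
#' @param r_v restrictor resistance in this patient's inspiration arm,
#'   cmH2O/L/s.
#' @return Tidal volume in ml.
#' @export
oracle_vt <- function(lung, settings, splitter = splitter_config(), r_v = 0) {
  br <- branch_spec(lung$c_l,
                    r_insp = r_v + splitter$r_i + lung$r_ett + lung$r_l,
                    r_exp = splitter$r_e + lung$r_ett + lung$r_l)
  steady_state_vt(br, settings)
}
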