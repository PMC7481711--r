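# Square-wave ventilator pressure and the inspiration/expiration phase signal.

#' Breath-cycle timing from ventilator settings
#'
#' The cycle period is 60/RR seconds and is split between inspiration and
#' expiration in the I:E ratio. The cycle starts at the inspiration onset
#' (t = 0 is the rising edge of the pressure square wave).
#'
#' @param settings a [ventilator_settings()].
#' @return An object of class `phase_schedule` with fields `period`, `t_insp`,
#'   `t_exp` (seconds).
#' @examples
#' phase_schedule(ventilator_settings(rr = 15, ie = c(1, 2))) # 4 s, 4/3 s, 8/3 s
#' @export
phase_schedule <- function(settings) {
  stopifnot(inherits(settings, "ventilator_settings"))
  period <- 60 / settings$rr
  t_insp <- period * settings$ie[1] / sum(settings$ie)
  structure(list(period = period, t_insp = t_insp, t_exp = period - t_insp),
            class = "phase_schedule")
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat(sprintf("Cycle %g s: inspiration %g s, expiration %g s\n",
              x$period, x$t_insp, x$t_exp))
  invisible(x)
}

#' Ventilator source pressure and phase at time t
#'
#' The source is a square wave: PIP while `t mod period` lies in
#' `[0, t_insp)` (phase "INSP"), PEEP otherwise (phase "EXP").
#'
#' @param settings a [ventilator_settings()].
#' @param t time(s) in seconds, `>= 0`; vectorized.
#' @return A data.frame with columns `t`, `pressure` (cmH2O) and `phase`
#'   ("INSP"/"EXP").
#' @export
source_pressure <- function(settings, t) {
  stopifnot(inherits(settings, "ventilator_settings"), all(t >= 0))
  sched <- phase_schedule(settings)
  tm <- t %% sched$period
  insp <- tm < sched$t_insp
  data.frame(t = t,
             pressure = ifelse(insp, settings$pip, settings$peep),
             phase = ifelse(insp, "INSP", "EXP"))
}
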