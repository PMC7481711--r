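# Unit conversions, parameter registry and lung presets.
#
# All internal computation uses clinical units: pressure in cmH2O, volume in L,
# time in s, resistance in cmH2O/L/s, compliance in L/cmH2O. The model is
# linear, so S.I. conversion only rescales results; it is provided as an I/O
# convenience and to document the parameter set.

# standard-gravity conversion: 1 cmH2O = 98.0665 Pa
.CMH2O_PA <- 98.0665

#' Convert pressure from cmH2O to Pa
#'
#' @param p pressure in cmH2O.
#' @return Pressure in Pa (`p * 98.0665`).
#' @seealso [pa_to_cmh2o()] for the inverse.
#' @examples
#' round(cmh2o_to_pa(15)) # 1471
#' @export
cmh2o_to_pa <- function(p) p * .CMH2O_PA

#' Convert pressure from Pa to cmH2O
#'
#' @param p pressure in Pa.
#' @return Pressure in cmH2O.
#' @export
pa_to_cmh2o <- function(p) p / .CMH2O_PA

#' Convert resistance from clinical to S.I. units
#'
#' Converts cmH2O/L/s to Pa s m^-3 (factor 98.0665 / 0.001).
#'
#' @param r resistance in cmH2O/L/s; must be non-negative.
#' @return Resistance in Pa s m^-3.
#' @export
resistance_clinical_to_si <- function(r) {
  if (any(r < 0)) stop("resistance must be non-negative")
  r * .CMH2O_PA / 1e-3
}

#' Convert resistance from S.I. to clinical units
#'
#' @param r resistance in Pa s m^-3; must be non-negative.
#' @return Resistance in cmH2O/L/s.
#' @export
resistance_si_to_clinical <- function(r) {
  if (any(r < 0)) stop("resistance must be non-negative")
  r * 1e-3 / .CMH2O_PA
}

#' Convert compliance from clinical to S.I. units
#'
#' Converts L/cmH2O to m^3 Pa^-1.
#'
#' @param c_l compliance in L/cmH2O; must be positive.
#' @return Compliance in m^3 Pa^-1.
#' @export
compliance_clinical_to_si <- function(c_l) {
  if (any(c_l <= 0)) stop("compliance must be positive")
  c_l * 1e-3 / .CMH2O_PA
}

#' Poiseuille resistance of a straight laminar tube
#'
#' `R = 128 * mu * L / (pi * D^4)` for fully developed laminar flow. Used to
#' derive the splitter tubing resistance (22 mm diameter, 1.8 m breathing-
#' circuit tubing, air viscosity 18.13e-6 Pa s gives ~5676 Pa s m^-3, i.e.
#' ~0.06 cmH2O/L/s).
#'
#' @param diameter tube inner diameter in m.
#' @param viscosity dynamic viscosity in Pa s.
#' @param length tube length in m.
#' @return Resistance in Pa s m^-3.
#' @export
poiseuille_resistance <- function(diameter, viscosity, length) {
  if (any(diameter <= 0) || any(viscosity <= 0) || any(length <= 0)) {
    stop("diameter, viscosity and length must all be positive")
  }
  128 * viscosity * length / (pi * diameter^4)
}

#' Ventilator settings for pressure-controlled ventilation
#'
#' Defines the square-wave pressure source: PIP during inspiration, PEEP during
#' expiration, cycle rate from the respiratory rate, and the split of the cycle
#' between phases from the I:E ratio.
#'
#' @param pip peak inspiratory pressure, cmH2O.
#' @param peep positive end-expiratory pressure, cmH2O.
#' @param rr respiratory rate, breaths/min.
#' @param ie inspiration:expiration ratio as a length-2 positive vector.
#' @return An object of class `ventilator_settings`.
#' @examples
#' ventilator_settings() # reference settings: PIP 15, PEEP 5, RR 15, I:E 1:2
#' @export
ventilator_settings <- function(pip = 15, peep = 5, rr = 15, ie = c(1, 2)) {
  stopifnot(is.numeric(pip), length(pip) == 1L,
            is.numeric(peep), length(peep) == 1L,
            is.numeric(rr), length(rr) == 1L,
            is.numeric(ie), length(ie) == 2L)
  if (peep < 0) stop("peep must be >= 0")
  if (pip < peep) stop("pip must be >= peep")
  if (rr <= 0) stop("rr must be > 0")
  if (any(ie <= 0)) stop("both I:E parts must be > 0")
  structure(list(pip = pip, peep = peep, rr = rr, ie = ie),
            class = "ventilator_settings")
}

#' @export
print.ventilator_settings <- function(x, ...) {
  cat(sprintf("Ventilator settings: PIP %g cmH2O, PEEP %g cmH2O, RR %g /min, I:E %g:%g\n",
              x$pip, x$peep, x$rr, x$ie[1], x$ie[2]))
  invisible(x)
}

#' Single-compartment lung model
#'
#' One patient's respiratory system as a series resistance-compliance branch:
#' endotracheal tube resistance, airway resistance, and the combined compliance
#' of lung and chest wall.
#'
#' @param c_l respiratory compliance, L/cmH2O (> 0).
#' @param r_l airway resistance, cmH2O/L/s (>= 0).
#' @param r_ett endotracheal tube resistance, cmH2O/L/s (>= 0).
#' @param label preset name, one of "A", "B", "C", "D" or "custom".
#' @return An object of class `lung_model`.
#' @seealso [lung_preset()]
#' @export
lung_model <- function(c_l, r_l = 2, r_ett = 8, label = "custom") {
  stopifnot(is.numeric(c_l), length(c_l) == 1L)
  if (c_l <= 0) stop("compliance c_l must be > 0")
  if (r_l < 0 || r_ett < 0) stop("resistances must be >= 0")
  structure(list(c_l = c_l, r_l = r_l, r_ett = r_ett, label = label),
            class = "lung_model")
}

#' @export
print.lung_model <- function(x, ...) {
  cat(sprintf("Lung model %s: C_L %g L/cmH2O, R_L %g, R_ETT %g cmH2O/L/s\n",
              x$label, x$c_l, x$r_l, x$r_ett))
  invisible(x)
}

# compliance reductions for the ARDS severity presets
.LUNG_REDUCTION <- c(A = 0, B = 0.2, C = 0.3, D = 0.4)

#' Lung model presets A-D
#'
#' Preset A is the healthy reference (compliance 0.054 L/cmH2O); B, C and D
#' represent mild, moderate and severe ARDS as 20%, 30% and 40% compliance
#' reductions (0.0432, 0.0378, 0.0324 L/cmH2O). Airway resistance (2) and
#' endotracheal tube resistance (8 cmH2O/L/s) are common to all presets.
#'
#' @param label one of "A", "B", "C", "D".
#' @return A [lung_model()].
#' @examples
#' lung_preset("B")$c_l # 0.0432
#' @export
lung_preset <- function(label) {
  label <- as.character(label)
  if (length(label) != 1L || !label %in% names(.LUNG_REDUCTION)) {
    stop("unknown lung preset; must be one of A, B, C, D")
  }
  lung_model(c_l = 0.054 * (1 - .LUNG_REDUCTION[[label]]),
             r_l = 2, r_ett = 8, label = label)
}

#' Splitter configuration
#'
#' Tubing resistances of the splitter arms and, for the modified topology, the
#' variable restrictor resistances in each inspiration arm.
#'
#' @param topology "single" (one patient, validation reduction), "standard"
#'   (plain T-splitter), or "modified" (variable restrictors on inspiration
#'   arms, one-way valves on expiration arms).
#' @param r_i inspiration-arm tubing resistance per arm, cmH2O/L/s.
#' @param r_e expiration-arm tubing resistance per arm, cmH2O/L/s.
#' @param r_v1,r_v2 variable restrictor resistances, cmH2O/L/s; used by the
#'   modified topology only.
#' @return An object of class `splitter_config`.
#' @export
splitter_config <- function(topology = c("standard", "modified", "single"),
                            r_i = 0.06, r_e = 0.06, r_v1 = 0, r_v2 = 0) {
  topology <- match.arg(topology)
  vals <- c(r_i = r_i, r_e = r_e, r_v1 = r_v1, r_v2 = r_v2)
  if (any(vals < 0)) stop("all splitter resistances must be >= 0")
  structure(list(topology = topology, r_i = r_i, r_e = r_e,
                 r_v1 = r_v1, r_v2 = r_v2),
            class = "splitter_config")
}

#' @export
print.splitter_config <- function(x, ...) {
  cat(sprintf("Splitter (%s): R_I %g, R_E %g", x$topology, x$r_i, x$r_e))
  if (x$topology == "modified") cat(sprintf(", R_V1 %g, R_V2 %g", x$r_v1, x$r_v2))
  cat(" cmH2O/L/s\n")
  invisible(x)
}

#' Model parameter registry
#'
#' The reference parameter set in clinical units with the matching S.I. values.
#' `si = "exact"` converts with 1 cmH2O = 98.0665 Pa; `si = "printed"`
#' substitutes the conventional rounded S.I. values (e.g. R_ETT 784000 rather
#' than 784532 Pa s m^-3) for byte-level comparison studies. The two differ by
#' < 0.1% and the effect on simulated tidal volume is < 0.1 ml.
#'
#' @param si "exact" or "printed".
#' @return A data.frame with columns `parameter`, `clinical`, `clinical_units`,
#'   `si`, `si_units`.
#' @export
param_registry <- function(si = c("exact", "printed")) {
  si <- match.arg(si)
  clin <- c(PEEP = 5, PIP = 15, RR = 15, R_I = 0.06, R_E = 0.06,
            R_L = 2, C_L = 0.054, R_ETT = 8)
  units <- c("cmH2O", "cmH2O", "breaths/min", "cmH2O/L/s", "cmH2O/L/s",
             "cmH2O/L/s", "L/cmH2O", "cmH2O/L/s")
  exact <- c(cmh2o_to_pa(5), cmh2o_to_pa(15), NA,
             resistance_clinical_to_si(0.06), resistance_clinical_to_si(0.06),
             resistance_clinical_to_si(2), compliance_clinical_to_si(0.054),
             resistance_clinical_to_si(8))
  printed <- c(490, 1471, NA, 5670, 5670, 196133, 5.5e-7, 784000)
  data.frame(parameter = names(clin),
             clinical = unname(clin),
             clinical_units = units,
             si = if (si == "exact") unname(exact) else printed,
             si_units = c("Pa", "Pa", NA, "Pa s m-3", "Pa s m-3",
                          "Pa s m-3", "m3 Pa-1", "Pa s m-3"),
             row.names = NULL)
}
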