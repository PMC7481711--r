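# Circuit topologies: single patient, standard T-splitter, modified splitter.
#
# Source topology: the square-wave pressure source feeds an inspiratory port
# through a phase valve that conducts during inspiration, and receives an
# expiratory port through a phase valve that conducts during expiration. Both
# ports tee to the patient arms. On the standard splitter this makes the two
# expiration arms a patient-to-patient path during inspiration (the "short
# circuit" the modified splitter's one-way valves remove).

# series chain of resistors from `from` to `to`; zero-valued entries are wires
# (their boundary node collapses onto the nearest resistor terminal). `ends[i]`
# is the realized node name downstream of element i. The final realized node is
# always `to`, so at least one value must be positive.
.series_chain <- function(from, to, values, names_) {
  nz <- sum(values > 0)
  if (nz == 0L) {
    stop("series path ", from, " -> ", to,
         " has zero total resistance; merge the nodes instead")
  }
  comps <- list()
  ends <- character(length(values))
  cur <- from
  cnt <- 0L
  for (i in seq_along(values)) {
    if (values[i] > 0) {
      cnt <- cnt + 1L
      nxt <- if (cnt == nz) to else paste0(to, "_j", cnt)
      comps[[length(comps) + 1L]] <- resistor(cur, nxt, values[i], names_[i])
      cur <- nxt
    }
    ends[i] <- cur
  }
  list(comps = comps, ends = ends)
}

# patient branch: wye -> R_ETT -> aw -> R_L -> alv, C_L alv -> gnd.
# The airway-pressure probe sits at the patient side of R_ETT.
.patient_branch <- function(k, lung, wye) {
  comp_name <- paste0("C_L", k)
  if (lung$r_ett + lung$r_l == 0) {
    return(list(comps = list(compliance(wye, lung$c_l, comp_name)),
                patient = list(aw = wye, alv = wye, comp = comp_name,
                               c_l = lung$c_l, lung = lung)))
  }
  ch <- .series_chain(wye, paste0("alv", k), c(lung$r_ett, lung$r_l),
                      paste0(c("R_ETT", "R_L"), k))
  list(comps = c(ch$comps, list(compliance(ch$ends[2], lung$c_l, comp_name))),
       patient = list(aw = ch$ends[1], alv = ch$ends[2], comp = comp_name,
                      c_l = lung$c_l, lung = lung))
}

.source_block <- function() {
  list(pressure_source("vsrc"),
       phase_valve("vsrc", "insp", "INSP", "PV_I"),
       phase_valve("exp", "vsrc", "EXP", "PV_E"))
}

#' Build the single-patient circuit
#'
#' Validation reduction of the standard splitter to one patient: source ->
#' inspiration arm (R_I) -> wye -> patient branch, with the expiration arm
#' (R_E) returning from the wye to the expiratory port.
#'
#' @param lung a [lung_model()].
#' @param splitter a [splitter_config()] (tubing resistances; topology field is
#'   not consulted).
#' @return A [netlist()].
#' @export
build_single <- function(lung, splitter = splitter_config("single")) {
  stopifnot(inherits(lung, "lung_model"), inherits(splitter, "splitter_config"))
  br <- .patient_branch(1, lung, "wye1")
  netlist(c(.source_block(),
            .series_chain("insp", "wye1", splitter$r_i, "R_I1")$comps,
            .series_chain("wye1", "exp", splitter$r_e, "R_E1")$comps,
            br$comps),
          patients = list(br$patient))
}

#' Build the standard splitter circuit
#'
#' Two T-junctions: the inspiratory port tees into one R_I arm per patient and
#' the two R_E arms tee into the expiratory port. No valves in the arms.
#'
#' @param lung1,lung2 [lung_model()]s for patients 1 and 2.
#' @param splitter a [splitter_config()] with topology "standard".
#' @return A [netlist()].
#' @export
build_standard <- function(lung1, lung2,
                           splitter = splitter_config("standard")) {
  stopifnot(inherits(lung1, "lung_model"), inherits(lung2, "lung_model"),
            inherits(splitter, "splitter_config"))
  comps <- .source_block()
  patients <- list()
  for (k in 1:2) {
    lung <- if (k == 1) lung1 else lung2
    wye <- paste0("wye", k)
    comps <- c(comps,
               .series_chain("insp", wye, splitter$r_i, paste0("R_I", k))$comps,
               .series_chain(wye, "exp", splitter$r_e, paste0("R_E", k))$comps)
    br <- .patient_branch(k, lung, wye)
    comps <- c(comps, br$comps)
    patients[[k]] <- br$patient
  }
  netlist(comps, patients = patients)
}

#' Build the modified splitter circuit
#'
#' As [build_standard()], plus a variable restrictor (R_V1/R_V2) in series with
#' each inspiration arm (between the inspiratory tee and R_I) and a one-way
#' valve in each expiration arm oriented to permit patient-to-ventilator flow
#' only. The valves stop the expiration arms from short-circuiting the two
#' inspiration arms during inspiration, decoupling the patients.
#'
#' @param lung1,lung2 [lung_model()]s for patients 1 and 2.
#' @param splitter a [splitter_config()] with topology "modified"; `r_v1` and
#'   `r_v2` set the restrictor resistances (0 = fully open).
#' @return A [netlist()].
#' @export
build_modified <- function(lung1, lung2,
                           splitter = splitter_config("modified")) {
  stopifnot(inherits(lung1, "lung_model"), inherits(lung2, "lung_model"),
            inherits(splitter, "splitter_config"))
  comps <- .source_block()
  patients <- list()
  for (k in 1:2) {
    lung <- if (k == 1) lung1 else lung2
    wye <- paste0("wye", k)
    r_v <- if (k == 1) splitter$r_v1 else splitter$r_v2
    comps <- c(comps,
               .series_chain("insp", wye, c(r_v, splitter$r_i),
                             paste0(c("R_V", "R_I"), k))$comps)
    ex <- paste0("ex", k)
    comps <- c(comps,
               .series_chain(wye, ex, splitter$r_e, paste0("R_E", k))$comps,
               list(check_valve(ex, "exp", paste0("D", k))))
    br <- .patient_branch(k, lung, wye)
    comps <- c(comps, br$comps)
    patients[[k]] <- br$patient
  }
  netlist(comps, patients = patients)
}

#' Build a netlist for a lung pair on a given topology
#'
#' Convenience dispatcher over [build_single()], [build_standard()] and
#' [build_modified()] using the topology recorded in `splitter`.
#'
#' @param lung1,lung2 [lung_model()]s; `lung2` is ignored for topology
#'   "single".
#' @param splitter a [splitter_config()].
#' @return A [netlist()].
#' @export
build_splitter <- function(lung1, lung2 = NULL, splitter) {
  switch(splitter$topology,
         single = build_single(lung1, splitter),
         standard = build_standard(lung1, lung2, splitter),
         modified = build_modified(lung1, lung2, splitter))
}
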