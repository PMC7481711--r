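# Lumped-element netlist: two-terminal components on named nodes, plus the
# conduction-state-consistent instantaneous nodal solve.
#
# Pneumatic-to-electrical mapping: volume <-> charge, flow <-> current,
# pressure <-> voltage, tube <-> resistor, lung+chest compliance <-> capacitor,
# one-way valve <-> diode, gated port <-> switch. All pressures are gauge
# (atmosphere = ground node = 0).
#
# Compliance bottom plates sit at ground, so at any instant the compliance top
# node potentials equal the state variables and the remaining resistive network
# is linear: assemble the nodal conductance matrix over the unknown internal
# nodes and solve. Check valves are piecewise-linear ideal diodes (small
# on-resistance, very large off-resistance); their conduction states are
# resolved by fixed-point iteration with exhaustive enumeration as fallback.

#' Netlist component constructors
#'
#' Two-terminal elements on named nodes. `check_valve(a, b)` permits flow from
#' `a` to `b` only; `phase_valve()` conducts only while the ventilator is in
#' the given phase. Compliances and the pressure source must have their second
#' terminal on the ground node.
#'
#' @param node_a,node_b node names (character).
#' @param value resistance in cmH2O/L/s (`resistor`) or compliance in L/cmH2O
#'   (`compliance`).
#' @param name component name, unique within a netlist.
#' @param gate phase in which a phase valve conducts, "INSP" or "EXP".
#' @return A component (a list with class `vent_component`).
#' @name components
NULL

.component <- function(kind, node_a, node_b, value = NA_real_,
                       orientation = NA_character_, gate = NA_character_,
                       name) {
  stopifnot(is.character(node_a), is.character(node_b),
            length(node_a) == 1L, length(node_b) == 1L)
  if (node_a == node_b) stop("component '", name, "': node_a == node_b")
  structure(list(kind = kind, node_a = node_a, node_b = node_b, value = value,
                 orientation = orientation, gate = gate, name = name),
            class = "vent_component")
}

#' @rdname components
#' @export
resistor <- function(node_a, node_b, value, name) {
  if (!is.numeric(value) || value <= 0) {
    stop("resistor '", name, "' must have value > 0 (merge nodes for a zero resistance)")
  }
  .component("RESISTOR", node_a, node_b, value, name = name)
}

#' @rdname components
#' @export
compliance <- function(node_a, value, name, node_b = "gnd") {
  if (!is.numeric(value) || value <= 0) stop("compliance '", name, "' must have value > 0")
  .component("COMPLIANCE", node_a, node_b, value, name = name)
}

#' @rdname components
#' @export
pressure_source <- function(node_a, name = "VENT", node_b = "gnd") {
  .component("SOURCE", node_a, node_b, name = name)
}

#' @rdname components
#' @export
check_valve <- function(node_a, node_b, name) {
  .component("CHECK_VALVE", node_a, node_b, orientation = "a_to_b", name = name)
}

#' @rdname components
#' @export
phase_valve <- function(node_a, node_b, gate = c("INSP", "EXP"), name) {
  gate <- match.arg(gate)
  .component("PHASE_VALVE", node_a, node_b, gate = gate, name = name)
}

#' Assemble a netlist
#'
#' @param components list of components (see [components]).
#' @param ground name of the ground (atmosphere) node.
#' @param patients per-patient probe metadata as produced by the splitter
#'   builders; a list of lists with fields `aw` (airway-pressure probe node,
#'   the R_ETT/R_L junction), `alv` (compliance top node), `comp` (compliance
#'   component name) and `c_l`.
#' @param r_on conducting (on) resistance of check and phase valves,
#'   cmH2O/L/s.
#' @param r_leak blocking (off) leak resistance of check and phase valves,
#'   cmH2O/L/s; keeps the nodal system nonsingular.
#' @return An object of class `vent_netlist`.
#' @export
netlist <- function(components, ground = "gnd", patients = list(),
                    r_on = 1e-4, r_leak = 1e8) {
  stopifnot(is.list(components), length(components) > 0)
  nm <- vapply(components, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate component names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  kinds <- vapply(components, `[[`, "", "kind")
  if (sum(kinds == "SOURCE") != 1L) stop("netlist must contain exactly one pressure source")
  for (cc in components) {
    if (cc$kind %in% c("COMPLIANCE", "SOURCE") && cc$node_b != ground) {
      stop("component '", cc$name, "' must have node_b on ground")
    }
  }
  nodes <- unique(c(ground, unlist(lapply(components, function(cc) c(cc$node_a, cc$node_b)))))
  # connectivity: every node reachable from ground through some component
  reach <- ground
  repeat {
    grew <- FALSE
    for (cc in components) {
      if (cc$node_a %in% reach && !(cc$node_b %in% reach)) { reach <- c(reach, cc$node_b); grew <- TRUE }
      if (cc$node_b %in% reach && !(cc$node_a %in% reach)) { reach <- c(reach, cc$node_a); grew <- TRUE }
    }
    if (!grew) break
  }
  if (length(setdiff(nodes, reach)) > 0) {
    stop("floating subnetwork: node(s) not connected to ground: ",
         paste(setdiff(nodes, reach), collapse = ", "))
  }
  structure(list(components = components, ground = ground, nodes = nodes,
                 patients = patients, r_on = r_on, r_leak = r_leak),
            class = "vent_netlist")
}

#' @export
print.vent_netlist <- function(x, ...) {
  cat(format_netlist(x), sep = "\n")
  invisible(x)
}

#' Plain-text netlist dump
#'
#' One component per line: kind, nodes, value (and orientation/gate where
#' applicable). Useful for debugging topologies.
#'
#' @param net a [netlist()].
#' @return Character vector, one line per component.
#' @export
format_netlist <- function(net) {
  stopifnot(inherits(net, "vent_netlist"))
  c(sprintf("netlist: %d components, %d nodes, ground '%s'",
            length(net$components), length(net$nodes), net$ground),
    vapply(net$components, function(cc) {
      extra <- switch(cc$kind,
                      CHECK_VALVE = " (permits a->b)",
                      PHASE_VALVE = paste0(" (gate ", cc$gate, ")"),
                      "")
      sprintf("  %-11s %-6s -> %-6s %s%s", cc$kind, cc$node_a, cc$node_b,
              ifelse(is.na(cc$value), "", format(cc$value)), extra)
    }, ""))
}

# ---- compiled form --------------------------------------------------------

# Precomputes node indexing so repeated instantaneous solves are cheap.
# Unknown nodes get positive indices 1..nu; known-potential nodes (ground,
# source node, compliance top nodes) get negative indices into the
# known-potential vector laid out as c(0, p_source, compliance states).
.compile_netlist <- function(net) {
  comps <- net$components
  kinds <- vapply(comps, `[[`, "", "kind")
  src_node <- comps[[which(kinds == "SOURCE")]]$node_a
  cap_idx <- which(kinds == "COMPLIANCE")
  cap_nodes <- vapply(comps[cap_idx], `[[`, "", "node_a")
  if (anyDuplicated(cap_nodes)) stop("two compliances share a node")
  known_nodes <- c(net$ground, src_node, cap_nodes)
  if (anyDuplicated(known_nodes)) {
    stop("source and compliance nodes must be distinct internal nodes")
  }
  unknown_nodes <- setdiff(net$nodes, known_nodes)
  node_code <- c(seq_along(unknown_nodes), -seq_along(known_nodes))
  names(node_code) <- c(unknown_nodes, known_nodes)

  list(
    net = net,
    kinds = kinds,
    names = vapply(comps, `[[`, "", "name"),
    values = vapply(comps, function(cc) ifelse(is.na(cc$value), 0, cc$value), 0),
    gates = vapply(comps, function(cc) ifelse(is.na(cc$gate), "", cc$gate), ""),
    ia = node_code[vapply(comps, `[[`, "", "node_a")],
    ib = node_code[vapply(comps, `[[`, "", "node_b")],
    nu = length(unknown_nodes),
    unknown_nodes = unknown_nodes,
    known_nodes = known_nodes,
    cap_idx = cap_idx,
    cap_names = vapply(comps[cap_idx], `[[`, "", "name"),
    cap_values = vapply(comps[cap_idx], `[[`, 0, "value"),
    cap_code = node_code[cap_nodes],   # negative indices of compliance nodes
    cv_idx = which(kinds == "CHECK_VALVE"),
    resistive = which(kinds %in% c("RESISTOR", "CHECK_VALVE", "PHASE_VALVE")),
    g_on = 1 / net$r_on,
    g_leak = 1 / net$r_leak
  )
}

# one linear nodal solve for a fixed conduction assignment
# vc: compliance node pressures in cap order; cv_state: logical per check valve
.nodal_solve <- function(cn, vc, phase, p_source, cv_state) {
  known <- c(0, p_source, vc)
  nu <- cn$nu
  G <- matrix(0, nu, nu)
  rhs <- numeric(nu)
  g_all <- numeric(length(cn$kinds))
  cv_seen <- 0L
  for (i in cn$resistive) {
    g <- switch(cn$kinds[i],
                RESISTOR = 1 / cn$values[i],
                CHECK_VALVE = {
                  cv_seen <- cv_seen + 1L
                  if (cv_state[cv_seen]) cn$g_on else cn$g_leak
                },
                PHASE_VALVE = if (cn$gates[i] == phase) cn$g_on else cn$g_leak)
    g_all[i] <- g
    a <- cn$ia[i]; b <- cn$ib[i]
    if (a > 0 && b > 0) {
      G[a, a] <- G[a, a] + g; G[b, b] <- G[b, b] + g
      G[a, b] <- G[a, b] - g; G[b, a] <- G[b, a] - g
    } else if (a > 0) {
      G[a, a] <- G[a, a] + g; rhs[a] <- rhs[a] + g * known[-b]
    } else if (b > 0) {
      G[b, b] <- G[b, b] + g; rhs[b] <- rhs[b] + g * known[-a]
    }
  }
  v_unknown <- if (nu > 0) {
    tryCatch(solve(G, rhs), error = function(e) {
      bad <- cn$unknown_nodes[which(abs(diag(G)) < .Machine$double.eps)]
      stop("singular network",
           if (length(bad)) paste0(" (floating node(s): ", paste(bad, collapse = ", "), ")"),
           call. = FALSE)
    })
  } else numeric(0)

  pot <- function(code) if (code > 0) v_unknown[code] else known[-code]
  flows <- numeric(length(cn$kinds))
  influx <- numeric(length(known))  # net resistive inflow at known nodes
  for (i in cn$resistive) {
    f <- g_all[i] * (pot(cn$ia[i]) - pot(cn$ib[i]))
    flows[i] <- f
    if (cn$ia[i] < 0) influx[-cn$ia[i]] <- influx[-cn$ia[i]] - f
    if (cn$ib[i] < 0) influx[-cn$ib[i]] <- influx[-cn$ib[i]] + f
  }
  # compliance charging currents and source delivery
  flows[cn$cap_idx] <- influx[-cn$cap_code]
  flows[cn$kinds == "SOURCE"] <- -influx[2L]
  pressures <- c(v_unknown, known)
  names(pressures) <- c(cn$unknown_nodes, cn$known_nodes)
  list(pressures = pressures, flows = flows, v_unknown = v_unknown)
}

# resolve check-valve conduction states to a consistent assignment
.consistent_solve <- function(cn, vc, phase, p_source, guess = NULL, tol = 1e-9) {
  ncv <- length(cn$cv_idx)
  state <- if (is.null(guess)) rep(TRUE, ncv) else as.logical(guess)
  if (length(state) != ncv) stop("conduction guess has wrong length")
  check <- function(sol, state) {
    if (ncv == 0L) return(list(ok = TRUE, state = state))
    ok <- logical(ncv)
    new <- state
    for (j in seq_len(ncv)) {
      i <- cn$cv_idx[j]
      if (state[j]) {                    # conducting: forward flow required
        ok[j] <- sol$flows[i] >= -tol
        if (!ok[j]) new[j] <- FALSE
      } else {                           # blocking: no forward driving pressure
        pot_a <- sol$pressures[[cn$net$components[[i]]$node_a]]
        pot_b <- sol$pressures[[cn$net$components[[i]]$node_b]]
        ok[j] <- (pot_a - pot_b) <= tol
        if (!ok[j]) new[j] <- TRUE
      }
    }
    list(ok = all(ok), state = new)
  }
  seen <- character(0)
  iters <- 0L
  repeat {
    iters <- iters + 1L
    sol <- .nodal_solve(cn, vc, phase, p_source, state)
    chk <- check(sol, state)
    if (chk$ok) {
      return(c(sol, list(cv_state = state, iterations = iters)))
    }
    key <- paste(as.integer(state), collapse = "")
    if (key %in% seen || iters > 2^ncv + 2L) break
    seen <- c(seen, key)
    state <- chk$state
  }
  # fixed point cycled: exhaustive enumeration over all conduction states
  combos <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), ncv)))
  for (r in seq_len(nrow(combos))) {
    state <- as.logical(combos[r, ])
    sol <- .nodal_solve(cn, vc, phase, p_source, state)
    chk <- check(sol, state)
    iters <- iters + 1L
    if (chk$ok) return(c(sol, list(cv_state = state, iterations = iters)))
  }
  stop("no consistent check-valve conduction assignment found (modelling bug?)")
}

#' Instantaneous network solve
#'
#' Solves the resistive network at one instant, given the compliance pressures
#' (the state variables), the ventilator phase and the source pressure. Check
#' valve conduction states are resolved so that every conducting valve carries
#' non-negative forward flow and every blocking valve sees non-positive forward
#' driving pressure; phase valves conduct iff their gate matches `phase`.
#'
#' @param net a [netlist()].
#' @param compliance_pressures named (or positional, in netlist order) vector
#'   of compliance node pressures, cmH2O.
#' @param phase "INSP" or "EXP".
#' @param p_source source pressure at this instant, cmH2O.
#' @param conduction_guess optional logical vector, initial conduction guess
#'   for the check valves in netlist order.
#' @return A list with `pressures` (named node potentials, cmH2O), `flows`
#'   (named branch flows, L/s, positive from node_a to node_b; for compliances
#'   the charging flow, for the source the delivered flow), `conduction`
#'   (named logical per check valve) and `iterations`.
#' @examples
#' net <- netlist(list(pressure_source("s"),
#'                     resistor("s", "m", 1, "R1"),
#'                     resistor("m", "gnd", 1, "R2")))
#' solve_instant(net, numeric(0), "INSP", 10)$pressures[["m"]] # 5
#' @export
solve_instant <- function(net, compliance_pressures, phase = c("INSP", "EXP"),
                          p_source, conduction_guess = NULL) {
  stopifnot(inherits(net, "vent_netlist"))
  phase <- match.arg(phase)
  cn <- .compile_netlist(net)
  vc <- compliance_pressures
  if (length(vc) != length(cn$cap_idx)) stop("need one pressure per compliance")
  if (!is.null(names(vc)) && length(vc)) vc <- vc[cn$cap_names]
  sol <- .consistent_solve(cn, as.numeric(vc), phase, p_source, conduction_guess)
  flows <- sol$flows
  names(flows) <- cn$names
  conduction <- sol$cv_state
  names(conduction) <- cn$names[cn$cv_idx]
  list(pressures = sol$pressures, flows = flows, conduction = conduction,
       iterations = sol$iterations)
}
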