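test_that("instantaneous solve satisfies nodal balance on a voltage divider", {
  net <- netlist(list(pressure_source("s"),
                      resistor("s", "m", 1, "R1"),
                      resistor("m", "gnd", 1, "R2")))
  sol <- solve_instant(net, numeric(0), "INSP", 10)
  expect_equal(sol$pressures[["m"]], 5)
  # net flow at the internal node is zero
  expect_lt(abs(sol$flows[["R1"]] - sol$flows[["R2"]]), 1e-10)
  # unequal divider
  net2 <- netlist(list(pressure_source("s"),
                       resistor("s", "m", 3, "R1"),
                       resistor("m", "gnd", 1, "R2")))
  expect_equal(solve_instant(net2, numeric(0), "INSP", 12)$pressures[["m"]], 3)
})

test_that("a reverse-biased check valve blocks flow down to the leak level", {
  net <- netlist(list(pressure_source("s"),
                      resistor("s", "n1", 1, "R1"),
                      check_valve("gnd", "n1", "Dv")))
  sol <- solve_instant(net, numeric(0), "INSP", 10)
  expect_false(sol$conduction[["Dv"]])
  expect_lt(abs(sol$flows[["Dv"]]), 1e-6)
  # forward-biased orientation conducts essentially the full current
  net_f <- netlist(list(pressure_source("s"),
                        resistor("s", "n1", 1, "R1"),
                        check_valve("n1", "gnd", "Dv")))
  sol_f <- solve_instant(net_f, numeric(0), "INSP", 10)
  expect_true(sol_f$conduction[["Dv"]])
  expect_equal(sol_f$flows[["Dv"]], 10, tolerance = 1e-3)
})

test_that("symmetric standard splitter carries no patient-to-patient cross flow", {
  net <- build_standard(LUNG$A, LUNG$A)
  # mid-inspiration with both lungs partially inflated to the same pressure
  sol <- solve_instant(net, c(C_L1 = 9, C_L2 = 9), "INSP", 15)
  expect_lt(abs(sol$flows[["R_E1"]]), 1e-6)
  expect_lt(abs(sol$flows[["R_E2"]]), 1e-6)
  expect_equal(sol$pressures[["wye1"]], sol$pressures[["wye2"]], tolerance = 1e-10)
  # flow into both lungs identical by symmetry
  expect_equal(sol$flows[["C_L1"]], sol$flows[["C_L2"]], tolerance = 1e-10)
})

test_that("phase valves gate the inspiratory and expiratory ports", {
  net <- build_single(LUNG$A)
  insp <- solve_instant(net, c(C_L1 = 7), "INSP", 15)
  exp_ <- solve_instant(net, c(C_L1 = 9), "EXP", 5)
  # inspiration: flow enters the lung through the inspiratory arm
  expect_gt(insp$flows[["R_I1"]], 0.1)
  expect_lt(abs(insp$flows[["R_E1"]]), 1e-6)
  # expiration: lung empties through the expiratory arm
  expect_lt(exp_$flows[["C_L1"]], -0.1)
  expect_gt(exp_$flows[["R_E1"]], 0.1)
  expect_lt(abs(exp_$flows[["R_I1"]]), 1e-6)
})

test_that("netlist validation rejects malformed networks", {
  expect_error(netlist(list(pressure_source("s"),
                            resistor("s", "gnd", 1, "R1"),
                            resistor("x", "y", 1, "R2"))),
               "floating")
  expect_error(netlist(list(pressure_source("s"),
                            resistor("s", "gnd", 1, "R1"),
                            resistor("s", "gnd", 1, "R1"))),
               "duplicate")
  expect_error(netlist(list(resistor("a", "gnd", 1, "R1"))),
               "exactly one pressure source")
  expect_error(resistor("a", "b", 0, "R0"), "> 0")
  expect_error(resistor("a", "a", 1, "Rx"), "node_a == node_b")
})

test_that("netlist dump lists one component per line", {
  txt <- format_netlist(build_modified(LUNG$A, LUNG$D))
  expect_match(txt[1], "components")
  expect_length(txt, 1 + length(build_modified(LUNG$A, LUNG$D)$components))
  expect_true(any(grepl("CHECK_VALVE", txt)))
  expect_true(any(grepl("gate INSP", txt)))
})
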