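test_that("pressure conversions match the clinical/S.I. reference values", {
  expect_equal(round(cmh2o_to_pa(15)), 1471)
  expect_equal(round(cmh2o_to_pa(5)), 490)
  expect_equal(cmh2o_to_pa(0), 0)
  expect_equal(resistance_clinical_to_si(2), 196133, tolerance = 1e-9)
  expect_equal(resistance_clinical_to_si(0), 0)
  # exact conversion of the ETT resistance; the conventional rounded value
  # 784000 differs by < 0.1%
  expect_equal(resistance_clinical_to_si(8), 784532, tolerance = 1e-6)
  expect_lt(abs(resistance_clinical_to_si(8) - 784000) / 784000, 1e-3)
  expect_equal(compliance_clinical_to_si(0.054), 5.5e-7, tolerance = 2e-3)
  expect_error(resistance_clinical_to_si(-1), "non-negative")
})

test_that("conversions round-trip to machine precision", {
  set.seed(42)
  p <- runif(50, 0, 80)
  r <- runif(50, 0, 1e3)
  expect_equal(pa_to_cmh2o(cmh2o_to_pa(p)), p, tolerance = 1e-12)
  expect_equal(resistance_si_to_clinical(resistance_clinical_to_si(r)), r,
               tolerance = 1e-12)
})

test_that("Poiseuille resistance reproduces the tubing derivation and scalings", {
  r <- poiseuille_resistance(0.022, 18.13e-6, 1.8)
  expect_equal(r, 5676, tolerance = 1e-3)
  expect_lt(abs(r - 5670) / 5670, 2e-3)        # rounded reference value
  # ~0.06 cmH2O/L/s in clinical units
  expect_equal(resistance_si_to_clinical(r), 0.06, tolerance = 0.05)
  expect_equal(poiseuille_resistance(0.022, 18.13e-6, 3.6), 2 * r)
  expect_equal(poiseuille_resistance(0.011, 18.13e-6, 1.8), 16 * r)
  expect_error(poiseuille_resistance(0, 1, 1), "positive")
})

test_that("lung presets encode the compliance-reduction ladder exactly", {
  expect_equal(lung_preset("A")$c_l, 0.054)
  expect_equal(lung_preset("B")$c_l, 0.0432)
  expect_equal(lung_preset("C")$c_l, 0.0378)
  expect_equal(lung_preset("D")$c_l, 0.0324)
  for (lab in c("A", "B", "C", "D")) {
    l <- lung_preset(lab)
    red <- c(A = 0, B = 0.2, C = 0.3, D = 0.4)[[lab]]
    expect_identical(l$c_l, 0.054 * (1 - red))
    expect_equal(l$r_l, 2)
    expect_equal(l$r_ett, 8)
  }
  expect_error(lung_preset("E"), "unknown")
})

test_that("domain constructors enforce their invariants", {
  expect_error(ventilator_settings(pip = 4, peep = 5), "pip")
  expect_error(ventilator_settings(peep = -1), "peep")
  expect_error(ventilator_settings(rr = 0), "rr")
  expect_error(ventilator_settings(ie = c(1, 0)), "I:E")
  expect_silent(ventilator_settings(pip = 5, peep = 5))  # constant-pressure case
  expect_error(lung_model(0), "compliance")
  expect_error(lung_model(0.05, r_l = -1), "resistances")
  expect_error(splitter_config(r_i = -0.1), ">= 0")
})

test_that("parameter registry offers exact and conventionally rounded S.I. values", {
  exact <- param_registry("exact")
  printed <- param_registry("printed")
  expect_equal(exact$si[exact$parameter == "R_ETT"], 784532, tolerance = 1e-6)
  expect_equal(printed$si[printed$parameter == "R_ETT"], 784000)
  # rows whose printed S.I. value is the (rounded) conversion of the clinical
  # value; R_I/R_E are excluded because their printed S.I. value comes from
  # the Poiseuille derivation while the clinical 0.06 is itself rounded
  conv <- exact$parameter %in% c("PEEP", "PIP", "R_L", "C_L", "R_ETT")
  expect_true(all(abs(exact$si[conv] - printed$si[conv]) /
                    printed$si[conv] < 2e-3))
})
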