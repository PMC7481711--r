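test_that("PIP titration reaches the tidal-volume band for a matched stiff pair", {
  tr <- tune_pip(LUNG$C, LUNG$C)
  expect_true(tr$converged)
  expect_gt(tr$pip, 18)
  expect_lt(tr$pip, 19)
  expect_lt(abs(tr$vt1 - 490), 10)
  expect_equal(tr$vt1, tr$vt2, tolerance = 1e-6)
})

test_that("PIP titration recognises an already-satisfied target", {
  tr <- tune_pip(LUNG$A, LUNG$A)
  expect_true(tr$converged)
  expect_lt(abs(tr$pip - 15), 0.25)
  expect_lt(abs(tr$vt1 - 490), 0.5)
})

test_that("PIP titration reports unreachable targets with the bracket", {
  expect_error(tune_pip(LUNG$D, LUNG$D, target_vt = 5000), "unreachable")
})

test_that("two-stage equalization balances a severely mismatched pair", {
  tr <- tune_modified(LUNG$A, LUNG$D)
  expect_true(tr$converged)
  expect_gt(tr$pip, 20)
  expect_lt(tr$pip, 20.8)
  expect_gt(tr$r_v1, 16)
  expect_lt(tr$r_v1, 19)
  expect_true(all(abs(c(tr$vt1, tr$vt2) - 490) <= 10))
  expect_equal(tr$r_v2, 0)
})

test_that("equalization requires patient 2 to be the stiffer patient", {
  expect_error(tune_modified(LUNG$D, LUNG$A), "lower-compliance")
})

test_that("equalization leaves matched lungs untouched", {
  tr <- tune_modified(LUNG$C, LUNG$C)
  expect_true(tr$converged)
  expect_lt(tr$r_v1, 0.5)
  expect_lt(abs(tr$vt1 - 490), 10)
})

test_that("independent adjustment lowers patient 2 while holding patient 1", {
  tr <- adjust_patient2(LUNG$C, LUNG$C, delta_fraction = -0.30)
  base <- attr(tr, "baseline")
  expect_true(tr$converged)
  expect_equal(tr$pip, 18.5)
  expect_equal(tr$r_v1, 0)
  expect_gt(tr$r_v2, 5)
  expect_lt(abs(tr$vt2 - 0.7 * base[2]), 1)
  expect_lt(abs(tr$vt1 - base[1]), 1)       # < 1 ml drift in patient 1
})

test_that("independent adjustment raises patient 2 via PIP and patient-1 restrictor", {
  tr <- adjust_patient2(LUNG$C, LUNG$C, delta_fraction = +0.30)
  base <- attr(tr, "baseline")
  expect_true(tr$converged)
  expect_gt(tr$pip, 18.5)
  expect_gt(tr$r_v1, 5)
  expect_equal(tr$r_v2, 0)
  expect_lt(abs(tr$vt2 - 1.3 * base[2]), 1)
  expect_lt(abs(tr$vt1 - base[1]), 1)
})

test_that("zero adjustment is the identity", {
  tr <- adjust_patient2(LUNG$C, LUNG$C, delta_fraction = 0)
  expect_equal(tr$pip, 18.5)
  expect_equal(tr$r_v1, 0)
  expect_equal(tr$r_v2, 0)
  expect_true(tr$converged)
  expect_error(adjust_patient2(LUNG$C, LUNG$C, delta_fraction = 1.2), "< 1")
})

test_that("tidal volume is monotone over the bisection brackets", {
  # increasing in PIP on the standard splitter
  net <- build_standard(LUNG$C, LUNG$C)
  vt_pip <- vapply(c(10, 14, 18, 25), function(p) {
    steady_vts(net, ref_settings(p))$vt[1]
  }, 0)
  expect_true(all(diff(vt_pip) > 0))
  # decreasing in the patient's own restrictor on the modified splitter
  vt_rv <- vapply(c(0, 8, 20, 50), function(rv) {
    steady_vts(build_modified(LUNG$A, LUNG$D,
                              splitter_config("modified", r_v1 = rv)),
               ref_settings(20.33))$vt[1]
  }, 0)
  expect_true(all(diff(vt_rv) < 0))
})
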