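test_that("standard splitter with matched healthy lungs delivers ~490 ml to both", {
  res <- steady_vts(build_standard(LUNG$A, LUNG$A), ref_settings())
  expect_lt(abs(res$vt[1] - 490.2), 1)
  expect_equal(res$vt[1], res$vt[2], tolerance = 1e-9)
})

test_that("modified splitter with open restrictors recovers the standard result", {
  s <- ref_settings()
  vt_std <- steady_vts(build_standard(LUNG$A, LUNG$A), s)$vt
  vt_mod <- steady_vts(build_modified(LUNG$A, LUNG$A,
                                      splitter_config("modified")), s)$vt
  expect_lt(max(abs(vt_std - vt_mod)), 0.1)
})

test_that("check valves only matter through their one-way action", {
  # replace the one-way valves by their conducting resistance: the modified
  # splitter with open restrictors must then match the standard splitter
  # even for a mismatched pair
  s <- ref_settings()
  net <- build_modified(LUNG$A, LUNG$D, splitter_config("modified"))
  net$components <- lapply(net$components, function(cc) {
    if (cc$kind == "CHECK_VALVE") {
      cc$kind <- "RESISTOR"
      cc$value <- net$r_on
    }
    cc
  })
  vt_wired <- steady_vts(net, s)$vt
  vt_std <- steady_vts(build_standard(LUNG$A, LUNG$D), s)$vt
  expect_lt(max(abs(vt_wired - vt_std)), 0.1)
})

test_that("expiration arms carry no flow during inspiration on the modified splitter", {
  net <- build_modified(LUNG$A, LUNG$D, splitter_config("modified"))
  ts <- simulate_circuit(net, ref_settings(), n_cycles = 4)
  # probe several mid-inspiration instants of the settled cycles
  rows <- which(ts$phase == "INSP" & ts$t > 8)
  for (i in rows[seq(1, length(rows), length.out = 5)]) {
    y <- c(ts$vol1[i] / LUNG$A$c_l, ts$vol2[i] / LUNG$D$c_l)
    sol <- solve_instant(net, y, "INSP", 15)
    expect_lt(abs(sol$flows[["R_E1"]]), 2e-6)
    expect_lt(abs(sol$flows[["R_E2"]]), 2e-6)
  }
})

test_that("raising one restrictor strictly reduces only that patient's volume", {
  s <- ref_settings(18.5)
  vt2 <- vapply(c(0, 5, 15, 30), function(rv) {
    spl <- splitter_config("modified", r_v2 = rv)
    steady_vts(build_modified(LUNG$C, LUNG$C, spl), s)$vt
  }, numeric(2))
  expect_true(all(diff(vt2[2, ]) < -1))          # own volume falls
  expect_lt(max(vt2[1, ]) - min(vt2[1, ]), 0.5)  # partner volume held
})

test_that("patient 1 is insensitive to the partner's compliance on the standard splitter", {
  s <- ref_settings()
  vt1 <- vapply(c("B", "C", "D"), function(lab) {
    steady_vts(build_standard(LUNG$A, LUNG[[lab]]), s)$vt[1]
  }, 0)
  expect_lt(max(vt1) - min(vt1), 0.2)
})

test_that("builders collapse zero-resistance elements onto shared nodes", {
  lung0 <- lung_model(0.054, r_l = 0, r_ett = 8)
  net <- build_single(lung0)
  p <- net$patients[[1]]
  expect_identical(p$aw, p$alv)   # probe collapses onto the compliance node
  res <- steady_vts(net, ref_settings())
  expect_lt(abs(res$vt[1] - oracle_vt(lung0, ref_settings())), 0.5)
})

test_that("topology dispatcher builds the requested circuit", {
  expect_length(build_splitter(LUNG$A, splitter = splitter_config("single"))$patients, 1)
  expect_length(build_splitter(LUNG$A, LUNG$B, splitter_config("standard"))$patients, 2)
  kinds <- vapply(build_splitter(LUNG$A, LUNG$B, splitter_config("modified"))$components,
                  `[[`, "", "kind")
  expect_equal(sum(kinds == "CHECK_VALVE"), 2)
})
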