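test_that("validation scenario reproduces matched-pair volumes and the closed form", {
  tab <- run_validation(tune = FALSE)
  expect_equal(tab$pair, c("A-A", "B-B", "C-C", "D-D"))
  expect_equal(tab$vt1_ml, tab$vt2_ml, tolerance = 1e-9)  # symmetry
  expect_true(all(abs(tab$resid_ml) < 0.5))               # simulator vs closed form
  expect_true(all(abs(tab$peep1 - 5) <= 0.1))
  expect_true(all(tab$steady_cycle <= 6))
})

test_that("standard splitter starves the stiffer patient; closed form tracks both", {
  tab <- run_standard_mismatch()
  ad <- tab[tab$pair == "A-D", ]
  expect_equal(round(ad$deficit_pct), 35)
  expect_gt(ad$deficit_ml, 170)
  # patient-2 volume falls as partner compliance falls
  ax <- tab[tab$pair %in% c("A-A", "A-B", "A-C", "A-D"), ]
  expect_true(all(diff(ax$vt2_ml) < 0))
  # single-branch prediction is within 0.5 ml even with cross coupling
  expect_true(all(abs(tab$vt1_ml - tab$vt1_oracle_ml) < 0.5))
  expect_true(all(abs(tab$vt2_ml - tab$vt2_oracle_ml) < 0.5))
})

test_that("independent-adjustment scenario holds patient 1 across its rows", {
  tab <- run_independent_adjust(adjust = FALSE)
  expect_equal(tab$label, c("C-C", "C-C(-)", "C-C(+)"))
  base <- tab$vt1_ml[1]
  expect_lt(abs(base - oracle_vt(LUNG$C, ref_settings(18.5))), 0.5)
  expect_lt(abs(tab$vt1_ml[2] - base), 0.5)   # restricting patient 2 leaves patient 1
  expect_lt(tab$vt2_ml[2], 0.8 * base)
  expect_gt(tab$vt2_ml[3], 1.2 * base)
})

test_that("YAML and JSON configurations build the same simulation", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("ventilator: {pip: 17, peep: 5, rr: 15, ie: [1, 2]}",
               "splitter: {topology: standard}",
               "patients: [B, C]"), yml)
  cfg <- read_config(yml)
  expect_equal(cfg$settings$pip, 17)
  expect_equal(cfg$patients[[2]]$c_l, 0.0378)
  jsn <- tempfile(fileext = ".json")
  writeLines('{"ventilator": {"pip": 17}, "splitter": {"topology": "standard"},
               "patients": ["B", "C"]}', jsn)
  cfg2 <- read_config(jsn)
  expect_equal(cfg2$settings$pip, cfg$settings$pip)
  net <- build_from_config(cfg)
  expect_length(net$patients, 2)
  # custom lung parameters pass through
  yml2 <- tempfile(fileext = ".yml")
  writeLines(c("splitter: {topology: single}",
               "patients:",
               "  - {c_l: 0.05, r_l: 3}"), yml2)
  expect_equal(read_config(yml2)$patients[[1]]$r_l, 3)
  expect_error(read_config(tempfile(fileext = ".txt")), "unsupported")
})

test_that("command line simulates a config file and writes the trace CSV", {
  cfgfile <- system.file("extdata", "example_config.yaml", package = "ventsplit")
  out <- tempfile(fileext = ".csv")
  ts <- vent_cli(c("simulate", "--config", cfgfile, "--cycles", "3",
                   "--out", out))
  expect_s3_class(ts, "vent_timeseries")
  header <- readLines(out, n = 1)
  expect_identical(header,
                   "t_s,phase,P_vent_cmH2O,P_aw1_cmH2O,P_aw2_cmH2O,flow1_L_s,flow2_L_s,vol1_L,vol2_L")
  df <- utils::read.csv(out)
  expect_equal(nrow(df), nrow(ts))
  expect_false(any(is.na(df$vol2_L)))
})

test_that("command line reproduces the validation table to CSV with metadata", {
  out <- tempfile(fileext = ".csv")
  tab <- vent_cli(c("reproduce", "validation", "--out", out))
  expect_equal(nrow(tab), 4)
  lines <- readLines(out)
  expect_match(lines[1], "^# experiment=validation")
  expect_error(vent_cli(c("reproduce", "tableX")), "unknown reproduction")
  expect_error(vent_cli(c("frobnicate")), "unknown verb")
})
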