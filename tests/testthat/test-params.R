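test_that("weekly regimen costs reproduce the published pricing arithmetic", {
  cases <- list(
    list(drug = 208 + 556, admin = 1288, cycle = 2, expect = 1026),    # FOLFOX
    list(drug = 331 + 556, admin = 335, cycle = 3, expect = 407.33),   # SOX
    list(drug = 677, admin = 335, cycle = 3, expect = 337.33),         # irinotecan
    list(drug = 180 + 556, admin = 335, cycle = 3, expect = 357),      # CAPOX
    list(drug = 331 + 348, admin = 335, cycle = 3, expect = 338),      # IRIS
    list(drug = 398, admin = 0, cycle = 3, expect = 132.67),           # S-1 mono
    list(drug = 180, admin = 0, cycle = 3, expect = 60)                # red. cape
  )
  for (cs in cases) {
    r <- regimen_cost("x", cs$drug, cs$admin, cs$cycle)
    expect_equal(weekly_cost(r), cs$expect, tolerance = 0.005)
  }
  expect_identical(weekly_cost(NULL), 0)
})

test_that("weekly cost is homogeneous of degree 1 in the cost fields", {
  set.seed(42)
  for (i in 1:20) {
    drug <- runif(1, 0, 2000); admin <- runif(1, 0, 2000)
    cyc <- sample(c(2, 3), 1); c0 <- runif(1, 0.1, 10)
    expect_equal(
      weekly_cost(regimen_cost("x", c0 * drug, c0 * admin, cyc)),
      c0 * weekly_cost(regimen_cost("x", drug, admin, cyc))
    )
  }
})

test_that("invalid cycle lengths and negative costs are rejected", {
  expect_error(regimen_cost("x", 100, 0, 4), "cycle_length")
  expect_error(regimen_cost("x", 100, 0, 1), "cycle_length")
  expect_error(regimen_cost("x", -1, 0, 2), "drug_cost_per_cycle")
  expect_error(regimen_from_components("x", "no_such", NA, 3), "component")
})

test_that("expected adverse-event cost is the probability-weighted sum over HFS and CVT", {
  expect_equal(expected_ae_cost(ae_profile_fluoropyrimidine()), 107.5)
  expect_equal(expected_ae_cost(ae_profile_s1()), 10.5)
  expect_equal(expected_ae_cost(adverse_event_profile()), 0)
  # diarrhoea/anorexia affect disutility only, never cost
  with_dia <- adverse_event_profile(p_hfs = 0.55, p_cvt = 0.40,
                                    p_diarrhoea = 0.9, p_anorexia = 0.9)
  expect_equal(expected_ae_cost(with_dia), 107.5)
})

test_that("adverse-event profiles validate their probabilities", {
  expect_error(adverse_event_profile(p_hfs = 1.2), "p_hfs")
  expect_error(adverse_event_profile(p_cvt = -0.1), "p_cvt")
  expect_error(adverse_event_profile(cost_hfs = -5), "cost")
  expect_error(adverse_event_profile(duration = 0), "duration")
})

test_that("bundled scenarios load with the published strategy sets", {
  capox <- load_scenario("capox")
  expect_s3_class(capox$scenario, "scenario_spec")
  expect_named(capox$scenario$strategies,
               c("stop_iri", "redCAPOX_iri", "SOX_iri", "SOX_IRIS"))
  expect_null(capox$scenario$strategies$stop_iri$first_line)
  expect_equal(capox$scenario$strategies$stop_iri$rr_os, 1.5)
  expect_equal(capox$scenario$strategies$SOX_iri$rr_os, 0.93)
  expect_equal(capox$scenario$strategies$SOX_iri$rr_ttp, 1.0)
  expect_true(capox$scenario$strategies$SOX_iri$s1_based)

  folfox <- load_scenario("folfox")
  expect_length(folfox$scenario$strategies, 4)
  expect_equal(
    weekly_cost(folfox$scenario$strategies$redFOLFOX_iri$first_line), 1026)

  cm <- load_scenario("cap_mono")
  expect_length(cm$scenario$strategies, 3)
  expect_named(cm$scenario$strategies, c("stop_iri", "redCAP_CAPOX", "S1_SOX"))

  # defaults filled
  expect_equal(capox$settings$p_second_line, 0.8)
  expect_equal(capox$settings$weeks_per_year, 365.25 / 7)
})

test_that("point estimates from the calibration table are preloaded exactly", {
  ct <- default_cost_table()
  expect_equal(unname(ct[c("s1_mono", "s1_combo", "cape_red", "oxaliplatin",
                           "fu_lv", "iri_mono", "iri_combo", "admin_short",
                           "admin_long")]),
               c(398, 331, 180, 556, 208, 677, 348, 335, 1288))
  capox <- load_scenario("capox")$scenario
  expect_equal(capox$strategies$redCAPOX_iri$ae$p_hfs, 0.55)
  expect_equal(capox$strategies$redCAPOX_iri$ae$p_cvt, 0.40)
  expect_equal(capox$strategies$SOX_iri$ae$p_hfs, 0.05)
  expect_equal(capox$strategies$SOX_iri$ae$p_cvt, 0.04)
  expect_equal(capox$strategies$SOX_iri$ae$cost_hfs, 50)
  expect_equal(capox$strategies$SOX_iri$ae$cost_cvt, 200)
  u <- utility_set()
  expect_equal(c(u$u_first_line, u$d_second_line, u$d_prog_no_treat, u$u_death),
               c(0.83, 0.15, 0.10, 0))
})

test_that("a configuration with an out-of-range probability is rejected by name", {
  cfg <- write_scenario(load_scenario("capox")$scenario,
                        load_scenario("capox")$settings)
  cfg$scenario$strategies[[2]]$ae$p_hfs <- 1.2
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  expect_error(load_scenario(f), "p_hfs")
})

test_that("scenario configurations round-trip through serialisation", {
  for (name in builtin_scenarios()) {
    cfg <- load_scenario(name)
    f <- tempfile(fileext = ".yaml")
    write_scenario(cfg$scenario, cfg$settings, file = f)
    cfg2 <- load_scenario(f)
    expect_equal(cfg2$scenario, cfg$scenario)
    expect_equal(cfg2$settings, cfg$settings)
    # canonical form is a fixed point of load . write
    expect_identical(write_scenario(cfg2$scenario, cfg2$settings),
                     write_scenario(cfg$scenario, cfg$settings))
  }
})

test_that("unknown scenarios and malformed configs raise descriptive errors", {
  expect_error(load_scenario("nosuch"), "unknown scenario")
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(scenario = list(name = "x")), f)
  expect_error(load_scenario(f), "strategies")
})
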