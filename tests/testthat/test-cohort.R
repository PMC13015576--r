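test_that("discount factors follow the closed form", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(500, 0), 1)
  expect_equal(discount_factor(365.25 / 7, 0.03, 365.25 / 7), 1 / 1.03)
  expect_error(discount_factor(10, -0.01), "domain")
})

test_that("cohort traces conserve mass and death is monotone for random draws", {
  set.seed(31)
  settings <- model_settings()
  scen <- toy_scenario()
  for (i in 1:100) {
    os <- random_weibull(); ttp <- random_weibull()
    s <- scen$strategies[[sample(2, 1)]]
    s$rr_os <- runif(1, 0.5, 2); s$rr_ttp <- runif(1, 0.5, 2)
    tr <- run_cohort(s, settings, os, ttp)
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
    expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-12))
    expect_true(all(tr$occupancy >= -1e-12))
  }
})

test_that("the progression state is transient: occupancy equals last week's first-line inflow", {
  settings <- model_settings()
  tr <- run_cohort(toy_scenario()$strategies$sox, settings)
  occ <- tr$occupancy
  H <- settings$horizon
  pd <- weekly_transition_prob(0:(H - 1), default_os_params(), 0.93)
  pp <- weekly_transition_prob(0:(H - 1), default_ttp_params(), 1)
  inflow <- occ[1:H, "first_line"] * (1 - pd) * pp
  expect_equal(unname(occ[2:(H + 1), "progression"]), unname(inflow),
               tolerance = 1e-12)
  expect_equal(tr$new_progressions, unname(occ[, "progression"]))
})

test_that("degenerate transition probabilities behave as absorbing limits", {
  settings <- model_settings(horizon = 20)
  s <- toy_scenario()$strategies$sox
  s$rr_os <- 0; s$rr_ttp <- 0
  tr <- run_cohort(s, settings)
  expect_equal(unname(tr$occupancy[21, "first_line"]), 1)
  # near-immediate death: whole cohort in the absorbing state from week 1
  s2 <- toy_scenario()$strategies$sox
  s2$rr_os <- 1
  tr2 <- run_cohort(s2, settings, os = weibull_params(4, 1e-3))
  expect_equal(unname(tr2$occupancy[2:21, "death"]), rep(1, 20),
               tolerance = 1e-12)
})

test_that("the cohort survival curve reproduces the fitted distribution when rr = 1", {
  settings <- model_settings()
  s <- toy_scenario()$strategies$sox
  s$rr_os <- 1
  tr <- run_cohort(s, settings)
  alive <- 1 - tr$occupancy[, "death"]
  expect_lt(max(abs(alive - survival_at(0:settings$horizon,
                                        default_os_params()))), 1e-6)
})

test_that("accrual splits costs by source and prices discontinuation at zero", {
  cfg <- load_scenario("capox")
  outs <- lapply(cfg$scenario$strategies, run_strategy,
                 settings = cfg$settings)
  tab <- outcomes_table(outs)
  expect_equal(tab$total_cost,
               tab$cost_first_line + tab$cost_second_line + tab$cost_ae,
               tolerance = 1e-9)
  stop_row <- tab[tab$strategy == "stop_iri", ]
  expect_equal(stop_row$cost_first_line, 0)
  expect_equal(stop_row$cost_ae, 0)
  expect_equal(stop_row$mean_cycles_first_line, 0)
  # point-estimate checks against the published per-strategy cells
  expect_equal(tab$cost_ae[tab$strategy == "redCAPOX_iri"], 107.5)
  expect_equal(tab$pct_progressed[tab$strategy == "SOX_iri"], 65,
               tolerance = 0.02)
  expect_true(all(tab$qalys >= 0))
  expect_true(all(tab$pct_progressed >= 0 & tab$pct_progressed <= 100))
})

test_that("undiscounted cost approximates cycles times per-cycle cost", {
  cfg <- load_scenario("capox")
  s <- cfg$scenario$strategies$SOX_iri
  o <- run_strategy(s, cfg$settings)
  per_cycle <- s$first_line$drug_cost_per_cycle + s$first_line$admin_cost_per_cycle
  expect_lt(abs(o$cost_first_line - o$mean_cycles_first_line * per_cycle) /
              (o$mean_cycles_first_line * per_cycle), 0.10)
})

test_that("removing discounting increases both costs and QALYs", {
  cfg <- load_scenario("capox")
  s <- cfg$scenario$strategies$SOX_iri
  base <- run_strategy(s, cfg$settings)
  undisc <- run_strategy(s, model_settings(discount_costs = 0,
                                           discount_qalys = 0))
  expect_gt(undisc$total_cost, base$total_cost)
  expect_gt(undisc$qalys, base$qalys)
})

test_that("treatment discontinuation yields the fewest QALYs at default parameters", {
  for (name in builtin_scenarios()) {
    cfg <- load_scenario(name)
    tab <- outcomes_table(lapply(cfg$scenario$strategies, run_strategy,
                                 settings = cfg$settings))
    stop_q <- tab$qalys[tab$strategy == "stop_iri"]
    expect_true(all(tab$qalys[tab$strategy != "stop_iri"] > stop_q))
  }
})

test_that("a zero-utility configuration accrues zero QALYs", {
  cfg <- load_scenario("capox")
  s <- cfg$scenario$strategies$SOX_iri
  tr <- run_cohort(s, cfg$settings)
  o <- accrue(tr, s, cfg$settings,
              utilities = utility_set(u_first_line = 0, d_second_line = 0,
                                      d_prog_no_treat = 0))
  expect_equal(o$qalys, 0)
})

test_that("utilities that leave a state below zero are rejected", {
  expect_error(utility_set(u_first_line = 0.1, d_second_line = 0.15),
               "utility")
})

test_that("trace export round-trips through the delimited format", {
  cfg <- load_scenario("capox")
  tr <- run_cohort(cfg$scenario$strategies$SOX_iri, cfg$settings)
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read.csv(f)
  expect_equal(names(back),
               c("week", "s_first_line", "s_progression",
                 "s_second_line_treat", "s_prog_no_treat", "s_death",
                 "new_progressions"))
  expect_equal(back$s_death, unname(tr$occupancy[, "death"]))
})
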