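test_that("gamma cost draws have the stated mean and variance", {
  set.seed(41)
  n <- 1e5
  c_mean <- 398
  x <- rgamma(n, shape = sqrt(c_mean), rate = 1 / sqrt(c_mean))
  # var = shape / rate^2 = c^1.5
  se <- sqrt(c_mean^1.5 / n)
  expect_lt(abs(mean(x) - c_mean), 3 * se)
  expect_lt(abs(var(x) - c_mean^1.5) / c_mean^1.5, 0.05)
  # the sampler itself reproduces the mean for every tabulated cost
  draws <- replicate(4000, sample_parameters(psa_distributions())$costs)
  mns <- rowMeans(draws)
  ses <- sqrt(default_cost_table()^1.5 / 4000)
  expect_true(all(abs(mns - default_cost_table()) < 4 * ses))
})

test_that("sampled parameters reproduce their calibration distributions", {
  set.seed(43)
  d <- psa_distributions()
  draws <- replicate(5000, {
    s <- sample_parameters(d)
    c(s$os$shape, s$os$scale, s$ttp$shape, s$ttp$scale, s$rr_s1,
      s$u_first_line)
  })
  # lognormal relative risk: median at the point estimate 0.93
  expect_equal(median(draws[5, ]), exp(-0.0726), tolerance = 0.01)
  # bivariate normal pairs: means, and bootstrap correlations 0.555 / -0.255
  expect_equal(mean(draws[1, ]), 1.473, tolerance = 0.01)
  expect_equal(mean(draws[2, ]), 79.4, tolerance = 0.01)
  # 4x the large-sample SE of a correlation at n = 5000
  expect_lt(abs(cor(draws[1, ], draws[2, ]) - 0.555),
            4 * (1 - 0.555^2) / sqrt(5000))
  expect_lt(abs(cor(draws[3, ], draws[4, ]) + 0.255),
            4 * (1 - 0.255^2) / sqrt(5000))
  expect_equal(mean(draws[6, ]), 0.83, tolerance = 0.001)
  expect_true(all(draws[6, ] >= 0 & draws[6, ] <= 1))
  expect_true(all(draws[1:4, ] > 0))
})

test_that("degenerate distributions collapse to the point estimates", {
  d <- psa_distributions(utility_sd = 0, rr_s1_sdlog = 0,
                         os_sd = c(1e-12, 1e-12), ttp_sd = c(1e-12, 1e-12))
  set.seed(44)
  s <- sample_parameters(d)
  expect_equal(s$u_first_line, 0.83)
  expect_equal(s$rr_s1, exp(-0.0726))
  expect_equal(s$os$shape, 1.473, tolerance = 1e-6)
  expect_equal(s$os$scale, 79.4, tolerance = 1e-6)
  expect_equal(s$ttp$shape, 1.560, tolerance = 1e-6)
})

test_that("the probabilistic analysis is reproducible from its seed", {
  scen <- toy_scenario()
  settings <- model_settings()
  a <- run_psa(scen, settings, n_runs = 5, seed = 99)
  b <- run_psa(scen, settings, n_runs = 5, seed = 99)
  expect_identical(a$draws, b$draws)
  expect_identical(a$params, b$params)
  c2 <- run_psa(scen, settings, n_runs = 5, seed = 100)
  expect_false(identical(a$draws, c2$draws))
})

test_that("strategies within a run share one parameter draw", {
  scen <- toy_scenario()
  settings <- model_settings()
  psa <- run_psa(scen, settings, n_runs = 4, seed = 7)
  # recompute each strategy outcome from the stored per-run parameters; if
  # draws were not shared, the recomputation could not match both rows
  for (i in 1:4) {
    par <- psa$params[psa$params$run == i, ]
    os <- weibull_params(par$os_shape, par$os_scale)
    ttp <- weibull_params(par$ttp_shape, par$ttp_scale)
    util <- utility_set(u_first_line = par$u_first_line)
    costs <- default_cost_table()
    costs[] <- as.numeric(par[names(costs)][1, ])
    for (nm in names(scen$strategies)) {
      s <- scen$strategies[[nm]]
      s$first_line <- s1switch:::reprice_regimen(s$first_line, costs)
      s$second_line <- s1switch:::reprice_regimen(s$second_line, costs)
      if (s$s1_based) s$rr_os <- par$rr_s1
      o <- run_strategy(s, settings, os, ttp, util)
      row <- psa$draws[psa$draws$run == i & psa$draws$strategy == nm, ]
      expect_equal(row$total_cost, o$total_cost, tolerance = 1e-9)
      expect_equal(row$qalys, o$qalys, tolerance = 1e-9)
    }
  }
})

test_that("PSA means converge to the deterministic run as uncertainty vanishes", {
  scen <- toy_scenario()
  settings <- model_settings()
  d0 <- psa_distributions(utility_sd = 0, rr_s1_sdlog = 0,
                          os_sd = c(1e-12, 1e-12), ttp_sd = c(1e-12, 1e-12),
                          cost_means = default_cost_table() * 1e-12)
  psa <- run_psa(scen, settings, dists = d0, n_runs = 3, seed = 5)
  # gamma draws keep some spread; null the cost channel and compare QALYs
  det <- lapply(scen$strategies, function(s) {
    if (s$s1_based) s$rr_os <- exp(-0.0726)
    run_strategy(s, settings)
  })
  expect_equal(psa$summary$qalys,
               vapply(det, function(o) o$qalys, numeric(1)),
               ignore_attr = TRUE, tolerance = 1e-6)
  # and n_runs = 1 with vanishing spread equals the single run exactly
  psa1 <- run_psa(scen, settings, dists = d0, n_runs = 1, seed = 5)
  expect_equal(psa1$summary$qalys, psa$summary$qalys, tolerance = 1e-9)
})

test_that("mean PSA outcomes and cost draws stay near calibration means at n = 1000 scale", {
  scen <- toy_scenario()
  settings <- model_settings()
  psa <- run_psa(scen, settings, n_runs = 300, seed = 12)
  par <- psa$params
  expect_equal(mean(par$os_shape), 1.473, tolerance = 0.02)
  expect_equal(mean(par$os_scale), 79.4, tolerance = 0.02)
  expect_equal(mean(par$u_first_line), 0.83, tolerance = 0.005)
  mns <- colMeans(par[names(default_cost_table())])
  ses <- sqrt(default_cost_table()^1.5 / nrow(par))
  expect_true(all(abs(mns - default_cost_table()) < 4 * ses))
})

test_that("PSA exports one row per run and strategy", {
  psa <- run_psa(toy_scenario(), model_settings(), n_runs = 6, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_psa(psa, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 12)
  expect_true(all(c("run", "strategy", "total_cost", "qalys") %in% names(back)))
  expect_equal(sort(unique(back$run)), 1:6)
})
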