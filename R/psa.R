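#' Uncertainty distributions for probabilistic sensitivity analysis
#'
#' Encodes the uncertainty attached to each calibration parameter:
#' \itemize{
#'   \item costs: gamma with shape `sqrt(c)` and rate `1/sqrt(c)` for a
#'     point estimate `c` (so the mean is exactly `c` and the variance
#'     `c^1.5`);
#'   \item the S-1 overall-survival relative risk: lognormal(-0.0726,
#'     0.058), median 0.93;
#'   \item first-line utility: normal(0.83, 0.01), truncated to `[0, 1]`;
#'   \item the Weibull (shape, scale) pairs: bivariate normal with the
#'     fitted means, standard errors and bootstrap shape-scale
#'     correlations (0.555 for OS, -0.255 for TTP), redrawn if a component
#'     is non-positive.
#' }
#' The discontinuation relative risk (1.50), adverse-event probabilities
#' and costs, disutilities and the second-line treatment proportion are
#' fixed.
#'
#' @param cost_means Named vector of per-cycle cost means to sample.
#' @param rr_s1_meanlog,rr_s1_sdlog Lognormal parameters of the S-1 OS
#'   relative risk.
#' @param utility_mean,utility_sd Normal parameters of the first-line
#'   utility.
#' @param os_mean,os_sd,os_cor OS Weibull (shape, scale) means, SDs and
#'   correlation.
#' @param ttp_mean,ttp_sd,ttp_cor TTP Weibull (shape, scale) means, SDs
#'   and correlation.
#' @return An object of class `psa_distributions`.
#' @export
psa_distributions <- function(cost_means = default_cost_table(),
                              rr_s1_meanlog = -0.0726, rr_s1_sdlog = 0.058,
                              utility_mean = 0.83, utility_sd = 0.01,
                              os_mean = c(1.473, 79.4),
                              os_sd = c(0.096, 4.874), os_cor = 0.555,
                              ttp_mean = c(1.560, 53.9),
                              ttp_sd = c(0.107, 3.243), ttp_cor = -0.255) {
  if (abs(os_cor) > 1 || abs(ttp_cor) > 1) {
    stop("configuration error: correlations must lie in [-1, 1]")
  }
  if (any(c(os_sd, ttp_sd) <= 0) || rr_s1_sdlog < 0 || utility_sd < 0) {
    stop("configuration error: standard deviations must be > 0")
  }
  if (any(cost_means < 0)) {
    stop("configuration error: cost means must be >= 0")
  }
  structure(
    list(cost_means = cost_means,
         rr_s1_meanlog = rr_s1_meanlog, rr_s1_sdlog = rr_s1_sdlog,
         utility_mean = utility_mean, utility_sd = utility_sd,
         os_mean = os_mean, os_sd = os_sd, os_cor = os_cor,
         ttp_mean = ttp_mean, ttp_sd = ttp_sd, ttp_cor = ttp_cor),
    class = "psa_distributions"
  )
}

#' Draw a per-cycle cost from its gamma uncertainty distribution
#'
#' Shape `sqrt(c)`, rate `1/sqrt(c)`: the mean is exactly the point
#' estimate `c`. A zero point estimate stays zero.
#' @param c_mean Point estimate(s) (EUR); vectorised.
#' @return Sampled cost(s).
#' @keywords internal
rgamma_cost <- function(c_mean) {
  out <- c_mean
  pos <- c_mean > 0
  out[pos] <- stats::rgamma(sum(pos), shape = sqrt(c_mean[pos]),
                            rate = 1 / sqrt(c_mean[pos]))
  out
}

rbvnorm_positive <- function(mean, sd, rho, max_tries = 1000L) {
  Sigma <- diag(sd) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(sd)
  for (i in seq_len(max_tries)) {
    x <- drop(MASS::mvrnorm(1, mu = mean, Sigma = Sigma))
    if (all(x > 0)) return(x)
  }
  stop("sampling error: could not draw positive Weibull parameters")
}

rnorm_unit <- function(mean, sd, max_tries = 1000L) {
  if (sd == 0) return(mean)
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= 0 && x <= 1) return(x)
  }
  stop("sampling error: could not draw a utility in [0, 1]")
}

#' Draw one full parameter set
#'
#' Samples every uncertain parameter once from `dists` using the current
#' RNG state. The same draw is shared by all strategies of a scenario
#' within a PSA run, so incremental comparisons are paired.
#'
#' @param dists A `psa_distributions`.
#' @return A list with `costs` (named per-cycle cost vector), `rr_s1`,
#'   `u_first_line`, and `os`, `ttp` (`weibull_params`).
#' @export
sample_parameters <- function(dists) {
  stopifnot(inherits(dists, "psa_distributions"))
  costs <- rgamma_cost(dists$cost_means)
  rr_s1 <- stats::rlnorm(1, dists$rr_s1_meanlog, dists$rr_s1_sdlog)
  u <- rnorm_unit(dists$utility_mean, dists$utility_sd)
  os <- rbvnorm_positive(dists$os_mean, dists$os_sd, dists$os_cor)
  ttp <- rbvnorm_positive(dists$ttp_mean, dists$ttp_sd, dists$ttp_cor)
  list(costs = costs, rr_s1 = rr_s1, u_first_line = u,
       os = weibull_params(os[1], os[2]), ttp = weibull_params(ttp[1], ttp[2]))
}

apply_draw <- function(strategy, draw) {
  s <- strategy
  s$first_line <- reprice_regimen(s$first_line, draw$costs)
  s$second_line <- reprice_regimen(s$second_line, draw$costs)
  if (s$s1_based) s$rr_os <- draw$rr_s1
  s
}

#' Run the probabilistic sensitivity analysis
#'
#' Runs the cohort model `n_runs` times per strategy, each run under a
#' common parameter draw shared by all strategies of the scenario.
#' Reproducible from `seed`: one RNG substream is derived per run index,
#' so results do not depend on execution order.
#'
#' @param scenario A `scenario_spec`.
#' @param settings A `model_settings`.
#' @param dists A `psa_distributions`.
#' @param n_runs Number of PSA runs (default 1000).
#' @param seed Integer master seed.
#' @return An object of class `psa_results`: `draws` (long data frame of
#'   per-run, per-strategy outcomes), `params` (per-run sampled
#'   parameters), `summary` (per-strategy means over runs), `n_runs`,
#'   `seed`.
#' @export
run_psa <- function(scenario, settings, dists = psa_distributions(),
                    n_runs = 1000, seed = 20260317) {
  stopifnot(inherits(scenario, "scenario_spec"), n_runs >= 1)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  utilities0 <- utility_set()
  draws <- vector("list", n_runs)
  params <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    set.seed(run_seeds[i])
    draw <- sample_parameters(dists)
    util <- utility_set(u_first_line = draw$u_first_line,
                        d_second_line = utilities0$d_second_line,
                        d_prog_no_treat = utilities0$d_prog_no_treat)
    out <- lapply(scenario$strategies, function(strat) {
      s <- apply_draw(strat, draw)
      tryCatch(
        run_strategy(s, settings, os = draw$os, ttp = draw$ttp,
                     utilities = util),
        error = function(e) {
          stop("PSA run ", i, " (strategy '", strat$name, "'): ",
               conditionMessage(e))
        }
      )
    })
    tab <- outcomes_table(out)
    tab$run <- i
    draws[[i]] <- tab
    params[[i]] <- data.frame(
      run = i, os_shape = draw$os$shape, os_scale = draw$os$scale,
      ttp_shape = draw$ttp$shape, ttp_scale = draw$ttp$scale,
      rr_s1 = draw$rr_s1, u_first_line = draw$u_first_line,
      t(draw$costs)
    )
  }
  draws <- do.call(rbind, draws)
  rownames(draws) <- NULL
  num_cols <- setdiff(names(draws), c("strategy", "run"))
  summary <- do.call(rbind, lapply(split(draws, draws$strategy), function(d) {
    cbind(data.frame(strategy = d$strategy[1]),
          as.data.frame(as.list(colMeans(d[num_cols], na.rm = TRUE))))
  }))
  # preserve scenario strategy order
  summary <- summary[match(names(scenario$strategies), summary$strategy), ]
  rownames(summary) <- NULL
  structure(
    list(scenario = scenario$name, draws = draws,
         params = do.call(rbind, params), summary = summary,
         n_runs = n_runs, seed = seed),
    class = "psa_results"
  )
}

#' @export
print.psa_results <- function(x, ...) {
  cat("<psa_results>", x$scenario, "-", x$n_runs, "runs, seed", x$seed, "\n")
  print(x$summary[, c("strategy", "total_cost", "qalys")], digits = 4)
  invisible(x)
}

#' Export PSA draws in long format
#'
#' One row per run and strategy, enabling external recomputation of
#' acceptability curves.
#' @param psa A `psa_results`.
#' @param file Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
write_psa <- function(psa, file) {
  d <- psa$draws[, c("run", "strategy", setdiff(names(psa$draws),
                                                c("run", "strategy")))]
  utils::write.csv(d, file, row.names = FALSE)
  invisible(d)
}
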