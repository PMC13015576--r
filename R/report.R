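format_outcome_table <- function(tab) {
  out <- tab
  eur <- c("total_cost", "cost_first_line", "cost_second_line", "cost_ae")
  for (cn in eur) out[[cn]] <- round(out[[cn]])
  out$qalys <- round(out$qalys, 2)
  out$median_os <- round(out$median_os, 1)
  out$median_ttp <- round(out$median_ttp, 1)
  out$mean_cycles_first_line <- round(out$mean_cycles_first_line, 1)
  out$mean_cycles_second_line <- round(out$mean_cycles_second_line, 1)
  out$pct_progressed <- round(out$pct_progressed)
  out
}

write_manifest <- function(path, scenario_name, settings, seed, n_runs,
                           deterministic, outputs, extra = list()) {
  manifest <- c(list(
    scenario = scenario_name,
    settings = list(
      horizon_weeks = settings$horizon,
      weeks_per_year = settings$weeks_per_year,
      discount_costs = settings$discount_costs,
      discount_qalys = settings$discount_qalys,
      p_second_line = settings$p_second_line,
      cohort_size = settings$cohort_size
    ),
    seed = seed, n_runs = n_runs, deterministic = deterministic,
    package_version = as.character(utils::packageVersion("s1switch")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outputs = as.list(outputs)
  ), extra)
  yaml::write_yaml(manifest, path, precision = 15)
  invisible(manifest)
}

#' Run a scenario end to end and write all result tables
#'
#' Loads a scenario (bundled name or YAML path), runs either a single
#' deterministic evaluation at the point estimates or a full probabilistic
#' sensitivity analysis, and writes to `out_dir`: the per-strategy outcome
#' table (`outcomes.csv`, published-table column order and rounding, plus
#' `outcomes_raw.csv` at full precision), per-strategy cohort traces at
#' point estimates (`trace_<strategy>.csv`), the dominance frontier
#' (`frontier.csv`), acceptability curves (`ceac.csv`, PSA only), the
#' long-format PSA draws (`psa_draws.csv`), and a run manifest
#' (`manifest.yaml`) from which the run is exactly reproducible.
#'
#' @param scenario Bundled scenario name or path to a YAML config.
#' @param out_dir Output directory (created if needed).
#' @param n_runs Number of PSA runs.
#' @param seed Integer master seed.
#' @param deterministic If `TRUE`, a single run at point estimates
#'   replaces the PSA.
#' @return Invisibly, a list with the computed objects and output paths.
#' @export
cea_run <- function(scenario, out_dir, n_runs = 1000, seed = 20260317,
                    deterministic = FALSE) {
  cfg <- load_scenario(scenario)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- function(f) file.path(out_dir, f)

  if (deterministic) {
    outs <- lapply(cfg$scenario$strategies, run_strategy,
                   settings = cfg$settings)
    tab <- outcomes_table(outs)
    psa <- NULL
    cc <- NULL
  } else {
    psa <- run_psa(cfg$scenario, cfg$settings, n_runs = n_runs, seed = seed)
    tab <- psa$summary
    cc <- ceac(psa)
  }
  fr <- frontier(tab, reference = cfg$scenario$reference_strategy)

  utils::write.csv(format_outcome_table(tab), p("outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(tab, p("outcomes_raw.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(fr), p("frontier.csv"), row.names = FALSE)
  paths <- c(paths, "outcomes.csv", "outcomes_raw.csv", "frontier.csv")
  for (s in cfg$scenario$strategies) {
    f <- paste0("trace_", s$name, ".csv")
    write_trace(run_cohort(s, cfg$settings), p(f))
    paths <- c(paths, f)
  }
  if (!is.null(cc)) {
    utils::write.csv(as.data.frame(cc), p("ceac.csv"), row.names = FALSE)
    write_psa(psa, p("psa_draws.csv"))
    paths <- c(paths, "ceac.csv", "psa_draws.csv")
  }
  write_manifest(p("manifest.yaml"), cfg$scenario$name, cfg$settings,
                 seed = seed, n_runs = if (deterministic) 1L else n_runs,
                 deterministic = deterministic, outputs = paths)
  invisible(list(scenario = cfg$scenario, settings = cfg$settings,
                 outcomes = tab, frontier = fr, ceac = cc, psa = psa,
                 out_dir = out_dir, outputs = file.path(out_dir, paths)))
}

#' Run a sensitivity-analysis variant and write its result tables
#'
#' @param scenario Bundled scenario name or YAML config path.
#' @param variant One of `rr12`/`rr_1.2`, `rr15`/`rr_1.5`, `rr18`/`rr_1.8`,
#'   `cond9w`/`conditional_9wk` (see [run_sensitivity()]).
#' @inheritParams cea_run
#' @return Invisibly, the [run_sensitivity()] bundle plus output paths.
#' @export
cea_sensitivity <- function(scenario, variant, out_dir, n_runs = 1000,
                            seed = 20260317) {
  cfg <- load_scenario(scenario)
  res <- run_sensitivity(cfg$scenario, cfg$settings, variant,
                         n_runs = n_runs, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(format_outcome_table(res$psa$summary), p("outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(res$psa$summary, p("outcomes_raw.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$frontier), p("frontier.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$ceac), p("ceac.csv"), row.names = FALSE)
  paths <- c("outcomes.csv", "outcomes_raw.csv", "frontier.csv", "ceac.csv")
  write_manifest(p("manifest.yaml"), cfg$scenario$name, cfg$settings,
                 seed = seed, n_runs = n_runs, deterministic = FALSE,
                 outputs = paths, extra = list(variant = res$variant))
  invisible(c(res, list(out_dir = out_dir,
                        outputs = file.path(out_dir, paths))))
}

#' Simulate a synthetic trial dataset and write it to disk
#'
#' Writes an individual-patient table and prints a fit summary comparing
#' the exponential and Weibull models on the simulated overall survival
#' (the Weibull should win on AIC under the default generating shape).
#'
#' @param out_file Output CSV path.
#' @param n Number of patients (>= 10).
#' @param seed Integer seed.
#' @inheritParams simulate_ipd
#' @return Invisibly, a list with the `ipd` table and both `fit_result`s.
#' @export
cea_simulate <- function(out_file, n = 160, seed = 20260317,
                         os = default_os_params(), ttp = default_ttp_params(),
                         censor_time = 156, accrual_weeks = 104) {
  ipd <- simulate_ipd(n = n, os = os, ttp = ttp, censor_time = censor_time,
                      accrual_weeks = accrual_weeks, seed = seed)
  write_ipd(ipd, out_file)
  fw <- fit_parametric(ipd, "os", "weibull")
  fe <- fit_parametric(ipd, "os", "exponential")
  message(sprintf("wrote %d patients to %s", nrow(ipd), out_file))
  message(sprintf("OS fit: Weibull AIC %.1f vs exponential AIC %.1f (%s preferred)",
                  fw$AIC, fe$AIC,
                  if (fw$AIC < fe$AIC) "Weibull" else "exponential"))
  invisible(list(ipd = ipd, weibull = fw, exponential = fe,
                 out_file = out_file))
}
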