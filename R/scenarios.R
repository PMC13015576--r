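#' Names of the bundled treatment scenarios
#'
#' Three clinical settings are bundled, one per first-line treatment on
#' which hand-foot syndrome or cardiovascular toxicity occurred:
#' `"capox"` (4 strategies: discontinuation -> irinotecan, reduced CAPOX ->
#' irinotecan, SOX -> irinotecan, SOX -> IRIS), `"folfox"` (same with
#' reduced FOLFOX), and `"cap_mono"` (3 strategies: discontinuation ->
#' irinotecan, reduced capecitabine -> CAPOX, S-1 -> SOX).
#'
#' @return Character vector of scenario names.
#' @export
builtin_scenarios <- function() c("capox", "folfox", "cap_mono")

config_path <- function(name) {
  system.file("extdata", "scenarios", paste0(name, ".yaml"),
              package = "s1switch", mustWork = TRUE)
}

req <- function(x, key, where) {
  if (is.null(x[[key]])) {
    stop("validation error: missing required key '", key, "' in ", where)
  }
  x[[key]]
}

parse_regimen <- function(node, where) {
  if (is.null(node)) return(NULL)
  name <- if (is.null(node$name)) where else node$name
  cyc <- req(node, "cycle_weeks", where)
  if (!is.null(node$components)) {
    admin <- if (is.null(node$admin)) NA_character_ else node$admin
    regimen_from_components(name, unlist(node$components), admin, cyc)
  } else {
    regimen_cost(name, req(node, "drug_cost", where),
                 if (is.null(node$admin_cost)) 0 else node$admin_cost, cyc)
  }
}

parse_ae <- function(node) {
  if (is.null(node)) node <- list()
  g <- function(key, default) if (is.null(node[[key]])) default else node[[key]]
  adverse_event_profile(
    p_hfs = g("p_hfs", 0), p_cvt = g("p_cvt", 0),
    p_diarrhoea = g("p_diarrhoea", 0), p_anorexia = g("p_anorexia", 0),
    cost_hfs = g("cost_hfs", 50), cost_cvt = g("cost_cvt", 200),
    disutility = g("disutility", 0.15), duration = g("duration_weeks", 2)
  )
}

#' Load and validate a scenario configuration
#'
#' Accepts either the name of a bundled scenario (see
#' [builtin_scenarios()]) or the path to a YAML configuration file
#' following the bundled schema. All calibration values are validated
#' (probabilities in range, costs non-negative, cycle lengths 2 or 3) and
#' omitted settings are filled with the model defaults.
#'
#' @param source Scenario name or path to a YAML file.
#' @return A list with elements `scenario` (a `scenario_spec`) and
#'   `settings` (a `model_settings`).
#' @export
#' @examples
#' cfg <- load_scenario("capox")
#' names(cfg$scenario$strategies)
load_scenario <- function(source) {
  path <- if (source %in% builtin_scenarios()) config_path(source)
          else source
  if (!file.exists(path)) {
    stop("validation error: unknown scenario or missing config file: '",
         source, "'")
  }
  raw <- yaml::read_yaml(path)
  sc <- req(raw, "scenario", "config root")
  sc_name <- req(sc, "name", "scenario")
  strat_nodes <- req(sc, "strategies", "scenario")
  if (length(strat_nodes) < 2) {
    stop("validation error: 'strategies' must list at least 2 strategies")
  }
  strategies <- lapply(strat_nodes, function(s) {
    nm <- req(s, "name", "strategy")
    where <- paste0("strategy '", nm, "'")
    strategy_spec(
      name = nm,
      label = if (is.null(s$label)) nm else s$label,
      first_line = parse_regimen(s$first_line, paste0(where, " first_line")),
      second_line = parse_regimen(req(s, "second_line", where),
                                  paste0(where, " second_line")),
      rr_os = req(s, "rr_os", where),
      rr_ttp = req(s, "rr_ttp", where),
      ae = parse_ae(s$ae),
      s1_based = isTRUE(s$s1_based),
      discontinuation = isTRUE(s$discontinuation) || is.null(s$first_line)
    )
  })
  scen <- scenario_spec(sc_name, strategies,
                        req(sc, "reference_strategy", "scenario"))
  st <- raw$settings
  g <- function(key, default) if (is.null(st[[key]])) default else st[[key]]
  settings <- model_settings(
    horizon = g("horizon_weeks", 780),
    weeks_per_year = g("weeks_per_year", 365.25 / 7),
    discount_costs = g("discount_costs", 0.03),
    discount_qalys = g("discount_qalys", 0.015),
    p_second_line = g("p_second_line", 0.80),
    cohort_size = g("cohort_size", 1000)
  )
  list(scenario = scen, settings = settings)
}

regimen_to_config <- function(r) {
  if (is.null(r)) return(NULL)
  out <- list(name = r$name)
  if (!is.null(r$drug_components)) {
    out$components <- as.list(r$drug_components)
    if (!is.na(r$admin_component)) out$admin <- r$admin_component
  } else {
    out$drug_cost <- r$drug_cost_per_cycle
    out$admin_cost <- r$admin_cost_per_cycle
  }
  out$cycle_weeks <- r$cycle_length
  out
}

#' Serialise a scenario back to its canonical configuration form
#'
#' Inverse of [load_scenario()]: produces the canonical nested-list form of
#' the configuration (all defaults made explicit), optionally writing it as
#' YAML. Loading the written file reproduces the same objects.
#'
#' @param scenario A `scenario_spec`.
#' @param settings A `model_settings`.
#' @param file Optional path; if given, the YAML is written there.
#' @return The canonical configuration list, invisibly if `file` is given.
#' @export
write_scenario <- function(scenario, settings, file = NULL) {
  cfg <- list(
    scenario = list(
      name = scenario$name,
      reference_strategy = scenario$reference_strategy,
      strategies = lapply(unname(scenario$strategies), function(s) {
        list(
          name = s$name, label = s$label,
          first_line = regimen_to_config(s$first_line),
          second_line = regimen_to_config(s$second_line),
          rr_os = s$rr_os, rr_ttp = s$rr_ttp,
          s1_based = s$s1_based, discontinuation = s$discontinuation,
          ae = list(
            p_hfs = s$ae$p_hfs, p_cvt = s$ae$p_cvt,
            p_diarrhoea = s$ae$p_diarrhoea, p_anorexia = s$ae$p_anorexia,
            cost_hfs = s$ae$cost_hfs, cost_cvt = s$ae$cost_cvt,
            disutility = s$ae$disutility, duration_weeks = s$ae$duration
          )
        )
      })
    ),
    settings = list(
      horizon_weeks = settings$horizon,
      weeks_per_year = settings$weeks_per_year,
      discount_costs = settings$discount_costs,
      discount_qalys = settings$discount_qalys,
      p_second_line = settings$p_second_line,
      cohort_size = settings$cohort_size
    )
  )
  if (!is.null(file)) {
    yaml::write_yaml(cfg, file, precision = 15)
    return(invisible(cfg))
  }
  cfg
}
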